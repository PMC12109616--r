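#include <Rcpp.h>
using namespace Rcpp;

// EM for the equal-variance two-component Gaussian mixture.
// Log-space responsibilities so far-tail points cannot underflow the
// denominator. Returns the fitted parameters, log-likelihood, iteration
// count and convergence flag for one start.
// [[Rcpp::export(name = ".em_gmm2_cpp")]]
List em_gmm2_cpp(NumericVector x, double mu1, double mu2, double sigma,
                 double pi_hi, double tol, int max_iter, double sigma_floor) {
  const int n = x.size();
  if (sigma < sigma_floor) sigma = sigma_floor;
  if (pi_hi < 1e-6) pi_hi = 1e-6;
  if (pi_hi > 1 - 1e-6) pi_hi = 1 - 1e-6;
  std::vector<double> gam(n);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, monotone = true;
  int iter = 0;
  const double log2pi = std::log(2.0 * M_PI);
  while (iter < max_iter) {
    ++iter;
    const double lsig = std::log(sigma);
    const double lp1 = std::log1p(-pi_hi), lp2 = std::log(pi_hi);
    // equal variances make the log-odds of component membership linear in x:
    // u = lb - la = c0 + c1 * x, so one exp and one log1p per point suffice
    const double inv_s2 = 1.0 / (sigma * sigma);
    const double c1 = (mu2 - mu1) * inv_s2;
    const double c0 = lp2 - lp1 + 0.5 * (mu1 * mu1 - mu2 * mu2) * inv_s2;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double z1 = (x[i] - mu1) / sigma;
      const double la = lp1 - 0.5 * z1 * z1 - lsig - 0.5 * log2pi;
      const double u = c0 + c1 * x[i];
      if (u <= 0) {
        const double eu = std::exp(u);
        ll += la + std::log1p(eu);
        gam[i] = eu / (1.0 + eu);
      } else {
        const double enu = std::exp(-u);
        ll += la + u + std::log1p(enu);
        gam[i] = 1.0 / (1.0 + enu);
      }
    }
    if (R_finite(ll_old) && ll < ll_old - 1e-6 * (std::fabs(ll_old) + 1.0))
      monotone = false; // EM guarantees ascent; a drop signals a defect
    if (R_finite(ll) && R_finite(ll_old) &&
        std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + tol)) {
      converged = true;
      break;
    }
    ll_old = ll;
    if (iter >= max_iter) break;
    double sg = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      sg += gam[i];
      s2 += gam[i] * x[i];
      s1 += (1.0 - gam[i]) * x[i];
    }
    pi_hi = sg / n;
    if (pi_hi < 1e-12) pi_hi = 1e-12;
    if (pi_hi > 1 - 1e-12) pi_hi = 1 - 1e-12;
    mu1 = s1 / std::max(n - sg, 1e-12);
    mu2 = s2 / std::max(sg, 1e-12);
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d1 = x[i] - mu1, d2 = x[i] - mu2;
      ss += (1.0 - gam[i]) * d1 * d1 + gam[i] * d2 * d2;
    }
    sigma = std::sqrt(ss / n);
    if (sigma < sigma_floor) sigma = sigma_floor;
  }
  return List::create(_["mu1"] = mu1, _["mu2"] = mu2, _["sigma"] = sigma,
                      _["pi"] = pi_hi, _["loglik"] = ll, _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["monotone"] = monotone);
}
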