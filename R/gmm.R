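#' Fit a two-component equal-variance Gaussian mixture
#'
#' Expectation-maximization for the model
#' `x ~ (1 - pi) N(mu_low, sigma^2) + pi N(mu_high, sigma^2)`, the working
#' model behind bimodal-expression screening. Multiple deterministic starts
#' (quantile splits at 25/50/75%) guard against local optima; the best
#' restart by log-likelihood is kept and components are relabeled so
#' `mu_low <= mu_high`. The common SD is floored at `1e-6 * sd(x)` to
#' prevent component collapse.
#'
#' @param values Numeric vector; at least 10 finite values with nonzero
#'   variance.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Number of starts. The first three are deterministic
#'   quantile splits; any further starts are random and use `seed`.
#' @param seed Seed for random restarts beyond the deterministic three.
#' @return An object of class `gmm2_fit` with fields `mu_low`, `mu_high`,
#'   `sigma`, `pi` (proportion of the high component), `delta`
#'   (standardized separation `(mu_high - mu_low)/sigma`), `bi` (bimodal
#'   index), `cutoff` (posterior-0.5 crossing), `loglik`, `n_iter`,
#'   `converged`, `n`, and the input `values`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(700, 0), rnorm(300, 3))
#' fit <- fit_gmm2(x)
#' fit$bi
#' @export
fit_gmm2 <- function(values, tol = 1e-8, max_iter = 500L, n_starts = 3L, seed = 1L) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop_arg("need at least 10 finite values, got %d", length(x))
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop_degenerate("input is constant; mixture fit is undefined")
  sigma_floor <- 1e-6 * s

  pi0 <- c(0.25, 0.5, 0.75)
  starts <- lapply(pi0, function(p) {
    q <- quantile(x, 1 - p, names = FALSE, type = 7)
    hi <- x > q
    if (!any(hi) || all(hi)) hi <- x > median(x)
    list(mu1 = mean(x[!hi]), mu2 = mean(x[hi]),
         sigma = max(s / 2, sigma_floor), pi = mean(hi))
  })
  if (n_starts > 3) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    extra <- lapply(seq_len(n_starts - 3), function(i) {
      mus <- sort(sample(x, 2))
      list(mu1 = mus[1], mu2 = mus[2], sigma = s, pi = runif(1, 0.1, 0.9))
    })
    starts <- c(starts, extra)
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (st in starts) {
    fit <- em_gmm2(x, st, tol, max_iter, sigma_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  mu1 <- best$mu1; mu2 <- best$mu2; pi_hi <- best$pi
  if (mu1 > mu2) { # relabel so the high component has the larger mean
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    pi_hi <- 1 - pi_hi
  }
  pi_hi <- min(max(pi_hi, 1e-12), 1 - 1e-12)
  delta <- (mu2 - mu1) / best$sigma
  structure(
    list(
      mu_low = mu1, mu_high = mu2, sigma = best$sigma, pi = pi_hi,
      delta = delta,
      bi = delta * sqrt(pi_hi * (1 - pi_hi)),
      cutoff = gmm2_cutoff(mu1, mu2, best$sigma, pi_hi),
      loglik = best$loglik, n_iter = best$n_iter, converged = best$converged,
      loglik_monotone = best$monotone,
      n = length(x), values = x
    ),
    class = "gmm2_fit"
  )
}

# one EM run; compiled inner loop, log-space responsibilities
em_gmm2 <- function(x, start, tol, max_iter, sigma_floor) {
  .em_gmm2_cpp(x, start$mu1, start$mu2, max(start$sigma, sigma_floor),
               min(max(start$pi, 1e-6), 1 - 1e-6),
               tol, as.integer(max_iter), sigma_floor)
}

# posterior-0.5 crossing; closed form for equal variances
gmm2_cutoff <- function(mu1, mu2, sigma, pi_hi) {
  if (mu2 <= mu1) return(NA_real_)
  (mu1 + mu2) / 2 + sigma^2 * log((1 - pi_hi) / pi_hi) / (mu2 - mu1)
}

#' Bimodal index of a fitted two-component mixture
#'
#' `BI = delta * sqrt(pi * (1 - pi))` with `delta = (mu_high - mu_low) /
#' sigma`: the standardized separation weighted by how balanced the two
#' components are. Large values indicate a well-separated, non-trivial
#' minor component.
#'
#' @param fit A [fit_gmm2()] result, or any list with `delta` and `pi`.
#' @return A single number.
#' @examples
#' bimodal_index(list(delta = 2, pi = 0.5)) # 1
#' @export
bimodal_index <- function(fit) {
  stopifnot(is.numeric(fit$delta), is.numeric(fit$pi))
  fit$delta * sqrt(fit$pi * (1 - fit$pi))
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<gmm2_fit> n = %d\n  mu_low = %.4g, mu_high = %.4g, sigma = %.4g, ",
           "pi(high) = %.4g\n  delta = %.4g, BI = %.4g, cutoff = %.4g\n",
           "  loglik = %.6g after %d iteration(s)%s\n"),
    x$n, x$mu_low, x$mu_high, x$sigma, x$pi, x$delta, x$bi, x$cutoff,
    x$loglik, x$n_iter, if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for mixture fits
#'
#' `tidy()` returns one row per estimated parameter; `glance()` returns a
#' one-row model summary including the bimodal index.
#'
#' @param x A `gmm2_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gmm2_fit <- function(x, ...) {
  tibble(
    term = c("mu_low", "mu_high", "sigma", "pi"),
    estimate = c(x$mu_low, x$mu_high, x$sigma, x$pi)
  )
}

#' @rdname tidy.gmm2_fit
#' @export
glance.gmm2_fit <- function(x, ...) {
  tibble(
    n = x$n, loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    delta = x$delta, bi = x$bi, cutoff = x$cutoff
  )
}

#' Plot a fitted mixture over the data
#'
#' Histogram of the input values with the two scaled component densities and
#' the model-based dichotomization cutoff.
#'
#' @param object A `gmm2_fit`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm2_fit <- function(object, bins = 40, ...) {
  grid <- seq(min(object$values), max(object$values), length.out = 400)
  dens <- tibble(
    x = rep(grid, 2),
    component = rep(c("low", "high"), each = length(grid)),
    density = c((1 - object$pi) * dnorm(grid, object$mu_low, object$sigma),
                object$pi * dnorm(grid, object$mu_high, object$sigma))
  )
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(x = object$values),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey80", color = "grey50"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, color = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "expression", y = "density", color = "component") +
    ggplot2::theme_minimal()
}
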