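test_that("EM recovers known mixture parameters at n = 2000", {
  x <- mixture_sample(2000, mu1 = 0, mu2 = 3, sigma = 1, pi_high = 0.3, seed = 42)
  fit <- fit_gmm2(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_low - 0), 0.15)
  expect_lt(abs(fit$mu_high - 3), 0.15)
  expect_lt(abs(fit$sigma - 1), 0.15)
  expect_lt(abs(fit$pi - 0.3), 0.15)
})

test_that("degenerate input is rejected and short input errors", {
  expect_error(fit_gmm2(rep(0, 50)), class = "bimodalsurv_degenerate_error")
  expect_error(fit_gmm2(1:5), class = "bimodalsurv_argument_error")
})

test_that("bimodal index follows its closed form and limits", {
  expect_identical(bimodal_index(list(delta = 2, pi = 0.5)), 1.0)
  expect_identical(bimodal_index(list(delta = 3, pi = 0.5)), 1.5)
  # vanishing minor component drives BI to zero monotonically
  pis <- c(0.2, 0.1, 0.01, 0.001)
  bis <- vapply(pis, function(p) bimodal_index(list(delta = 2, pi = p)), numeric(1))
  expect_true(all(diff(bis) < 0))
  expect_lt(bis[length(bis)], 0.1)
})

test_that("EM log-likelihood ascends monotonically on varied inputs", {
  for (s in 1:8) {
    x <- withr::with_seed(s, c(rnorm(150, 0), rnorm(50 + 10 * s, 2 + 0.3 * s)))
    fit <- fit_gmm2(x)
    expect_true(fit$loglik_monotone)
  }
})

test_that("fitting a negated sample gives the mirrored fit and identical BI", {
  x <- mixture_sample(800, mu1 = 1, mu2 = 4, sigma = 0.8, pi_high = 0.25, seed = 9)
  f1 <- fit_gmm2(x)
  f2 <- fit_gmm2(-x)
  expect_equal(f2$mu_low, -f1$mu_high, tolerance = 1e-5)
  expect_equal(f2$mu_high, -f1$mu_low, tolerance = 1e-5)
  expect_equal(f2$pi, 1 - f1$pi, tolerance = 1e-5)
  expect_equal(f2$bi, f1$bi, tolerance = 1e-5)
})

test_that("BI estimates at n = 1e4 sit within 3 Monte-Carlo SEs of truth", {
  delta_true <- 2.5; pi_true <- 0.35
  bi_true <- delta_true * sqrt(pi_true * (1 - pi_true))
  bis <- vapply(1:5, function(s) {
    x <- mixture_sample(10000, mu1 = 0, mu2 = delta_true, sigma = 1,
                        pi_high = pi_true, seed = 100 + s)
    fit_gmm2(x)$bi
  }, numeric(1))
  mc_se <- sd(bis) / sqrt(length(bis))
  expect_lt(abs(mean(bis) - bi_true), 3 * max(mc_se, 0.01))
})

test_that("the closed-form cutoff is the posterior-0.5 root and MAP boundary", {
  for (s in 1:20) {
    pars <- withr::with_seed(200 + s, list(
      mu1 = runif(1, -2, 2), dmu = runif(1, 1.5, 4),
      sigma = runif(1, 0.5, 1.5), pi = runif(1, 0.15, 0.85)
    ))
    x <- mixture_sample(300, pars$mu1, pars$mu1 + pars$dmu, pars$sigma,
                        pars$pi, seed = 300 + s)
    fit <- fit_gmm2(x)
    post_high <- function(v) {
      a <- (1 - fit$pi) * dnorm(v, fit$mu_low, fit$sigma)
      b <- fit$pi * dnorm(v, fit$mu_high, fit$sigma)
      b / (a + b)
    }
    root <- stats::uniroot(function(v) post_high(v) - 0.5,
                           interval = c(fit$mu_low - 10 * fit$sigma,
                                        fit$mu_high + 10 * fit$sigma),
                           tol = 1e-12)$root
    expect_lt(abs(fit$cutoff - root), 1e-8)
    # the crossing sits between the component means whenever the prior odds
    # are dominated by the separation (it drifts outside for weak, lopsided
    # fits, as the posterior algebra dictates)
    if (abs(log((1 - fit$pi) / fit$pi)) < fit$delta^2 / 2) {
      expect_gt(fit$cutoff, fit$mu_low)
      expect_lt(fit$cutoff, fit$mu_high)
    }
    # MAP labels equal thresholding at the cutoff, for every sample
    lab <- dichotomize_cluster(x, fit)
    expect_identical(lab$label == "high", post_high(x) > 0.5)
  }
})

test_that("cluster dichotomization needs a non-degenerate fit and honors pi", {
  # balanced components put the cutoff exactly at the midpoint
  expect_equal(bimodalsurv:::gmm2_cutoff(0, 3, 1, 0.5), 1.5)
  # a rarer high component pushes the cutoff toward it
  expect_gt(bimodalsurv:::gmm2_cutoff(0, 3, 1, 0.2), 1.5)
  x <- mixture_sample(400, 0, 3, 1, 0.5, seed = 5)
  fake <- structure(list(delta = 0, cutoff = NA_real_), class = "gmm2_fit")
  expect_error(dichotomize_cluster(x, fake), class = "bimodalsurv_degenerate_error")
})

test_that("median dichotomization labels strictly above the median as high", {
  lab <- dichotomize_median(c(1, 2, 3, 4))
  expect_identical(as.character(lab$label), c("low", "low", "high", "high"))
  all_tied <- dichotomize_median(rep(2, 6))
  expect_true(all(all_tied$label == "low"))
  v <- withr::with_seed(8, sample(rep(1:5, times = c(3, 1, 4, 1, 1))))
  lab2 <- dichotomize_median(v)
  n_ties <- sum(v == median(v))
  # ties all go low, so the imbalance is bounded by twice the tie count
  expect_lte(abs(sum(lab2$label == "high") - sum(lab2$label == "low")), 2 * n_ties)
})

test_that("quantile-band dichotomization uses type-7 quantiles with strict edges", {
  lab <- dichotomize_quantile(1:100)
  expect_equal(sum(lab$label == "high"), 20)
  expect_equal(sum(lab$label == "low"), 70)
  expect_equal(sum(lab$label == "excluded"), 10)
  collapsed <- dichotomize_quantile(1:9, hi_q = 0.5, lo_q = 0.5)
  med <- median(1:9)
  expect_identical(as.character(collapsed$label),
                   ifelse(1:9 > med, "high", ifelse(1:9 < med, "low", "excluded")))
  none_high <- dichotomize_quantile(1:50, hi_q = 1, lo_q = 0.5)
  expect_equal(sum(none_high$label == "high"), 0)
  expect_error(dichotomize_quantile(1:10, hi_q = 0.3, lo_q = 0.7),
               class = "bimodalsurv_argument_error")
})

test_that("z-score standardization centers, scales, and is affine invariant", {
  expect_equal(zscore_standardize(c(1, 2, 3)), c(-1, 0, 1))
  v <- withr::with_seed(3, rnorm(50, 10, 4))
  z <- zscore_standardize(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_standardize(2 + 3 * v), z, tolerance = 1e-12)
  expect_error(zscore_standardize(rep(1, 10)), class = "bimodalsurv_degenerate_error")
})

test_that("the bimodal screen ranks genes by BI and flags degenerate genes", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 300, n_null_genes = 30,
                          n_null_candidates = 0, seed = 17)
  co <- simulate_cohort(cfg, 1)
  vals <- rbind(co$expression$values, CONSTG = rep(5, 300))
  ds <- expression_dataset(vals, "c1")
  scr <- screen_bimodal_genes(ds)
  expect_identical(scr$gene[1], "KYNU")
  expect_true(all(diff(scr$bi[!scr$degenerate]) <= 0))
  const_row <- scr[scr$gene == "CONSTG", ]
  expect_true(const_row$degenerate)
  expect_true(is.na(const_row$rank))
  expect_equal(sum(!is.na(scr$rank)), sum(!scr$degenerate))
})

test_that("tidy and glance summarize mixture fits", {
  x <- mixture_sample(500, 0, 3, 1, 0.3, seed = 12)
  fit <- fit_gmm2(x)
  td <- tidy(fit)
  expect_identical(td$term, c("mu_low", "mu_high", "sigma", "pi"))
  gl <- glance(fit)
  expect_equal(gl$bi, fit$bi)
  expect_s3_class(autoplot(fit), "ggplot")
})
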