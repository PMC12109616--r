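test_that("the Cox Newton fit matches a dense grid search of the Efron partial likelihood", {
  clin <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    time = c(2, 4, 5, 7, 9, 11, 14, 18),
    event = c(1, 1, 0, 1, 1, 0, 1, 1)
  )
  x <- c(1, 0, 1, 0, 1, 1, 0, 0)
  eff <- cox_fit(clin, list(grp = x))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, efron_partial_loglik, numeric(1),
               time = clin$time, event = clin$event, x = x)
  beta_grid <- grid[which.max(ll)]
  expect_lt(abs(eff$log_hr - beta_grid), 1e-3)
  expect_equal(eff$hr, exp(eff$log_hr))
  expect_equal(eff$n_events, 6)
})

test_that("a binary Cox coefficient is antisymmetric under label swap", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 120, n_null_genes = 0,
                          n_null_candidates = 0, seed = 88)
  co <- simulate_cohort(cfg, 1)
  z <- unname(co$truth$z)
  a <- cox_fit(co$clinical, list(grp = z))
  b <- cox_fit(co$clinical, list(grp = 1 - z))
  expect_equal(a$log_hr, -b$log_hr, tolerance = 1e-8)
  expect_equal(a$se, b$se, tolerance = 1e-8)
})

test_that("degenerate Cox designs are refused", {
  clin <- tibble::tibble(sample_id = sprintf("s%d", 1:20),
                         time = seq(1, 20), event = rep(c(1, 0), 10))
  x <- rep(c(0, 1), 10)
  expect_error(cox_fit(clin, list(a = x, b = x)),
               class = "bimodalsurv_degenerate_error")
  expect_error(cox_fit(clin, list(a = rep(1, 20))),
               class = "bimodalsurv_degenerate_error")
  no_events <- dplyr::mutate(clin, event = 0)
  expect_error(cox_fit(no_events, list(a = x)), class = "bimodalsurv_argument_error")
})

test_that("null binary effects cover zero at the nominal rate", {
  covered <- 0; reps <- 100
  for (r in seq_len(reps)) {
    dat <- withr::with_seed(4000 + r, {
      n <- 80
      tibble::tibble(sample_id = sprintf("s%d", 1:n),
                     time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                     x = rbinom(n, 1, 0.5))
    })
    eff <- tryCatch(cox_fit(dat[, 1:3], list(grp = dat$x)),
                    error = function(e) NULL)
    if (is.null(eff)) next
    ci <- eff$log_hr + c(-1.96, 1.96) * eff$se
    covered <- covered + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(covered / reps, 0.88)
})

test_that("the log-rank test matches a hand-computed table and is symmetric", {
  # 6 subjects, groups A = {t 1+, 3, 5}, B = {2, 4, 6+}; events at 2,3,4,5
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(0, 1, 1, 1, 1, 0)
  grp <- c("A", "A", "A", "B", "B", "B")
  # hand calculation, O-E for group A across event times:
  # t=2: at risk A 2 of 5, death B -> E_A = 2/5
  # t=3: at risk A 2 of 4, death A -> O_A = 1, E_A = 1/2
  # t=4: at risk A 1 of 3, death B -> E_A = 1/3
  # t=5: at risk A 1 of 2, death A -> O_A = 1, E_A = 1/2
  o_minus_e <- (0 - 2 / 5) + (1 - 1 / 2) + (0 - 1 / 3) + (1 - 1 / 2)
  v <- (2 / 5) * (3 / 5) + (1 / 2) * (1 / 2) + (1 / 3) * (2 / 3) + (1 / 2) * (1 / 2)
  expected_stat <- o_minus_e^2 / v
  res <- logrank_test(time, event, grp)
  expect_equal(res$statistic, expected_stat, tolerance = 1e-10)
  # swapping group labels leaves the statistic unchanged
  expect_equal(res$statistic,
               logrank_test(time, event, ifelse(grp == "A", "B", "A"))$statistic)

  # duplicated groups carry no signal
  t2 <- c(1, 2, 3, 1, 2, 3); e2 <- c(1, 1, 0, 1, 1, 0)
  same <- logrank_test(t2, e2, c("A", "A", "A", "B", "B", "B"))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(t2, e2, rep("A", 6)), class = "bimodalsurv_argument_error")
})

test_that("Kaplan-Meier estimates follow the product-limit form", {
  all_cens <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  steps <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(steps$surv, c(2 / 3, 1 / 3, 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "bimodalsurv_domain_error")
  expect_s3_class(autoplot(steps), "ggplot")
})

test_that("DerSimonian-Laird pooling matches a direct formula transcription", {
  th <- c(0.2, 0.5, 0.9); se <- c(0.1, 0.2, 0.3)
  res <- meta_random_effects(tibble::tibble(log_hr = th, se = se))
  # independent transcription of the estimator
  w <- 1 / se^2
  fe <- sum(w * th) / sum(w)
  Q <- sum(w * (th - fe)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * th) / sum(ws)
  expect_equal(res$pooled_log_hr, pooled, tolerance = 1e-10)
  expect_equal(res$pooled_se, sqrt(1 / sum(ws)), tolerance = 1e-10)
  expect_equal(res$tau2, tau2, tolerance = 1e-10)
  expect_equal(res$Q, Q, tolerance = 1e-10)
  # independent implementation cross-check
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = th, sei = se, method = "DL")
  expect_equal(res$pooled_log_hr, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(res$pooled_se, rma$se, tolerance = 1e-8)
  expect_equal(res$tau2, rma$tau2, tolerance = 1e-8)
})

test_that("meta-analysis edge cases behave as the estimator dictates", {
  one <- meta_random_effects(tibble::tibble(log_hr = 0.4, se = 0.2))
  expect_equal(one$pooled_log_hr, 0.4)
  expect_equal(one$pooled_se, 0.2)
  expect_equal(one$tau2, 0)
  expect_equal(one$k, 1)

  homog <- meta_random_effects(tibble::tibble(log_hr = rep(0.3, 4),
                                              se = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(homog$tau2, 0)
  expect_equal(homog$pooled_log_hr, 0.3)
  expect_equal(homog$I2, 0)

  eq_se <- meta_random_effects(tibble::tibble(log_hr = c(0.1, 0.2, 0.3),
                                              se = rep(0.2, 3)))
  # equal SEs: with tau2 the weights stay equal, so pooled = arithmetic mean
  expect_equal(eq_se$pooled_log_hr, 0.2, tolerance = 1e-12)

  expect_error(meta_random_effects(tibble::tibble(log_hr = numeric(0),
                                                  se = numeric(0))),
               class = "bimodalsurv_argument_error")
  expect_error(meta_random_effects(tibble::tibble(log_hr = c(1, Inf), se = c(1, 1))),
               class = "bimodalsurv_argument_error")
})

test_that("tau2 and I2 vanish whenever Q is at most k - 1", {
  for (s in 1:20) {
    eff <- withr::with_seed(600 + s, tibble::tibble(
      log_hr = rnorm(5, 0.2, 0.05), se = runif(5, 0.2, 0.6)
    ))
    res <- meta_random_effects(eff)
    if (res$Q <= nrow(eff) - 1) {
      expect_equal(res$tau2, 0)
      expect_equal(res$I2, 0)
    } else {
      expect_gt(res$tau2, 0)
    }
  }
})

test_that("the survival screen applies the minimum-cohort-size gate exactly", {
  cfg <- synthetic_config(n_cohorts = 3, n_samples = c(9, 10, 50),
                          n_null_genes = 0, n_null_candidates = 0, seed = 77)
  st <- simulate_study(cfg)
  scr <- run_survival_screen(st$cohorts, genes = "KYNU", min_n = 10)
  expect_identical(attr(scr, "cohorts_used"), c("cohort02", "cohort03"))
  bin <- scr[scr$mode == "binary", ]
  expect_equal(bin$k, 2)
  excl <- attr(scr, "exclusions")
  expect_true("cohort01" %in% excl$cohort_id)
  expect_match(excl$reason[excl$cohort_id == "cohort01"][1], "min_n")
})

test_that("genes absent everywhere are reported as not screened", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 40, n_null_genes = 2,
                          n_null_candidates = 0, seed = 78)
  st <- simulate_study(cfg)
  scr <- run_survival_screen(st$cohorts, genes = "NOPE", min_n = 10)
  expect_true(all(scr$screened == FALSE))
})

test_that("binary and continuous modes both recover a positive pooled hazard", {
  cfg <- synthetic_config(n_cohorts = 3, n_samples = 150, n_null_genes = 0,
                          n_null_candidates = 0, seed = 79)
  st <- simulate_study(cfg)
  scr <- run_survival_screen(st$cohorts, genes = "KYNU")
  expect_equal(nrow(scr), 2)
  expect_true(all(scr$screened))
  expect_true(all(scr$pooled_log_hr > 0))
  expect_s3_class(plot_meta_forest(scr, "KYNU", "binary"), "ggplot")
})
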