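test_that("the correlation screen excludes the target and honors affine structure", {
  n <- 60
  x <- withr::with_seed(1, rnorm(n, 5, 1))
  vals <- rbind(
    KYNU = x,
    AFFINE = 2 + 3 * x,
    NOISE = withr::with_seed(2, rnorm(n)),
    FLAT = rep(1, n)
  )
  colnames(vals) <- sprintf("s%02d", 1:n)
  ds <- expression_dataset(vals, "c1")
  res <- correlation_screen(ds, "KYNU")
  expect_false("KYNU" %in% res$feature)
  expect_equal(res$r[res$feature == "AFFINE"], 1, tolerance = 1e-12)
  expect_true(res$flagged[res$feature == "FLAT"])
  expect_true(is.na(res$r[res$feature == "FLAT"]))
  expect_lt(abs(res$r[res$feature == "NOISE"]), 3 / sqrt(n))
})

test_that("correlations in the generative model match the closed form", {
  # m = a + b x + noise: cor(x, m) = b sd(x) / sqrt(b^2 var(x) + tau^2)
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 4000, n_null_genes = 0,
                          n_null_candidates = 0, met_slope = 0.5,
                          met_gamma_keap1 = 0, met_gamma_stk11 = 0,
                          met_sd = 1, seed = 99)
  co <- simulate_cohort(cfg, 1)
  x <- co$expression$values["KYNU", ]
  m <- co$metabolites$metabolite
  var_x <- 1 + 3^2 * 0.3 * 0.7 # sigma^2 + delta^2 pi (1 - pi)
  r_theory <- 0.5 * sqrt(var_x) / sqrt(0.25 * var_x + 1)
  r_obs <- cor(x, m)
  se_r <- (1 - r_theory^2) / sqrt(length(x) - 3)
  expect_lt(abs(r_obs - r_theory), 3 * se_r)
})

test_that("within-group correlation detects biphasic association", {
  n <- 400
  dat <- withr::with_seed(7, {
    x <- c(rnorm(n / 2, 0), rnorm(n / 2, 4))
    y <- ifelse(x < 2, 0.8 * x, 0) + rnorm(n, 0, 0.5)
    list(x = x, y = y)
  })
  fit <- fit_gmm2(dat$x)
  lab <- dichotomize_cluster(dat$x, fit)
  res <- within_group_correlation(dat$x, dat$y, lab)
  expect_gt(res$r[res$group == "low"], 0.5)
  expect_lt(abs(res$r[res$group == "high"]), 0.2)

  # independent y: both group correlations are small
  y0 <- withr::with_seed(8, rnorm(n))
  res0 <- within_group_correlation(dat$x, y0, lab)
  for (g in c("low", "high"))
    expect_lt(abs(res0$r[res0$group == g]), 2 / sqrt(res0$n[res0$group == g]))

  # single-group labels give a single record
  xx <- withr::with_seed(9, rnorm(20))
  one <- bimodalsurv:::new_dichotomy(xx, rep("low", 20), "median", 0)
  res1 <- within_group_correlation(xx, withr::with_seed(10, rnorm(20)), one)
  expect_equal(nrow(res1), 1)
  expect_identical(res1$group, "low")
})

test_that("one-way ANOVA reduces to the squared t statistic for two groups", {
  v <- withr::with_seed(11, rnorm(40))
  g <- rep(c("a", "b"), each = 20)
  res <- anova_oneway(v, g)
  tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_oneway(v, rep("a", 40)), class = "bimodalsurv_argument_error")
})

test_that("genotype effects on the metabolite are detected by ANOVA", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 400, n_null_genes = 0,
                          n_null_candidates = 0, met_gamma_keap1 = 1,
                          met_gamma_stk11 = 1, met_sd = 1, seed = 12)
  co <- simulate_cohort(cfg, 1)
  status <- call_tsg_status(colnames(co$expression$values),
                            mutations = co$mutations)
  grp <- assign_genotype_group(status)
  m <- co$metabolites$metabolite[match(grp$sample_id, co$metabolites$sample_id)]
  res <- anova_oneway(m, grp$group)
  expect_lt(res$p, 0.01)
})

test_that("the multivariate metabolite model adjusts for genotype confounding", {
  n <- 200
  dat <- withr::with_seed(13, {
    keap1 <- rbinom(n, 1, 0.3)
    stk11 <- rbinom(n, 1, 0.3)
    kynu <- rbinom(n, 1, 0.4)
    met <- 2 * keap1 + rnorm(n) # driven only by keap1
    list(keap1 = keap1, stk11 = stk11, kynu = kynu, met = met)
  })
  fit <- metabolite_multivariate(dat$met, dat$kynu, dat$keap1, dat$stk11)
  kynu_row <- fit[fit$term == "kynu_status", ]
  keap_row <- fit[fit$term == "keap1", ]
  expect_lt(abs(kynu_row$estimate), 1.96 * kynu_row$se) # CI covers 0
  expect_gt(abs(keap_row$estimate), 1.96 * keap_row$se) # CI excludes 0
  expect_error(metabolite_multivariate(dat$met, dat$keap1, dat$keap1, dat$stk11),
               class = "bimodalsurv_degenerate_error")
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_gte(gl$r_squared, 0)
})

test_that("the metabolite model recovers the dichotomy-induced mean difference", {
  hits <- 0; reps <- 25
  for (r in seq_len(reps)) {
    cfg <- synthetic_config(n_cohorts = 1, n_samples = 300, n_null_genes = 0,
                            n_null_candidates = 0, met_slope = 0.5,
                            met_gamma_keap1 = 0, met_gamma_stk11 = 0,
                            met_sd = 1, seed = 7000 + r)
    co <- simulate_cohort(cfg, 1)
    x <- co$expression$values["KYNU", ]
    lab <- dichotomize_cluster(x, fit_gmm2(x))
    hi <- lab$label == "high"
    induced <- 0.5 * (mean(x[hi]) - mean(x[!hi]))
    fit <- metabolite_multivariate(co$metabolites$metabolite, hi,
                                   co$truth$mut_keap1, co$truth$mut_stk11)
    kr <- fit[fit$term == "kynu_status", ]
    hits <- hits + (abs(kr$estimate - induced) <= 3 * kr$se)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("hypergeometric enrichment matches direct pmf summation", {
  universe <- sprintf("g%02d", 1:20)
  sets <- gene_set_collection(list(S = universe[1:5]))
  hits <- c(universe[c(1, 2, 3)], universe[10:11]) # overlap k = 3, n_h = 5
  res <- hypergeom_enrichment(hits, sets, universe)
  p_direct <- sum(vapply(3:5, function(j)
    choose(5, j) * choose(15, 5 - j) / choose(20, 5), numeric(1)))
  expect_equal(res$p, p_direct, tolerance = 1e-14)

  # saturation: hits = universe makes every overlap certain
  res_sat <- hypergeom_enrichment(universe, sets, universe)
  expect_equal(res_sat$p, 1)

  # disjoint sets are skipped with a notice
  sets2 <- gene_set_collection(list(S = universe[1:5], OFF = c("zz1", "zz2")))
  expect_message(res2 <- hypergeom_enrichment(hits, sets2, universe), "disjoint")
  expect_identical(res2$set_name, "S")
  expect_error(hypergeom_enrichment(hits, sets, character(0)),
               class = "bimodalsurv_argument_error")
})

test_that("enrichment p decreases as the overlap grows", {
  universe <- sprintf("g%03d", 1:100)
  setg <- universe[1:10]
  sets <- gene_set_collection(list(S = setg))
  ps <- vapply(1:10, function(k) {
    hits <- c(setg[seq_len(k)], universe[60:(79 - k)])
    hypergeom_enrichment(hits, sets, universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("cross-cohort intersection keeps features significant everywhere", {
  r1 <- tibble::tibble(feature = c("a", "b", "c"), p_adj = c(0.01, 0.2, 0.03))
  r2 <- tibble::tibble(feature = c("a", "b", "c"), p_adj = c(0.04, 0.01, 0.5))
  expect_identical(intersect_significant(list(r1, r2)), "a")
  expect_identical(intersect_significant(list(r1)), c("a", "c"))
})
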