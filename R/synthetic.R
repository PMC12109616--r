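#' Configure a synthetic multi-cohort study
#'
#' Defines every generative parameter of a simulated multi-cohort biomarker
#' study with the statistical structure the pipeline assumes: one target gene
#' whose expression is a two-component equal-variance Gaussian mixture,
#' survival times whose hazard depends on the latent mixture component,
#' tumor-suppressor mutations enriched in the high-expression component, a
#' metabolite linearly coupled to expression and genotype, and unimodal null
#' genes.
#'
#' Defaults emulate a desk-scale multi-cohort lung-adenocarcinoma study:
#' one 500-patient discovery cohort plus four smaller validation cohorts
#' (200/150/120/100), a clearly separated mixture (delta = 3 SD, 30% high),
#' a doubled hazard in the high component with administrative censoring at
#' 60 months, and KEAP1/STK11 mutations strongly enriched in the high
#' component.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples Integer vector of per-cohort sample sizes (recycled to
#'   `n_cohorts`).
#' @param n_null_genes Number of i.i.d. Gaussian null genes.
#' @param n_null_candidates Number of null candidate genes in the mutation
#'   table (mutated at `background_mut_rate` independently of the mixture).
#' @param target_gene Name of the bimodal target gene.
#' @param mu_low Mean of the low component (log2-like scale).
#' @param delta Separation `mu_high - mu_low` in expression units.
#' @param sigma Common within-component SD (> 0).
#' @param pi_high Proportion of the high component, in (0, 1).
#' @param baseline_rate Baseline exponential hazard (events per time unit).
#' @param log_hr_component Log hazard ratio of the high vs low component.
#' @param admin_time Administrative censoring time.
#' @param random_censor_rate Rate of additional exponential censoring
#'   (0 disables it).
#' @param q_high,q_low Mutation probability of KEAP1 and STK11 given the
#'   high / low component.
#' @param background_mut_rate Mutation probability of null candidate genes.
#' @param met_intercept,met_slope Metabolite model intercept and slope per
#'   unit of target expression.
#' @param met_gamma_keap1,met_gamma_stk11 Additive metabolite effects of a
#'   KEAP1 / STK11 mutation.
#' @param met_sd Metabolite residual SD.
#' @param seed Master seed; every cohort draws from a substream derived
#'   deterministically from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cohorts = 5,
                             n_samples = c(500, 200, 150, 120, 100),
                             n_null_genes = 200,
                             n_null_candidates = 50,
                             target_gene = "KYNU",
                             mu_low = 4,
                             delta = 3,
                             sigma = 1,
                             pi_high = 0.3,
                             baseline_rate = 0.05,
                             log_hr_component = log(2),
                             admin_time = 60,
                             random_censor_rate = 0.01,
                             q_high = 0.5,
                             q_low = 0.05,
                             background_mut_rate = 0.15,
                             met_intercept = 0,
                             met_slope = 0.5,
                             met_gamma_keap1 = 0.5,
                             met_gamma_stk11 = 0.5,
                             met_sd = 1,
                             seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_samples = rep_len(as.integer(n_samples), n_cohorts),
    n_null_genes = as.integer(n_null_genes),
    n_null_candidates = as.integer(n_null_candidates),
    target_gene = as.character(target_gene),
    mu_low = mu_low, delta = delta, sigma = sigma, pi_high = pi_high,
    baseline_rate = baseline_rate, log_hr_component = log_hr_component,
    admin_time = admin_time, random_censor_rate = random_censor_rate,
    q_high = q_high, q_low = q_low, background_mut_rate = background_mut_rate,
    met_intercept = met_intercept, met_slope = met_slope,
    met_gamma_keap1 = met_gamma_keap1, met_gamma_stk11 = met_gamma_stk11,
    met_sd = met_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_cohorts < 1) stop_arg("`n_cohorts` must be >= 1")
  if (any(cfg$n_samples < 2)) stop_arg("each cohort needs at least 2 samples")
  if (cfg$sigma <= 0) stop_arg("`sigma` must be > 0")
  if (cfg$pi_high <= 0 || cfg$pi_high >= 1) stop_arg("`pi_high` must be in (0, 1)")
  if (cfg$baseline_rate <= 0) stop_arg("`baseline_rate` must be > 0")
  if (cfg$admin_time <= 0) stop_arg("`admin_time` must be > 0")
  if (cfg$random_censor_rate < 0) stop_arg("`random_censor_rate` must be >= 0")
  assert_prob(c(cfg$q_high, cfg$q_low, cfg$background_mut_rate), "mutation probabilities")
  if (cfg$delta < 0) stop_arg("`delta` must be >= 0")
  if (cfg$met_sd <= 0) stop_arg("`met_sd` must be > 0")
  structure(cfg, class = "synthetic_config")
}

#' Simulate one cohort of a synthetic study
#'
#' Draws, for each sample, a latent component `z ~ Bernoulli(pi_high)`;
#' target expression `mu_low + z * delta + N(0, sigma^2)`; an event time
#' `Exponential(baseline_rate * exp(log_hr_component * z))` subject to
#' administrative plus optional random exponential censoring; KEAP1/STK11
#' mutations with probability `q_high` or `q_low` given `z`; and a
#' metabolite `met_intercept + met_slope * x + gamma_K * mutK +
#' gamma_S * mutS + N(0, met_sd^2)`. Null genes are i.i.d. Gaussian at the
#' marginal target mean.
#'
#' @param config A [synthetic_config()].
#' @param cohort_index 1-based cohort index; selects the deterministic
#'   random substream, so any cohort subset regenerates identically.
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   ([expression_dataset()]), `clinical`, `mutations`, `metabolites`
#'   (tibbles), and `truth` (latent component labels and the generative
#'   parameters).
#' @export
simulate_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (cohort_index < 1 || cohort_index > config$n_cohorts)
    stop_arg("`cohort_index` must be in 1..n_cohorts")
  n <- config$n_samples[cohort_index]
  cohort_id <- sprintf("cohort%02d", cohort_index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config$seed, cohort_index))

  sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))
  z <- rbinom(n, 1, config$pi_high)
  x <- config$mu_low + z * config$delta + rnorm(n, 0, config$sigma)

  # survival: exponential baseline, proportional hazard on the component
  rate <- config$baseline_rate * exp(config$log_hr_component * z)
  t_event <- rexp(n, rate)
  t_cens <- rep(config$admin_time, n)
  if (config$random_censor_rate > 0)
    t_cens <- pmin(t_cens, rexp(n, config$random_censor_rate))
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  mut_k <- rbinom(n, 1, ifelse(z == 1, config$q_high, config$q_low))
  mut_s <- rbinom(n, 1, ifelse(z == 1, config$q_high, config$q_low))

  metab <- config$met_intercept + config$met_slope * x +
    config$met_gamma_keap1 * mut_k + config$met_gamma_stk11 * mut_s +
    rnorm(n, 0, config$met_sd)

  null_mu <- config$mu_low + config$delta * config$pi_high
  nulls <- matrix(rnorm(config$n_null_genes * n, null_mu, config$sigma),
                  nrow = config$n_null_genes, ncol = n)
  expr <- rbind(matrix(x, nrow = 1), nulls)
  rownames(expr) <- c(config$target_gene,
                      sprintf("NULLG%04d", seq_len(config$n_null_genes)))
  colnames(expr) <- sample_ids

  cand <- sprintf("CAND%03d", seq_len(config$n_null_candidates))
  cand_mut <- matrix(
    rbinom(config$n_null_candidates * n, 1, config$background_mut_rate),
    nrow = n
  )
  mut_tbl <- dplyr::bind_rows(
    tibble(sample_id = sample_ids[mut_k == 1], gene = "KEAP1"),
    tibble(sample_id = sample_ids[mut_s == 1], gene = "STK11"),
    tidyr::expand_grid(i = seq_len(n), j = seq_along(cand)) |>
      dplyr::filter(cand_mut[cbind(i, j)] == 1) |>
      dplyr::transmute(sample_id = sample_ids[i], gene = cand[j])
  ) |>
    dplyr::mutate(variant_classification = "Missense_Mutation")

  clinical <- tibble(
    sample_id = sample_ids,
    time = time,
    event = event,
    age = round(rnorm(n, 65, 10), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  )

  structure(
    list(
      cohort_id = cohort_id,
      expression = expression_dataset(expr, cohort_id, log2 = TRUE),
      clinical = clinical,
      mutations = mut_tbl,
      metabolites = tibble(sample_id = sample_ids, metabolite = metab),
      truth = list(
        z = setNames(z, sample_ids),
        mut_keap1 = setNames(mut_k, sample_ids),
        mut_stk11 = setNames(mut_s, sample_ids),
        config = config,
        cohort_seed = substream_seed(config$seed, cohort_index)
      )
    ),
    class = "synthetic_cohort"
  )
}

#' Simulate a full multi-cohort synthetic study
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `cohorts` (list of
#'   [simulate_cohort()] outputs) and `manifest` (tibble of cohort ids,
#'   sizes, substream seeds, and the true generative parameters).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cohorts <- lapply(seq_len(config$n_cohorts), function(i) simulate_cohort(config, i))
  manifest <- tibble(
    cohort_id = vapply(cohorts, `[[`, character(1), "cohort_id"),
    n = config$n_samples,
    cohort_seed = vapply(cohorts, function(co) co$truth$cohort_seed, integer(1)),
    pi_high = config$pi_high, delta = config$delta, sigma = config$sigma,
    log_hr_component = config$log_hr_component
  )
  structure(list(cohorts = cohorts, manifest = manifest, config = config),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Emits, per cohort, expression / clinical / mutation / metabolite TSVs and
#' a study-level manifest TSV, all in the dialects the readers in this
#' package accept.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Tibble listing the written files, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::map_dfr(study$cohorts, function(co) {
    base <- file.path(dir, co$cohort_id)
    write_expression(co$expression, paste0(base, "_expression.tsv"))
    write_clinical(co$clinical, paste0(base, "_clinical.tsv"))
    write_mutations(co$mutations, paste0(base, "_mutations.tsv"))
    readr::write_tsv(co$metabolites, paste0(base, "_metabolites.tsv"))
    tibble(cohort_id = co$cohort_id,
           file = paste0(base, c("_expression.tsv", "_clinical.tsv",
                                 "_mutations.tsv", "_metabolites.tsv")))
  })
  readr::write_tsv(study$manifest, file.path(dir, "manifest.tsv"))
  invisible(files)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
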