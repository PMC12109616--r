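#' Configure an end-to-end pipeline run
#'
#' Bundles the run's inputs (a [synthetic_config()], or paths to on-disk
#' cohort files), stage toggles, thresholds, and the master seed. All
#' randomness in a run flows from this one seed through named substreams.
#'
#' @param synthetic A [synthetic_config()] describing the study to simulate
#'   (the supported input mode; for on-disk data, load cohorts with the
#'   `read_*` functions and call the stage functions directly).
#' @param stages Named logical vector toggling stages among
#'   `bimodal`, `survival`, `genotype`, `association`, `gsea`.
#' @param min_n Minimum cohort size entering the survival meta-analysis.
#' @param min_mut Minimum mutant count for the oncogenotype screen.
#' @param cn_loss_threshold Copy-number loss threshold.
#' @param hi_q,lo_q Quantile-band dichotomization bounds.
#' @param min_bi Bimodal-index threshold flagged by the bimodal screen.
#' @param n_perm GSEA permutation count.
#' @param gmt Optional path to a GMT file for the GSEA stage; when absent,
#'   random demonstration sets are drawn from the simulated gene universe.
#' @param seed Master seed (overrides the synthetic config's seed so one
#'   number controls the whole run).
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       stages = c(bimodal = TRUE, survival = TRUE,
                                  genotype = TRUE, association = TRUE,
                                  gsea = TRUE),
                       min_n = 10, min_mut = 9, cn_loss_threshold = -1,
                       hi_q = 0.8, lo_q = 0.7, min_bi = 1.1,
                       n_perm = 200, gmt = NULL, seed = 1L,
                       out_dir = tempfile("bimodalsurv_run_")) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  all_stages <- c("bimodal", "survival", "genotype", "association", "gsea")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  if (!(min_n >= 2)) stop_arg("`min_n` must be >= 2")
  if (!(min_mut >= 1)) stop_arg("`min_mut` must be >= 1")
  if (!(lo_q >= 0 && hi_q <= 1 && lo_q <= hi_q))
    stop_arg("need 0 <= lo_q <= hi_q <= 1")
  if (n_perm < 100) stop_arg("`n_perm` must be >= 100")
  if (!is.null(gmt) && !file.exists(gmt)) stop_arg("gmt file not found: %s", gmt)
  synthetic$seed <- as.integer(seed)
  structure(
    list(synthetic = synthetic, stages = st, min_n = min_n, min_mut = min_mut,
         cn_loss_threshold = cn_loss_threshold, hi_q = hi_q, lo_q = lo_q,
         min_bi = min_bi, n_perm = n_perm, gmt = gmt, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order — simulate, bimodal
#' screen, dual-mode survival meta-analysis, oncogenotype screen,
#' association analyses, GSEA — writing each stage's tables as TSV under
#' `config$out_dir` and finishing with a `manifest.tsv` listing every
#' output file with its MD5 hash, plus a `run_log.txt` recording the seed
#' and thresholds. Identical configs (including seed) reproduce identical
#' manifests. A stage failure aborts the run with the stage named and
#' leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A [run_config()].
#' @return The manifest tibble (`file`, `stage`, `md5`), invisibly a list
#'   with `manifest` and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("bimodalsurv %s | seed %d", as.character(utils::packageVersion("bimodalsurv")),
           config$seed)
  log_line("thresholds: min_n=%g min_mut=%g cn_loss=%g hi_q=%g lo_q=%g min_bi=%g n_perm=%g",
           config$min_n, config$min_mut, config$cn_loss_threshold,
           config$hi_q, config$lo_q, config$min_bi, config$n_perm)

  outputs <- list()
  results <- list()
  record <- function(stage, file) {
    outputs[[length(outputs) + 1]] <<- tibble(stage = stage, file = file)
  }
  run_stage <- function(stage, fn) {
    log_line("stage %s: start", stage)
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "bimodalsurv_stage_error")
    })
  }

  # simulate (always on: it provides every downstream input)
  study <- run_stage("simulate", function() simulate_study(config$synthetic))
  files <- write_study(study, file.path(config$out_dir, "data"))
  for (f in files$file) record("simulate", f)
  record("simulate", file.path(config$out_dir, "data", "manifest.tsv"))
  results$study <- study
  target <- config$synthetic$target_gene
  co1 <- study$cohorts[[1]]

  if (config$stages[["bimodal"]]) {
    scr <- run_stage("bimodal", function() {
      screen_bimodal_genes(co1$expression, min_bi = config$min_bi)
    })
    f <- file.path(config$out_dir, "bimodal_screen.tsv")
    readr::write_tsv(scr, f); record("bimodal", f)
    results$bimodal <- scr
  }

  if (config$stages[["survival"]]) {
    surv <- run_stage("survival", function() {
      run_survival_screen(study$cohorts, genes = target, min_n = config$min_n)
    })
    f <- file.path(config$out_dir, "survival_meta.tsv")
    flat <- dplyr::select(surv, -dplyr::any_of("per_cohort"))
    readr::write_tsv(flat, f); record("survival", f)
    f2 <- file.path(config$out_dir, "survival_per_cohort.tsv")
    percoh <- dplyr::bind_rows(surv$per_cohort)
    readr::write_tsv(percoh, f2); record("survival", f2)
    excl <- attr(surv, "exclusions")
    f3 <- file.path(config$out_dir, "survival_exclusions.tsv")
    readr::write_tsv(excl %||% tibble(), f3); record("survival", f3)
    results$survival <- surv
  }

  if (config$stages[["genotype"]]) {
    geno <- run_stage("genotype", function() {
      samples <- colnames(co1$expression$values)
      status <- call_tsg_status(samples, mutations = co1$mutations,
                                cn_loss_threshold = config$cn_loss_threshold)
      cand <- setdiff(unique(co1$mutations$gene), character(0))
      hits <- oncogenotype_screen(co1$expression, target, co1$mutations,
                                  candidate_genes = cand,
                                  min_mut = config$min_mut)
      list(status = status, groups = assign_genotype_group(status), hits = hits)
    })
    f <- file.path(config$out_dir, "tsg_status.tsv")
    st_flat <- dplyr::mutate(geno$status,
                             evidence = purrr::map_chr(.data$evidence, paste, collapse = ","))
    readr::write_tsv(st_flat, f); record("genotype", f)
    f2 <- file.path(config$out_dir, "oncogenotype_screen.tsv")
    readr::write_tsv(geno$hits, f2); record("genotype", f2)
    results$genotype <- geno
  }

  if (config$stages[["association"]]) {
    assoc <- run_stage("association", function() {
      corr <- correlation_screen(co1$expression, target)
      fit <- fit_gmm2(co1$expression$values[target, ])
      lab <- dichotomize_cluster(co1$expression$values[target, ], fit)
      mutk <- co1$truth$mut_keap1
      muts <- co1$truth$mut_stk11
      met <- co1$metabolites$metabolite[match(lab$sample_id, co1$metabolites$sample_id)]
      mm <- metabolite_multivariate(met, lab$label == "high",
                                    mutk[lab$sample_id], muts[lab$sample_id])
      list(correlation = corr, metabolite_model = mm)
    })
    f <- file.path(config$out_dir, "correlation_screen.tsv")
    readr::write_tsv(assoc$correlation, f); record("association", f)
    f2 <- file.path(config$out_dir, "metabolite_model.tsv")
    readr::write_tsv(assoc$metabolite_model, f2); record("association", f2)
    results$association <- assoc
  }

  if (config$stages[["gsea"]]) {
    gsea_res <- run_stage("gsea", function() {
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else {
        # demonstration sets drawn reproducibly from the simulated universe
        old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(substream_seed(config$seed, 9001L))
        universe <- rownames(co1$expression$values)
        gene_set_collection(setNames(
          lapply(1:10, function(i) sample(universe, 15)),
          sprintf("DEMO_SET_%02d", 1:10)
        ))
      }
      fit <- fit_gmm2(co1$expression$values[target, ])
      lab <- dichotomize_cluster(co1$expression$values[target, ], fit)
      gsea_permutation(co1$expression, lab$label, sets,
                       n_perm = config$n_perm,
                       seed = substream_seed(config$seed, 9002L))
    })
    f <- file.path(config$out_dir, "gsea_results.tsv")
    flat <- dplyr::mutate(gsea_res,
                          leading_edge = purrr::map_chr(.data$leading_edge,
                                                        paste, collapse = ","))
    readr::write_tsv(flat, f); record("gsea", f)
    results$gsea <- gsea_res
  }

  manifest <- dplyr::bind_rows(outputs) |>
    dplyr::mutate(md5 = unname(tools::md5sum(.data$file)))
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  log_line("run complete: %d files", nrow(manifest))
  results$manifest <- manifest
  invisible(results)
}
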