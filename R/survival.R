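#' Cox proportional-hazards fit
#'
#' Fits a Cox model (Efron tie handling, Newton-Raphson on the partial
#' likelihood via the survival package) of `Surv(time, event)` on one or
#' more predictors and returns one effect row per predictor. With a single
#' predictor this is the univariate per-cohort model of the survival screen;
#' with several it is the multivariate adjustment model.
#'
#' Monotone partial likelihoods (complete separation) are flagged rather
#' than raised: the affected term gets `converged = FALSE` and a signed
#' infinite `log_hr` sentinel, so callers can exclude it from pooling.
#'
#' @param clinical Tibble with columns `sample_id`, `time`, `event`.
#' @param predictors Named list (or data frame) of numeric vectors aligned
#'   with `clinical` rows. Factors/characters are allowed and expanded by
#'   the usual treatment contrasts.
#' @param cohort_id,gene,mode Optional metadata copied into the output.
#' @return A tibble of class `survival_effect` with one row per model term:
#'   `cohort_id`, `gene`, `mode`, `term`, `log_hr`, `se`, `hr`, `p`, `n`,
#'   `n_events`, `converged`.
#' @export
cox_fit <- function(clinical, predictors, cohort_id = NA_character_,
                    gene = NA_character_, mode = NA_character_) {
  clinical <- validate_clinical(clinical)
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  if (is.atomic(predictors)) predictors <- list(x = predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop_arg("`predictors` must be named")
  bad_len <- names(predictors)[lengths(predictors) != nrow(clinical)]
  if (length(bad_len))
    stop_arg("predictor(s) not aligned with clinical rows: %s", paste(bad_len, collapse = ", "))
  if (sum(clinical$event) < 2)
    stop_arg("not estimable: fewer than 2 events")
  const <- names(predictors)[vapply(predictors, function(p) length(unique(p)) < 2, logical(1))]
  if (length(const))
    stop_degenerate("constant predictor(s): %s", paste(const, collapse = ", "))

  df <- data.frame(.time = clinical$time, .event = clinical$event, predictors)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(predictors)), collapse = " + ")
  ))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)
  if (anyNA(beta))
    stop_degenerate("rank-deficient design: term(s) %s not estimable",
                    paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(vcov(fit)))
  log_hr <- unname(beta)
  converged <- rep(TRUE, length(beta))
  # separation sentinel: coefficients running away with exploding SE
  runaway <- sep_warn & (abs(log_hr) > 10 | se > 100)
  if (any(runaway)) {
    converged[runaway] <- FALSE
    log_hr[runaway] <- sign(log_hr[runaway]) * Inf
  }
  p <- ifelse(converged, 2 * pnorm(-abs(log_hr / se)), NA_real_)
  structure(
    tibble(
      cohort_id = cohort_id, gene = gene, mode = mode,
      term = names(beta), log_hr = log_hr, se = unname(se),
      hr = exp(log_hr), p = p,
      n = fit$n, n_events = fit$nevent, converged = converged
    ),
    class = c("survival_effect", class(tibble())))
}

#' Two-group log-rank test
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @param groups Two-level grouping vector.
#' @return A tibble with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(time, event, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop_arg("log-rank test needs exactly two non-empty groups")
  if (any(time < 0)) stop_domain("negative survival times")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- unname(sd_fit$chisq)
  tibble(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @return An object of class `km_estimate`: tibble with `time`, `n_risk`,
#'   `n_event`, `surv` (right-continuous step values after each time).
#'   `S(0) = 1`; with no events the curve stays at 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_arg("need at least one observation")
  if (any(time < 0)) stop_domain("negative survival times")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                surv = sf$surv)
  structure(out, class = c("km_estimate", class(out)))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A [km_estimate()].
#' @param at Numeric times.
#' @return Survival probabilities (right-continuous; 1 before the first
#'   event).
#' @export
km_survival_at <- function(km, at) {
  ev <- km[km$n_event > 0, ]
  vapply(at, function(t0) {
    i <- which(ev$time <= t0)
    if (!length(i)) 1 else ev$surv[max(i)]
  }, numeric(1))
}

#' @param object A `km_estimate`.
#' @param ... Unused.
#' @rdname km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- dplyr::bind_rows(tibble(time = 0, surv = 1),
                         tibble(time = object$time, surv = object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' DerSimonian-Laird random-effects meta-analysis of log hazard ratios
#'
#' Pools per-cohort effects on the log scale: fixed-effect weights
#' `w_i = 1/se_i^2`, heterogeneity `Q = sum(w_i (theta_i - theta_FE)^2)`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, random-effect
#' weights `1/(se_i^2 + tau^2)`, and a two-sided Wald p on the pooled
#' estimate. `I^2 = max(0, (Q - (k-1))/Q)`.
#'
#' @param effects A tibble with columns `log_hr` and `se` (e.g. rows of
#'   [cox_fit()] output), all finite, `se > 0`.
#' @return A one-row tibble of class `meta_result`: `k`, `pooled_log_hr`,
#'   `pooled_se`, `pooled_hr`, `ci_low`, `ci_high`, `pooled_p`, `tau2`, `Q`,
#'   `I2`.
#' @export
meta_random_effects <- function(effects) {
  if (is.numeric(effects)) stop_arg("`effects` must be a data frame with log_hr and se")
  stopifnot(all(c("log_hr", "se") %in% names(effects)))
  th <- effects$log_hr; se <- effects$se
  k <- length(th)
  if (k == 0) stop_arg("no effects to pool")
  if (any(!is.finite(th)) || any(!is.finite(se)) || any(se <= 0))
    stop_arg("all effects must be finite with positive se; filter non-converged fits first")
  w <- 1 / se^2
  theta_fe <- sum(w * th) / sum(w)
  Q <- sum(w * (th - theta_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * th) / sum(w_star)
  pooled_se <- sqrt(1 / sum(w_star))
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(
    tibble(
      k = k, pooled_log_hr = pooled, pooled_se = pooled_se,
      pooled_hr = exp(pooled),
      ci_low = exp(pooled - qnorm(0.975) * pooled_se),
      ci_high = exp(pooled + qnorm(0.975) * pooled_se),
      pooled_p = 2 * pnorm(-abs(pooled / pooled_se)),
      tau2 = tau2, Q = Q, I2 = i2
    ),
    class = c("meta_result", class(tibble())))
}

#' Dual-mode survival screen across cohorts
#'
#' For every requested gene and every cohort with at least `min_n` patients
#' (cohorts below the threshold are excluded before fitting), estimates the
#' univariate Cox effect in two modes and pools each mode across cohorts by
#' [meta_random_effects()]:
#'
#' * `binary`: the cohort's expression is dichotomized at the model-based
#'   cluster cutoff ([fit_gmm2()] + [dichotomize_cluster()]) and the effect
#'   is high vs low;
#' * `continuous`: the effect is per SD of [zscore_standardize()]d
#'   expression.
#'
#' Cohorts where a mode is not estimable (degenerate mixture, a group with
#' no samples, fewer than 2 events, non-converged fit) are dropped from that
#' mode's pool and recorded in the exclusion log.
#'
#' @param studies List of cohorts; each element needs `$expression`
#'   (an [expression_dataset()]) and `$clinical` (a clinical tibble).
#'   [simulate_study()] `$cohorts` works directly.
#' @param genes Character vector of genes to screen; default all genes
#'   present in the first cohort.
#' @param min_n Minimum cohort size (matched expression + clinical samples).
#' @param dichotomize Dichotomization used for the binary mode: `"cluster"`
#'   (default) or `"median"`.
#' @return A tibble with one row per gene and mode: pooled columns of
#'   [meta_random_effects()] plus `gene`, `mode`, and a `per_cohort`
#'   list-column of per-cohort effects. Attributes `exclusions` (tibble of
#'   cohort/gene/mode/reason) and `cohorts_used`.
#' @export
run_survival_screen <- function(studies, genes = NULL, min_n = 10,
                                dichotomize = c("cluster", "median")) {
  dichotomize <- match.arg(dichotomize)
  stopifnot(length(studies) >= 1)
  genes <- genes %||% rownames(studies[[1]]$expression$values)
  excl <- list()
  note_excl <- function(cohort, gene, mode, reason) {
    excl[[length(excl) + 1]] <<- tibble(cohort_id = cohort, gene = gene,
                                        mode = mode, reason = reason)
  }

  prepped <- purrr::map(studies, function(co) {
    ds <- co$expression
    common <- intersect(colnames(ds$values), co$clinical$sample_id)
    list(
      cohort_id = ds$cohort_id,
      expr = ds$values[, common, drop = FALSE],
      clinical = co$clinical[match(common, co$clinical$sample_id), ]
    )
  })
  small <- vapply(prepped, function(p) ncol(p$expr) < min_n, logical(1))
  for (p in prepped[small])
    note_excl(p$cohort_id, NA_character_, "both",
              sprintf("cohort size %d < min_n = %d", ncol(p$expr), min_n))
  prepped <- prepped[!small]
  if (!length(prepped)) stop_arg("no cohort meets min_n = %d", min_n)

  res <- purrr::map_dfr(genes, function(g) {
    effs <- purrr::map_dfr(prepped, function(p) {
      if (!g %in% rownames(p$expr)) {
        note_excl(p$cohort_id, g, "both", "gene absent")
        return(tibble())
      }
      x <- p$expr[g, ]
      out <- list()
      # binary mode
      bin <- tryCatch({
        lab <- if (dichotomize == "cluster") {
          dichotomize_cluster(x, fit_gmm2(x))
        } else {
          dichotomize_median(x)
        }
        hi <- as.integer(lab$label == "high")
        if (length(unique(hi)) < 2) stop_degenerate("one expression group is empty")
        cox_fit(p$clinical, list(high = hi),
                cohort_id = p$cohort_id, gene = g, mode = "binary")
      }, error = function(e) {
        note_excl(p$cohort_id, g, "binary", conditionMessage(e)); NULL
      })
      # continuous mode
      cont <- tryCatch({
        z <- zscore_standardize(x)
        cox_fit(p$clinical, list(expr_z = unname(z)),
                cohort_id = p$cohort_id, gene = g, mode = "continuous")
      }, error = function(e) {
        note_excl(p$cohort_id, g, "continuous", conditionMessage(e)); NULL
      })
      dplyr::bind_rows(bin, cont)
    })
    if (!nrow(effs)) {
      return(tibble(gene = g, mode = c("binary", "continuous"),
                    screened = FALSE, per_cohort = list(tibble(), tibble())))
    }
    purrr::map_dfr(c("binary", "continuous"), function(md) {
      sub <- effs[effs$mode == md & effs$converged & is.finite(effs$log_hr), ]
      nc <- effs[effs$mode == md & !(effs$converged & is.finite(effs$log_hr)), ]
      if (nrow(nc))
        for (i in seq_len(nrow(nc)))
          note_excl(nc$cohort_id[i], g, md, "non-converged fit")
      if (!nrow(sub))
        return(tibble(gene = g, mode = md, screened = FALSE,
                      per_cohort = list(effs[effs$mode == md, ])))
      pooled <- meta_random_effects(sub)
      dplyr::bind_cols(tibble(gene = g, mode = md, screened = TRUE), pooled) |>
        dplyr::mutate(per_cohort = list(sub))
    })
  })
  structure(res,
            exclusions = dplyr::bind_rows(excl),
            cohorts_used = vapply(prepped, `[[`, character(1), "cohort_id"))
}

#' Forest-style plot of a pooled survival screen row
#'
#' @param screen A [run_survival_screen()] result.
#' @param gene Gene to plot.
#' @param mode `"binary"` or `"continuous"`.
#' @return A ggplot object showing per-cohort hazard ratios with 95%
#'   intervals and the pooled estimate.
#' @export
plot_meta_forest <- function(screen, gene, mode = "binary") {
  row <- screen[screen$gene == gene & screen$mode == mode, ]
  if (!nrow(row) || !isTRUE(row$screened[1]))
    stop_arg("gene '%s' (%s mode) was not screened", gene, mode)
  eff <- row$per_cohort[[1]] |>
    dplyr::mutate(lo = exp(.data$log_hr - 1.96 * .data$se),
                  hi = exp(.data$log_hr + 1.96 * .data$se))
  pooled <- tibble(cohort_id = "pooled", hr = row$pooled_hr,
                   lo = row$ci_low, hi = row$ci_high)
  df <- dplyr::bind_rows(eff[, c("cohort_id", "hr", "lo", "hi")], pooled) |>
    dplyr::mutate(cohort_id = factor(.data$cohort_id,
                                     levels = rev(unique(.data$cohort_id))),
                  pooled = .data$cohort_id == "pooled")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$cohort_id,
                                   color = .data$pooled)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c("black", "firebrick"), guide = "none") +
    ggplot2::labs(x = "hazard ratio (log scale)", y = NULL,
                  title = sprintf("%s (%s mode)", gene, mode)) +
    ggplot2::theme_minimal()
}
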