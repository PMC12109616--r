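#' Dichotomize samples by a fitted mixture model
#'
#' Labels each sample by its maximum-posterior component under a
#' [fit_gmm2()] model. For equal variances the posterior-0.5 crossing has
#' the closed form `x* = (mu_low + mu_high)/2 + sigma^2 *
#' log((1 - pi)/pi) / (mu_high - mu_low)`, so maximum-posterior labeling is
#' exactly thresholding at `x*`.
#'
#' @param values Numeric vector to label. Named vectors keep their names as
#'   `sample_id`.
#' @param fit A non-degenerate `gmm2_fit` (`delta > 0`).
#' @return A tibble of class `dichotomy` with columns `sample_id`, `value`,
#'   `label` (factor `low`/`high`/`excluded`); the method and cutoff(s) are
#'   stored in attributes `method` and `cutoff`.
#' @export
dichotomize_cluster <- function(values, fit) {
  stopifnot(inherits(fit, "gmm2_fit"))
  if (!is.finite(fit$delta) || fit$delta <= 0)
    stop_degenerate("mixture fit is degenerate (delta = %g); no cluster cutoff exists", fit$delta)
  new_dichotomy(values, ifelse(values > fit$cutoff, "high", "low"),
                method = "cluster", cutoff = fit$cutoff)
}

#' Dichotomize samples at the median
#'
#' Labels `high` strictly above the median; ties at the median go `low`.
#'
#' @inheritParams dichotomize_cluster
#' @return A `dichotomy` tibble (see [dichotomize_cluster()]).
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2) stop_arg("need at least 2 values")
  m <- median(values)
  new_dichotomy(values, ifelse(values > m, "high", "low"),
                method = "median", cutoff = m)
}

#' Dichotomize samples by quantile bands
#'
#' Labels `high` strictly above the `hi_q` quantile and `low` strictly below
#' the `lo_q` quantile; the middle band is `excluded`. Quantiles use linear
#' interpolation between order statistics (type 7), so on 100 distinct
#' values the default 0.8 / 0.7 bands give exactly 20 high and 70 low.
#'
#' @inheritParams dichotomize_cluster
#' @param hi_q Upper quantile defining the high group.
#' @param lo_q Lower quantile defining the low group (`lo_q <= hi_q`).
#' @return A `dichotomy` tibble; attribute `cutoff` holds both band edges.
#' @export
dichotomize_quantile <- function(values, hi_q = 0.8, lo_q = 0.7) {
  if (!(lo_q >= 0 && hi_q <= 1 && lo_q <= hi_q))
    stop_arg("need 0 <= lo_q <= hi_q <= 1 (got lo_q = %g, hi_q = %g)", lo_q, hi_q)
  qs <- quantile(values, c(lo_q, hi_q), names = FALSE, type = 7)
  lab <- ifelse(values > qs[2], "high", ifelse(values < qs[1], "low", "excluded"))
  new_dichotomy(values, lab, method = "quantile",
                cutoff = c(low = qs[1], high = qs[2]))
}

new_dichotomy <- function(values, labels, method, cutoff) {
  out <- tibble(
    sample_id = names(values) %||% as.character(seq_along(values)),
    value = unname(values),
    label = factor(labels, levels = c("low", "high", "excluded"))
  )
  structure(out, method = method, cutoff = cutoff,
            class = c("dichotomy", class(out)))
}

#' Z-score standardize a vector
#'
#' Centers to mean 0 and scales to SD 1 (denominator n - 1); the continuous
#' analysis mode of the survival screen uses this so hazard ratios are per
#' SD of expression and comparable across cohorts.
#'
#' @param values Numeric vector with at least 2 values and nonzero SD.
#' @return Numeric vector of the same length (names preserved).
#' @export
zscore_standardize <- function(values) {
  if (length(values) < 2) stop_arg("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop_degenerate("zero variance; z-score undefined")
  (values - mean(values)) / s
}

#' Screen all genes of a dataset for bimodal expression
#'
#' Fits the equal-variance two-component mixture to every gene and ranks
#' genes by bimodal index. Genes with (near-)zero variance are flagged
#' `degenerate` and left unranked rather than dropped, so output rows align
#' with the input gene list.
#'
#' @param ds An [expression_dataset()], preprocessed.
#' @param min_bi Minimum bimodal index for the `pass_min_bi` flag.
#' @param ... Passed to [fit_gmm2()] (tolerance, starts, ...).
#' @return A tibble with one row per gene: `gene`, `mu_low`, `mu_high`,
#'   `sigma`, `pi`, `delta`, `bi`, `cutoff`, `converged`, `degenerate`,
#'   `rank` (by descending `bi`; `NA` for degenerate genes), `pass_min_bi`;
#'   sorted by `bi` descending.
#' @export
screen_bimodal_genes <- function(ds, min_bi = 1.1, ...) {
  stopifnot(inherits(ds, "expr_dataset"))
  rows <- purrr::map(rownames(ds$values), function(g) {
    x <- ds$values[g, ]
    fit <- tryCatch(fit_gmm2(x, ...), error = function(e) NULL)
    if (is.null(fit)) {
      tibble(gene = g, mu_low = NA_real_, mu_high = NA_real_, sigma = NA_real_,
             pi = NA_real_, delta = NA_real_, bi = NA_real_, cutoff = NA_real_,
             converged = NA, degenerate = TRUE)
    } else {
      tibble(gene = g, mu_low = fit$mu_low, mu_high = fit$mu_high,
             sigma = fit$sigma, pi = fit$pi, delta = fit$delta, bi = fit$bi,
             cutoff = fit$cutoff, converged = fit$converged, degenerate = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$bi)) |>
    dplyr::mutate(
      rank = ifelse(.data$degenerate, NA_integer_, cumsum(!.data$degenerate)),
      pass_min_bi = !.data$degenerate & .data$bi >= min_bi
    )
  out
}
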