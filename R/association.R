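#' Genome-wide Pearson correlation screen against a target gene
#'
#' Correlates the target gene's expression with every other gene, overall
#' or within strata (e.g. genotype subgroups), with two-sided p-values from
#' the exact t transform (`t = r sqrt((n-2)/(1-r^2))`, n-2 df) and BH
#' adjustment within each stratum. The target itself is excluded;
#' zero-variance genes are reported with a missing `r` and `flagged =
#' TRUE` rather than dropped.
#'
#' @param ds An [expression_dataset()].
#' @param target Target gene name.
#' @param strata Optional named list of sample-id vectors defining strata;
#'   default a single stratum `"all"` with every sample. Strata with fewer
#'   than 3 samples are skipped with a notice.
#' @return A tibble of `CorrelationRecord`s: `feature`, `group`, `r`, `p`,
#'   `p_adj`, `n`, `flagged`.
#' @export
correlation_screen <- function(ds, target, strata = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!target %in% rownames(ds$values))
    stop_arg("target gene '%s' absent from dataset", target)
  strata <- strata %||% list(all = colnames(ds$values))
  purrr::imap_dfr(strata, function(ids, grp) {
    ids <- intersect(ids, colnames(ds$values))
    if (length(ids) < 3) {
      inform(sprintf("stratum '%s' has %d samples (< 3); skipped", grp, length(ids)))
      return(tibble())
    }
    m <- ds$values[setdiff(rownames(ds$values), target), ids, drop = FALSE]
    x <- ds$values[target, ids]
    n <- length(ids)
    sds <- apply(m, 1, sd)
    ok <- is.finite(sds) & sds > 0 & sd(x) > 0
    r <- rep(NA_real_, nrow(m))
    if (any(ok)) r[ok] <- as.numeric(cor(t(m[ok, , drop = FALSE]), x))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p_adj <- rep(NA_real_, length(p))
    p_adj[ok] <- bh_adjust(p[ok])
    tibble(feature = rownames(m), group = grp, r = r, p = p, p_adj = p_adj,
           n = n, flagged = !ok)
  })
}

#' Within-group Pearson correlation after dichotomization
#'
#' Biphasic association probe: correlates `x` and `y` separately inside the
#' low and high groups of a dichotomy (excluded samples are dropped), the
#' pattern used to ask whether a covariate tracks the target only below or
#' only above the expression cutoff.
#'
#' @param x,y Numeric vectors, aligned with `labels` rows.
#' @param labels A `dichotomy` tibble (see [dichotomize_cluster()]).
#' @return One `CorrelationRecord` row per group with at least 3 samples:
#'   `group`, `r`, `p`, `n`. Smaller groups are skipped with a notice.
#' @export
within_group_correlation <- function(x, y, labels) {
  stopifnot(inherits(labels, "dichotomy"),
            length(x) == nrow(labels), length(y) == nrow(labels))
  purrr::map_dfr(c("low", "high"), function(grp) {
    idx <- labels$label == grp
    if (sum(idx) == 0) return(tibble())
    if (sum(idx) < 3) {
      inform(sprintf("group '%s' has %d samples (< 3); skipped", grp, sum(idx)))
      return(tibble())
    }
    ct <- stats::cor.test(x[idx], y[idx], method = "pearson")
    tibble(group = grp, r = unname(ct$estimate), p = ct$p.value, n = sum(idx))
  })
}

#' One-way ANOVA across genotype groups
#'
#' Standard one-way F test (pooled within-group variance) of a numeric
#' response across groups, e.g. a metabolite across the four-way
#' KEAP1/STK11 oncogenotype partition.
#'
#' @param values Numeric response.
#' @param groups Grouping vector/factor; at least 2 groups with at least 2
#'   observations each.
#' @return A tibble: `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop_arg("need at least 2 groups")
  if (any(table(g) < 2)) stop_arg("each group needs at least 2 observations")
  ft <- oneway.test(values ~ g, var.equal = TRUE)
  tibble(F = unname(ft$statistic), p = ft$p.value,
         df_between = unname(ft$parameter[1]),
         df_within = unname(ft$parameter[2]))
}

#' Multivariate metabolite model adjusting for genotype
#'
#' Ordinary least squares `metabolite ~ kynu_status + keap1 + stk11`; the
#' target-expression-status term is the headline effect, with the two
#' mutation terms as adjustment covariates. This asks whether the
#' metabolite tracks target expression beyond what genotype explains.
#'
#' @param metabolite Numeric response.
#' @param kynu_status Binary (0/1 or logical) target-expression status
#'   (high = 1).
#' @param keap1,stk11 Binary mutation indicators.
#' @return A tibble of class `model_fit_record`, one row per model term:
#'   `term`, `estimate`, `se`, `p`; attributes `n`, `r_squared`, and
#'   `headline` (the `kynu_status` row as a one-row tibble).
#' @export
metabolite_multivariate <- function(metabolite, kynu_status, keap1, stk11) {
  df <- data.frame(metabolite = metabolite,
                   kynu_status = as.numeric(kynu_status),
                   keap1 = as.numeric(keap1), stk11 = as.numeric(stk11))
  df <- df[complete.cases(df), ]
  if (nrow(df) <= 5) stop_arg("need more than 5 complete observations")
  fit <- lm(metabolite ~ kynu_status + keap1 + stk11, data = df)
  if (anyNA(coef(fit)))
    stop_degenerate("rank-deficient design: term(s) %s not estimable",
                    paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)
  out <- tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    p = sm$coefficients[, "Pr(>|t|)"]
  )
  structure(out,
            n = nrow(df), r_squared = sm$r.squared,
            headline = out[out$term == "kynu_status", ],
            class = c("model_fit_record", class(tibble())))
}

#' @param x A `model_fit_record`.
#' @param ... Unused.
#' @rdname metabolite_multivariate
#' @export
glance.model_fit_record <- function(x, ...) {
  hl <- attr(x, "headline")
  tibble(n = attr(x, "n"), r_squared = attr(x, "r_squared"),
         kynu_estimate = hl$estimate, kynu_p = hl$p)
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap `k` between a
#' hit list and each gene set, against a stated universe; sets are
#' intersected with the universe before testing and BH-adjusted across the
#' tested sets. Hits outside the universe are dropped with a warning; sets
#' disjoint from the universe are skipped with a notice.
#'
#' @param hits Character vector of hit genes.
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: the gene universe (non-empty).
#' @return A tibble of `EnrichmentRecord`s: `set_name`, `overlap`,
#'   `set_size` (within universe), `n_hits`, `universe_size`, `p`, `p_adj`,
#'   sorted by `p`.
#' @export
hypergeom_enrichment <- function(hits, sets, universe) {
  if (!length(universe)) stop_arg("empty universe")
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    warn(sprintf("%d hit gene(s) outside the universe dropped", length(outside)))
    hits <- intersect(hits, universe)
  }
  n_h <- length(hits); N <- length(universe)
  rows <- purrr::imap_dfr(as.list(sets), function(members, nm) {
    k_set <- intersect(members, universe)
    if (!length(k_set)) {
      inform(sprintf("gene set '%s' is disjoint from the universe; skipped", nm))
      return(tibble())
    }
    K <- length(k_set)
    k <- length(intersect(k_set, hits))
    tibble(set_name = nm, overlap = k, set_size = K, n_hits = n_h,
           universe_size = N,
           p = phyper(k - 1, K, N - K, n_h, lower.tail = FALSE))
  })
  if (nrow(rows)) rows$p_adj <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p)
}

#' Intersect significant features across cohorts
#'
#' Cross-cohort consistency rule: keep features whose (adjusted) p-value is
#' below `alpha` in every cohort's record table. Sign concordance is not
#' required.
#'
#' @param records List of tibbles each with columns `feature` and `p_adj`
#'   (or `p` when `adjusted = FALSE`).
#' @param alpha Significance threshold.
#' @param adjusted Use `p_adj` (default) or nominal `p`.
#' @return Character vector of features significant in all cohorts.
#' @export
intersect_significant <- function(records, alpha = 0.05, adjusted = TRUE) {
  col <- if (adjusted) "p_adj" else "p"
  sig <- purrr::map(records, function(tbl) {
    stopifnot(all(c("feature", col) %in% names(tbl)))
    tbl$feature[!is.na(tbl[[col]]) & tbl[[col]] < alpha]
  })
  Reduce(intersect, sig)
}
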