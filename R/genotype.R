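#' Call tumor-suppressor functional-loss status from multi-modal evidence
#'
#' A sample is called "loss" for a gene if any available evidence source
#' says so: (a) a retained (non-excluded-class) mutation record, (b) a copy
#' number below `cn_loss_threshold`, (c) the gene at a fusion/translocation
#' breakpoint, (d) a protein (RPPA) level below the model-based cluster
#' cutoff of the protein distribution (equal-variance mixture fit), or
#' (e) a pre-classified external loss call. Evidence is combined by union;
#' adding a source can never revoke a loss call. Sources are optional —
#' mutation-only calling is a supported mode.
#'
#' @param samples Character vector: the full sample universe to call.
#' @param genes Genes to call status for (default KEAP1 and STK11).
#' @param mutations Optional mutation tibble (`sample_id`, `gene`, ...),
#'   already class-filtered (see [filter_mutations()]).
#' @param cn Optional copy-number tibble: `sample_id`, `gene`, `cn`.
#' @param fusions Optional tibble of breakpoint genes: `sample_id`, `gene`.
#' @param rppa Optional protein-level tibble: `sample_id`, `gene`, `level`.
#'   If the mixture fit on a gene's levels is degenerate, RPPA evidence for
#'   that gene is skipped with a warning and other evidence still applies.
#' @param external_calls Optional pre-classified loss calls: `sample_id`,
#'   `gene` (e.g. portal-style alteration tables mapped upstream).
#' @param cn_loss_threshold Copy-number value strictly below which a loss is
#'   called.
#' @return A tibble with one row per sample x gene: `sample_id`, `gene`,
#'   `loss` (logical), `evidence` (list-column of character vectors drawn
#'   from mutation/copy_number/fusion/rppa/external_call; empty iff not
#'   loss).
#' @export
call_tsg_status <- function(samples, genes = c("KEAP1", "STK11"),
                            mutations = NULL, cn = NULL, fusions = NULL,
                            rppa = NULL, external_calls = NULL,
                            cn_loss_threshold = -1) {
  if (is.null(mutations) && is.null(cn) && is.null(fusions) &&
      is.null(rppa) && is.null(external_calls))
    stop_arg("at least one evidence source must be provided")
  samples <- as.character(samples)
  ev <- list()
  add_ev <- function(sample_id, gene, source) {
    if (!length(sample_id)) return()
    ev[[length(ev) + 1]] <<- tibble(sample_id = as.character(sample_id),
                                    gene = gene, source = source)
  }
  for (g in genes) {
    if (!is.null(mutations)) {
      hit <- unique(mutations$sample_id[mutations$gene == g])
      add_ev(intersect(hit, samples), g, "mutation")
    }
    if (!is.null(cn)) {
      sub <- cn[cn$gene == g & cn$cn < cn_loss_threshold, ]
      add_ev(intersect(unique(sub$sample_id), samples), g, "copy_number")
    }
    if (!is.null(fusions)) {
      hit <- unique(fusions$sample_id[fusions$gene == g])
      add_ev(intersect(hit, samples), g, "fusion")
    }
    if (!is.null(rppa)) {
      sub <- rppa[rppa$gene == g & rppa$sample_id %in% samples, ]
      if (nrow(sub)) {
        cut <- tryCatch({
          fit <- fit_gmm2(sub$level)
          if (!is.finite(fit$delta) || fit$delta <= 0)
            stop_degenerate("degenerate protein mixture")
          fit$cutoff
        }, error = function(e) {
          warn(sprintf("RPPA clustering for %s failed (%s); RPPA evidence skipped",
                       g, conditionMessage(e)))
          NA_real_
        })
        if (is.finite(cut))
          add_ev(unique(sub$sample_id[sub$level < cut]), g, "rppa")
      }
    }
    if (!is.null(external_calls)) {
      hit <- unique(external_calls$sample_id[external_calls$gene == g])
      add_ev(intersect(hit, samples), g, "external_call")
    }
  }
  ev_tbl <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble(sample_id = character(), gene = character(), source = character())
  grid <- tidyr::expand_grid(sample_id = samples, gene = genes)
  grid$evidence <- purrr::map2(grid$sample_id, grid$gene, function(s, g) {
    sort(unique(ev_tbl$source[ev_tbl$sample_id == s & ev_tbl$gene == g]))
  })
  grid$loss <- lengths(grid$evidence) > 0
  grid[, c("sample_id", "gene", "loss", "evidence")]
}

#' Assign four-way oncogenotype groups from KEAP1/STK11 loss status
#'
#' @param status A [call_tsg_status()] result covering both genes for every
#'   sample.
#' @return A tibble `sample_id`, `group` with `group` a factor in
#'   `WT`, `KEAP1_only`, `STK11_only`, `double` — a partition, exactly one
#'   group per sample.
#' @export
assign_genotype_group <- function(status) {
  wide <- status |>
    dplyr::select("sample_id", "gene", "loss") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "loss")
  if (!all(c("KEAP1", "STK11") %in% names(wide)))
    stop_arg("status table must cover both KEAP1 and STK11")
  if (anyNA(wide$KEAP1) || anyNA(wide$STK11))
    stop_arg("status table must cover both genes for every sample")
  tibble(
    sample_id = wide$sample_id,
    group = factor(
      dplyr::case_when(
        wide$KEAP1 & wide$STK11 ~ "double",
        wide$KEAP1 ~ "KEAP1_only",
        wide$STK11 ~ "STK11_only",
        TRUE ~ "WT"
      ),
      levels = c("WT", "KEAP1_only", "STK11_only", "double")
    )
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of two independent samples. When
#' `n_a * n_b <= 400` and there are no cross-group ties the p-value is
#' exact (null distribution of U enumerated); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. `U` counts pairs where `a > b` (ties count 1/2).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A tibble: `U`, `p`, `method` (`"exact"` or `"normal"`), `n_a`,
#'   `n_b`.
#' @export
mwu_test <- function(a, b) {
  if (!length(a) || !length(b)) stop_arg("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n_a * n_b <= 400) {
    lo <- min(u, n_a * n_b - u)
    hi <- max(u, n_a * n_b - u)
    p <- pwilcox(lo, n_a, n_b) + pwilcox(hi - 1, n_a, n_b, lower.tail = FALSE)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(r)
    n <- n_a + n_b
    v <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- max(0, abs(u - mu) - 0.5) / sqrt(v)
    p <- 2 * pnorm(-z)
    method <- "normal"
  }
  tibble(U = u, p = min(p, 1), method = method, n_a = n_a, n_b = n_b)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; thin validation wrapper over
#' `p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_domain("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Screen candidate driver genes for association with target expression
#'
#' For every candidate gene mutated in at least `min_mut` samples, compares
#' target-gene expression between mutant and wild-type samples by
#' [mwu_test()]; p-values are BH-adjusted across the tested genes only.
#' Candidates below the mutant-count gate are reported `tested = FALSE`
#' rather than dropped. Both nominal and adjusted p-values are always
#' reported; nothing is filtered on significance.
#'
#' @param ds An [expression_dataset()] containing the target gene.
#' @param target Target gene name.
#' @param mutations Mutation tibble (already class-filtered).
#' @param candidate_genes Genes to screen (e.g. a cancer gene census list).
#' @param min_mut Minimum number of mutant samples required to test.
#' @return A tibble of class `screen_hits`, one row per candidate:
#'   `gene`, `n_mut`, `n_wt`, `tested`, `U`, `p`, `p_adj`, `direction`
#'   (sign of mutant-minus-wild-type median difference), sorted by `p`.
#' @export
oncogenotype_screen <- function(ds, target, mutations, candidate_genes,
                                min_mut = 9) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!target %in% rownames(ds$values))
    stop_arg("target gene '%s' absent from dataset", target)
  x <- ds$values[target, ]
  samples <- colnames(ds$values)
  rows <- purrr::map_dfr(unique(candidate_genes), function(g) {
    mut_samples <- intersect(unique(mutations$sample_id[mutations$gene == g]), samples)
    wt_samples <- setdiff(samples, mut_samples)
    n_mut <- length(mut_samples); n_wt <- length(wt_samples)
    if (n_mut < min_mut || n_wt == 0) {
      return(tibble(gene = g, n_mut = n_mut, n_wt = n_wt, tested = FALSE,
                    U = NA_real_, p = NA_real_, direction = NA_real_))
    }
    tst <- mwu_test(x[mut_samples], x[wt_samples])
    tibble(gene = g, n_mut = n_mut, n_wt = n_wt, tested = TRUE,
           U = tst$U, p = tst$p,
           direction = sign(median(x[mut_samples]) - median(x[wt_samples])))
  })
  rows$p_adj <- NA_real_
  if (any(rows$tested)) rows$p_adj[rows$tested] <- bh_adjust(rows$p[rows$tested])
  out <- dplyr::arrange(rows, dplyr::desc(.data$tested), .data$p)
  structure(out[, c("gene", "n_mut", "n_wt", "tested", "U", "p", "p_adj",
                    "direction")],
            class = c("screen_hits", class(tibble())))
}
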