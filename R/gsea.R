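#' Signal-to-noise gene ranking between two phenotype classes
#'
#' Per gene, `(mu_A - mu_B) / (sd_A + sd_B)` where A is the first level of
#' `labels` and each class SD is floored at `max(sd, 0.2 * |mean|, 0.2)` —
#' the classic enrichment-analysis convention that keeps near-constant
#' genes from dominating the ranking. Genes are sorted by metric descending
#' with a stable gene-id tie-break.
#'
#' @param ds An [expression_dataset()].
#' @param labels Two-level phenotype vector aligned with the dataset's
#'   samples; each class needs at least 3 samples.
#' @return A tibble of class `ranked_list`: `gene`, `metric`, `position`,
#'   ordered by metric descending.
#' @export
signal_to_noise <- function(ds, labels) {
  stopifnot(inherits(ds, "expr_dataset"))
  g <- droplevels(factor(labels))
  if (nlevels(g) != 2) stop_arg("`labels` must have exactly two classes")
  if (any(table(g) < 3)) stop_arg("each class needs at least 3 samples")
  m <- ds$values
  ranked <- rank_s2n(m, g == levels(g)[1])
  structure(ranked, class = c("ranked_list", class(ranked)))
}

# vectorized signal-to-noise over the rows of m; a_mask marks class A
rank_s2n <- function(m, a_mask) {
  s2n <- s2n_metric(m, a_mask)
  ord <- order(-s2n, rownames(m), method = "radix")
  tibble(gene = rownames(m)[ord], metric = unname(s2n[ord]),
         position = seq_along(s2n))
}

s2n_metric <- function(m, a_mask) {
  a <- m[, a_mask, drop = FALSE]
  b <- m[, !a_mask, drop = FALSE]
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- sqrt(rowSums((a - mu_a)^2) / (ncol(a) - 1))
  sd_b <- sqrt(rowSums((b - mu_b)^2) / (ncol(b) - 1))
  sd_a <- pmax(sd_a, 0.2 * abs(mu_a), 0.2)
  sd_b <- pmax(sd_b, 0.2 * abs(mu_b), 0.2)
  (mu_a - mu_b) / (sd_a + sd_b)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom; set members ("hits") add
#' `|metric|^weight / sum_hits |metric|^weight`, non-members subtract
#' `1 / (N - N_hits)`. The enrichment score is the maximum-magnitude
#' deviation of this running sum, and the leading edge contains the set
#' members at or before the extremum (at or after it, for negative ES).
#'
#' @param ranked A [signal_to_noise()] result (or any tibble with `gene`
#'   and `metric` in ranked order).
#' @param geneset Character vector of member genes.
#' @param weight Exponent on `|metric|` for hit increments (1 = classic
#'   weighted score).
#' @return A list: `es`, `leading_edge` (character vector), `running_sum`
#'   (tibble `position`, `gene`, `running` for plotting).
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% geneset
  n_h <- sum(hit)
  if (n_h == 0 || n_h == N)
    stop_arg("gene set must hit a non-empty proper subset of the universe (hits = %d of %d)",
             n_h, N)
  rs <- running_sum_stat(ranked$metric, hit, weight)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  leading <- if (es >= 0) genes[seq_len(i_ext)][hit[seq_len(i_ext)]]
             else genes[i_ext:N][hit[i_ext:N]]
  list(es = es, leading_edge = leading,
       running_sum = tibble(position = seq_len(N), gene = genes, running = rs))
}

running_sum_stat <- function(metric, hit, weight) {
  N <- length(metric)
  n_h <- sum(hit)
  w <- abs(metric[hit])^weight
  tot <- sum(w)
  inc <- numeric(N)
  if (tot > 0) {
    inc[hit] <- w / tot
  } else {
    inc[hit] <- 1 / n_h # all-zero metrics: fall back to unweighted hits
  }
  inc[!hit] <- -1 / (N - n_h)
  cumsum(inc)
}

# ES only, skipping bookkeeping; used in the permutation loop
es_only <- function(metric, hit, weight) {
  rs <- running_sum_stat(metric, hit, weight)
  rs[which.max(abs(rs))]
}

#' Gene set enrichment analysis with sample-label permutation
#'
#' Computes the observed enrichment score of each set on the
#' signal-to-noise ranking, then permutes the phenotype labels `n_perm`
#' times (labels are permuted, never resampled, so no class can empty) and
#' estimates, per set, a same-sign nominal p with an add-one correction:
#' `p = (1 + #{perm ES at least as extreme, same sign}) /
#' (1 + #{perm ES of the same sign})`, never exactly zero. `NES` normalizes
#' the observed ES by the mean magnitude of same-sign permutation scores.
#'
#' @param ds An [expression_dataset()].
#' @param labels Two-level phenotype vector aligned with samples.
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Seed making the permutation stream reproducible.
#' @param weight Running-sum weight (see [enrichment_score()]).
#' @param min_size,max_size Set-size bounds after universe intersection;
#'   sets outside the bounds are skipped.
#' @return A tibble of class `gsea_result`: `set_name`, `size`, `es`,
#'   `nes`, `p_nominal`, `leading_edge` (list-column), `n_perm`, `seed`,
#'   sorted by `p_nominal`.
#' @export
gsea_permutation <- function(ds, labels, sets, n_perm = 1000, seed = 1L,
                             weight = 1, min_size = 5, max_size = 500) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(sets, "gene_set_collection"))
  if (n_perm < 100) stop_arg("`n_perm` must be at least 100")
  g <- droplevels(factor(labels))
  if (nlevels(g) != 2) stop_arg("`labels` must have exactly two classes")
  if (any(table(g) < 3)) stop_arg("each class needs at least 3 samples")
  m <- ds$values
  universe <- rownames(m)
  kept <- purrr::keep(as.list(sets), function(s) {
    sz <- length(intersect(s, universe))
    sz >= min_size && sz <= max_size && sz < length(universe)
  })
  if (!length(kept)) stop_arg("no gene set within size bounds [%d, %d]", min_size, max_size)

  a_mask <- g == levels(g)[1]
  obs_rank <- rank_s2n(m, a_mask)
  hit_masks <- lapply(kept, function(s) obs_rank$gene %in% s)
  obs <- purrr::map2(kept, hit_masks, function(s, h) {
    es <- enrichment_score(obs_rank, s, weight)
    list(es = es$es, leading = es$leading_edge, size = sum(h))
  })

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_sets <- length(kept)
  perm_es <- matrix(NA_real_, nrow = n_perm, ncol = n_sets)
  # reuse the hit masks: permuting labels changes metrics, hence the order,
  # so masks must be recomputed against each permuted ranking
  member_sets <- lapply(kept, function(s) intersect(s, universe))
  for (b in seq_len(n_perm)) {
    mask_b <- sample(a_mask)
    s2n_b <- s2n_metric(m, mask_b)
    ord <- order(-s2n_b, universe, method = "radix")
    metric_b <- s2n_b[ord]
    genes_b <- universe[ord]
    for (j in seq_len(n_sets)) {
      perm_es[b, j] <- es_only(metric_b, genes_b %in% member_sets[[j]], weight)
    }
  }

  rows <- purrr::imap_dfr(obs, function(o, nm) {
    j <- match(nm, names(obs))
    same_sign <- if (o$es >= 0) perm_es[, j] >= 0 else perm_es[, j] < 0
    extreme <- abs(perm_es[, j]) >= abs(o$es) & same_sign
    p <- (1 + sum(extreme)) / (1 + sum(same_sign))
    denom <- mean(abs(perm_es[same_sign, j]))
    tibble(set_name = nm, size = o$size, es = o$es,
           nes = if (is.finite(denom) && denom > 0) o$es / denom else NA_real_,
           p_nominal = p, leading_edge = list(o$leading),
           n_perm = n_perm, seed = as.integer(seed))
  })
  structure(dplyr::arrange(rows, .data$p_nominal),
            class = c("gsea_result", class(tibble())))
}

#' Genes recurring across leading-edge lists
#'
#' Cross-result consistency utility: counts how often each gene appears in
#' the given leading-edge lists and returns those appearing at least
#' `min_count` times (default 2, i.e. "multiple" lists).
#'
#' @param leading_edges List of character vectors (e.g. the
#'   `leading_edge` column of one or more [gsea_permutation()] results).
#' @param min_count Minimum number of lists a gene must appear in.
#' @return A tibble `gene`, `n_lists`, sorted by `n_lists` descending.
#' @export
leading_edge_recurrence <- function(leading_edges, min_count = 2) {
  counts <- table(unlist(lapply(leading_edges, unique)))
  out <- tibble(gene = names(counts), n_lists = as.integer(counts)) |>
    dplyr::filter(.data$n_lists >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n_lists), .data$gene)
  out
}
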