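# shared fixture builders; everything is generated in code at test time

toy_expression <- function(genes = c("g1", "g2"), samples = c("s1", "s2", "s3"),
                           values = NULL, cohort_id = "toy") {
  if (is.null(values)) {
    values <- matrix(seq_len(length(genes) * length(samples)),
                     nrow = length(genes))
  }
  dimnames(values) <- list(genes, samples)
  expression_dataset(values, cohort_id)
}

# mixture draw with a fixed seed, restoring RNG state afterwards
mixture_sample <- function(n, mu1 = 0, mu2 = 3, sigma = 1, pi_high = 0.3,
                           seed = 1) {
  withr::with_seed(seed, {
    z <- rbinom(n, 1, pi_high)
    mu1 + z * (mu2 - mu1) + rnorm(n, 0, sigma)
  })
}

# Efron-approximation Cox partial log-likelihood for one covariate;
# independent oracle used against the Newton fit
efron_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    d_set <- which(time == t0 & event == 1)
    r_set <- which(time >= t0)
    d <- length(d_set)
    sum_r <- sum(exp(beta * x[r_set]))
    sum_d <- sum(exp(beta * x[d_set]))
    ll <- ll + beta * sum(x[d_set])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

# brute-force running-sum enrichment score, O(N * N_hit) and deliberately
# naive: recompute the hit-weight total and walk the list one gene at a time
brute_force_es <- function(genes, metric, geneset, weight = 1) {
  N <- length(genes)
  is_hit <- vapply(genes, function(g) g %in% geneset, logical(1))
  total_w <- 0
  for (i in seq_len(N)) if (is_hit[i]) total_w <- total_w + abs(metric[i])^weight
  n_hit <- sum(is_hit)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      acc <- acc + (if (total_w > 0) abs(metric[i])^weight / total_w else 1 / n_hit)
    } else {
      acc <- acc - 1 / (N - n_hit)
    }
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# phenotype-labeled random dataset, optionally with shifted genes in class "high"
make_phenotype_ds <- function(n_genes = 30, n_per_class = 10, shift_genes = NULL,
                              shift = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    vals <- matrix(rnorm(n_genes * n), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(n))))
    labels <- rep(c("high", "low"), each = n_per_class)
    if (length(shift_genes))
      vals[shift_genes, labels == "high"] <-
        vals[shift_genes, labels == "high"] + shift
    list(ds = expression_dataset(vals, "c1"), labels = labels)
  })
}
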