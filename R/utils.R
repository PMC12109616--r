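#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats dnorm quantile median sd var cor pt pnorm qnorm phyper
#'   p.adjust rnorm rbinom rexp runif lm oneway.test complete.cases
#'   setNames coef vcov dwilcox pwilcox
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib bimodalsurv, .registration = TRUE
NULL

# deterministic 32-bit substream seed: cohorts/stages draw from independent
# streams derived from one master seed, so any subset regenerates identically
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  # two rounds of a multiplicative congruential mix keyed by the index
  s <- (s * 48271) %% m
  s <- (s + (index + 1) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}

stop_format <- function(msg, ...) abort(sprintf(msg, ...), class = "bimodalsurv_format_error")
stop_domain <- function(msg, ...) abort(sprintf(msg, ...), class = "bimodalsurv_domain_error")
stop_degenerate <- function(msg, ...) abort(sprintf(msg, ...), class = "bimodalsurv_degenerate_error")
stop_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "bimodalsurv_argument_error")

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop_arg("`%s` must be a probability in [0, 1]", name)
  invisible(x)
}
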