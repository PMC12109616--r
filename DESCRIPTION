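Package: bimodalsurv
Title: Bimodal Biomarker Discovery with Mixture-Model Dichotomization and
    Survival Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bimodally expressed genes in multi-cohort tumor
    expression studies with an equal-variance two-component Gaussian
    mixture and the bimodal index, dichotomizes samples at the
    model-based posterior cutoff (or by median or quantile bands),
    estimates per-cohort Cox proportional-hazard effects in binary and
    continuous modes, and pools them by DerSimonian-Laird random-effects
    meta-analysis. Downstream screens cover oncogenotype association
    (Mann-Whitney with a minimum-mutant gate and Benjamini-Hochberg
    adjustment), tumor-suppressor loss calling from multi-modal evidence,
    genome-wide and within-group Pearson correlation, metabolite
    multivariate models, hypergeometric pathway over-representation, and
    gene set enrichment analysis with signal-to-noise ranking and
    sample-label permutation. A synthetic-study generator reproduces the
    statistical structure these analyses assume, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
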