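# bimodalsurv

Bimodal biomarker discovery for multi-cohort tumor expression studies:
equal-variance Gaussian-mixture detection of bimodally expressed genes,
model-based dichotomization, dual-mode Cox survival estimation per cohort,
and DerSimonian–Laird random-effects pooling — plus the downstream
oncogenotype, correlation, metabolite, and gene-set analyses that turn a
bimodal gene into a biological story.

## Who this is for

Computational biologists and biostatisticians screening tumor
transcriptomes (e.g. lung adenocarcinoma compendia) for genes whose
expression splits patients into discrete high/low modes — the signature of
oncogenotype-driven reprogramming, as with *KYNU* downstream of
KEAP1/STK11 loss — and asking whether that split carries prognostic or
metabolic consequences.

## The model

A candidate gene is modeled as a two-component Gaussian mixture with
common variance, `x ~ (1−π)·N(μ₁, σ²) + π·N(μ₂, σ²)` with `μ₁ ≤ μ₂`,
fitted by EM (`fit_gmm2()`). Genes are ranked by the **bimodal index**

    BI = δ·√(π(1−π)),   δ = (μ₂ − μ₁)/σ,

and patients are dichotomized at the posterior-0.5 crossing, which for
equal variances has the closed form
`x* = (μ₁+μ₂)/2 + σ²·ln((1−π)/π)/(μ₂−μ₁)`. Per cohort, Cox models
estimate the hazard of the high group (binary mode) and of z-scored
expression (continuous mode); cohorts with ≥ 10 patients are pooled on the
log-HR scale by DerSimonian–Laird random effects with Q, τ², and I²
heterogeneity summaries. Downstream: Mann–Whitney oncogenotype screening
(≥ 9 mutants, BH adjustment), multi-evidence KEAP1/STK11 loss calling
(mutation / copy number < −1 / fusion breakpoint / RPPA mixture cutoff),
Pearson correlation screens, OLS metabolite models adjusting for genotype,
hypergeometric pathway over-representation, and permutation GSEA with
signal-to-noise ranking.

A seeded synthetic-study generator (`synthetic_config()`,
`simulate_study()`) reproduces the statistical structure all of this
assumes — mixture expression, component-dependent hazards, mutation
enrichment, metabolite coupling — so the full pipeline runs and is tested
without any external downloads.

## Worked example

```r
library(bimodalsurv)

cfg   <- synthetic_config(seed = 7)   # 5 cohorts, bimodal KYNU among 200 null genes
study <- simulate_study(cfg)
disc  <- study$cohorts[[1]]           # 500-patient discovery cohort

fit_gmm2(disc$expression$values["KYNU", ])
#> <gmm2_fit> n = 500
#>   mu_low = 3.964, mu_high = 7.122, sigma = 0.9514, pi(high) = 0.3042
#>   delta = 3.319, BI = 1.527, cutoff = 5.78
```

The fit recovers the generative truth (μ = 4 and 7, σ = 1, π = 0.3); the
cutoff 5.78 sits between the modes, slightly above the midpoint because
the high component is the rarer one. Screening all 201 genes ranks the
target first, with the best null gene far behind:

```r
head(screen_bimodal_genes(disc$expression), 3)
#>   gene         pi delta    bi cutoff
#> 1 KYNU      0.304  3.32 1.53    5.78
#> 2 NULLG0002 0.484  1.94 0.970   4.97
#> 3 NULLG0095 0.455  1.88 0.935   5.08

run_survival_screen(study$cohorts, genes = "KYNU")
#>   gene       mode k pooled_hr ci_low ci_high     pooled_p   tau2   I2
#> 1 KYNU     binary 5      1.77   1.42    2.19      2.2e-07  0.027 0.46
#> 2 KYNU continuous 5      1.30   1.17    1.44      9.0e-07  0.007 0.48
```

The pooled binary-mode hazard ratio of 1.77 (true component HR: 2) says
high-mode patients die ~1.8× faster; the continuous mode gives the hazard
per SD of expression. The oncogenotype screen then recovers the mutations
that drive the high mode:

```r
oncogenotype_screen(disc$expression, "KYNU", disc$mutations,
                    candidate_genes = unique(disc$mutations$gene))
#>   gene    n_mut n_wt tested     U        p    p_adj direction
#> 1 STK11     107  393 TRUE   33951 1.76e-22 9.16e-21         1
#> 2 KEAP1      80  420 TRUE   26830 2.50e-17 6.49e-16         1
#> 3 CAND007    73  427 TRUE   12403 5.28e-03 9.16e-02        -1
```

KEAP1 and STK11 dominate; the 50 background candidates behave like nulls.
`run_pipeline(run_config(seed = 7))` chains every stage and writes TSVs
plus a hashed manifest.

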