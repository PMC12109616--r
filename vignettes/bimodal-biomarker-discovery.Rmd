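---
title: "Bimodal biomarker discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal biomarker discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodalsurv)
```

## The problem this package addresses

Some genes in tumor transcriptomes are not merely variable — they are
*bimodal*: tumors express them either very highly or hardly at all,
typically because an upstream oncogenotype (for example, loss of the tumor
suppressors KEAP1 or STK11 in lung adenocarcinoma) switches a downstream
program on or off. Kynureninase (*KYNU*), an enzyme linking tryptophan
catabolism to de novo NAD synthesis, is the motivating example: its
expression splits lung adenocarcinomas into a high and a low mode, and the
high mode carries worse survival. For such genes, splitting patients at the
*between-mode boundary* is both more biologically meaningful and more
statistically powerful than splitting at the median, which cuts through the
bulk of one mode and dilutes the contrast.

`bimodalsurv` implements this discovery loop end to end: detect bimodal
genes, dichotomize patients by the fitted model, estimate survival hazards
per cohort in two modes, pool cohorts by random-effects meta-analysis, and
run the downstream oncogenotype, correlation, metabolite, and gene-set
analyses — all exercisable on synthetic cohorts with known truth.

## The mixture model and the bimodal index

Expression of a candidate gene is modeled as a two-component Gaussian
mixture with a **common variance**:

$$x \sim (1-\pi)\,N(\mu_1, \sigma^2) + \pi\,N(\mu_2, \sigma^2),
\qquad \mu_1 \le \mu_2 .$$

`fit_gmm2()` maximizes the likelihood by EM. The equal-variance restriction
is deliberate: it matches the classical bimodal-index construction, keeps
the likelihood bounded (no variance-collapse degeneracy of the general
model), and yields a closed-form dichotomization cutoff. The **bimodal
index**

$$\mathrm{BI} = \delta\sqrt{\pi(1-\pi)}, \qquad
\delta = \frac{\mu_2 - \mu_1}{\sigma}$$

scores how separated *and* how balanced the two modes are; a huge
separation carried by a negligible minor component scores low, as it
should.

Numerical choices, all exposed as arguments:

* **Initialization / restarts.** Three deterministic starts from quantile
  splits at 25/50/75% (`n_starts = 3`); additional starts are random and
  seeded. The best restart by log-likelihood wins. Deterministic defaults
  make screens reproducible without seed bookkeeping.
* **Convergence.** Relative log-likelihood change below `1e-8` or 500
  iterations. The inner loop is compiled (Rcpp) with responsibilities
  computed in log space, exploiting that the membership log-odds are linear
  in `x` under equal variances.
* **Degeneracy guards.** A floor of `1e-6 * sd(x)` on `sigma`; constant
  input raises a degenerate-input error rather than returning nonsense.
* **Labeling.** The component with the larger mean is always "high". No
  prognostic direction is assumed; that is inferred downstream by the Cox
  sign.

Two facts about this estimator are worth knowing and are asserted in the
test suite rather than papered over. First, on *unimodal* Gaussian data the
equal-variance MLE does not sit at $\mu_1=\mu_2$: it finds a spurious split
near $\pm E|Z|\sigma$, so null genes carry BI values around 0.2–0.8 at
realistic sample sizes (we confirmed the same behavior in an independent
EM implementation). Screens must therefore rank by BI rather than
threshold it naively near zero; the default flag threshold is
`min_bi = 1.1`. Second, the posterior-0.5 cutoff (below) can fall outside
$(\mu_1,\mu_2)$ when $|\ln((1-\pi)/\pi)| \ge \delta^2/2$ — a property of
the posterior algebra for weak, lopsided fits, not a bug.

## Dichotomization

Three rules, sharing one return type:

* **Model-based** (`dichotomize_cluster()`): label by maximum posterior.
  For equal variances this is exactly thresholding at
  $$x^\* = \frac{\mu_1+\mu_2}{2} +
  \frac{\sigma^2 \ln\!\big((1-\pi)/\pi\big)}{\mu_2-\mu_1},$$
  which the package reports and the tests verify against a bisection root
  of the posterior.
* **Median** (`dichotomize_median()`): high strictly above the median;
  ties at the median go low.
* **Quantile bands** (`dichotomize_quantile()`): high above the 80th and
  low below the 70th percentile by default, middle band excluded.
  Quantiles are type 7 (linear interpolation) with strict inequalities, so
  100 distinct values yield exactly 20 high and 70 low.

## Survival estimation and pooling

Per cohort and gene, `run_survival_screen()` fits univariate Cox
proportional-hazards models in two modes: **binary** (high vs low from the
cluster cutoff) and **continuous** (per SD of z-scored expression; the
z-score is per gene within cohort, the survival-relevant reading of
"standardized expression"). Cox fitting, the log-rank test, and
Kaplan–Meier curves are delegated to the `survival` package with **Efron
tie handling** — the de facto standard and the default of the tooling this
field uses; the test suite validates the fit against an independent dense
grid search of the Efron partial likelihood. Complete separation is flagged
(infinite log-HR sentinel, `converged = FALSE`) and excluded from pooling
with a logged reason, as are cohorts below `min_n = 10` patients.

Pooling is **DerSimonian–Laird random-effects on the log-HR scale**
(`meta_random_effects()`), implemented from the estimator's defining
formulas and cross-checked against `metafor`: fixed-effect weights
$w_i = 1/se_i^2$, heterogeneity $Q$, $\tau^2 = \max(0,
(Q-(k-1))/(\sum w - \sum w^2/\sum w))$, re-weighting by
$1/(se_i^2+\tau^2)$, Wald p. Log-scale pooling is the variance-stable
reading of "summary hazard ratios"; DL is the historical default estimator
of the standard meta-analysis tooling and is kept here for that reason.
$I^2 = \max(0, (Q-(k-1))/Q)$, and $\tau^2 = I^2 = 0$ whenever
$Q \le k-1$.

## Genotype calling and the oncogenotype screen

`call_tsg_status()` calls KEAP1/STK11 functional loss as the **union** of
evidence: a retained (non-silent-class) mutation, copy number strictly
below −1, the gene at a fusion/translocation breakpoint, a protein (RPPA)
level below the model-based cluster cutoff of the protein distribution, or
a pre-classified external call. Union means adding evidence can never
revoke a loss call; whether protein evidence should be allowed to override
contradictory mutation evidence is genuinely open, and the union rule is
the conservative, monotone choice. A degenerate protein distribution skips
only the RPPA channel, with a warning.

`oncogenotype_screen()` compares target-gene expression between mutants
and wild type per candidate gene by Mann–Whitney U, testing only
candidates with at least `min_mut = 9` mutant samples, and reports both
nominal and BH-adjusted p-values without filtering on either. The U test
is exact (enumerated null) when $n_a n_b \le 400$ without ties — small
enough to verify against brute-force enumeration — and otherwise uses the
normal approximation with tie-corrected variance and continuity
correction.

## Associations and enrichment

Genome-wide Pearson screens (`correlation_screen()`) use the exact t
transform with $n-2$ df and BH adjustment within stratum; zero-variance
genes are flagged, not dropped, so row counts stay predictable.
`within_group_correlation()` probes biphasic association (a covariate
tracking the target only below or only above the cutoff).
`metabolite_multivariate()` is ordinary least squares
`metabolite ~ target_status + keap1 + stk11`, the adjustment asking
whether a metabolite tracks target expression beyond genotype.
`hypergeom_enrichment()` is the upper-tail hypergeometric test against an
explicit universe. The cross-cohort consistency rule
(`intersect_significant()`) intersects features significant in *every*
cohort; sign concordance is deliberately not imposed.

GSEA (`gsea_permutation()`) ranks genes by signal-to-noise
$(\mu_A-\mu_B)/(\sigma_A+\sigma_B)$ with the classical per-class SD floor
$\max(\sigma, 0.2|\mu|, 0.2)$, walks the weighted running sum (weight
$p=1$), and estimates significance by **sample-label permutation** with an
add-one, same-sign convention:
$p = (1 + \#\{\text{perm ES at least as extreme, same sign}\}) /
(1 + \#\{\text{perm ES same sign}\})$ — never exactly zero. NES divides
the observed ES by the mean magnitude of same-sign permutation scores. Set
sizes are bounded to $[5, 500]$ after universe intersection; FDR q-values
across sets are out of scope. "Genes in multiple leading-edge lists" is
operationalized as at least 2 lists (`leading_edge_recurrence()`).

## The synthetic-study generator

`synthetic_config()` fixes the generative model the analyses assume:

| parameter | default | meaning |
|---|---|---|
| cohorts | 5 (500/200/150/120/100) | one TCGA-sized discovery cohort plus four smaller validation series |
| `mu_low`, `delta`, `sigma`, `pi_high` | 4, 3, 1, 0.3 | log2-scale mixture; BI ≈ 1.37 |
| `baseline_rate` | 0.05 / month | exponential baseline hazard |
| `log_hr_component` | ln 2 | hazard ratio of high vs low component |
| `admin_time`, `random_censor_rate` | 60 months, 0.01 | ~35% censoring |
| `q_high`, `q_low` | 0.5, 0.05 | KEAP1/STK11 mutation rates by component |
| `background_mut_rate` | 0.15 | null candidate genes, component-independent |
| `met_slope`, `met_gamma_*`, `met_sd` | 0.5, 0.5, 1 | metabolite coupling |
| `n_null_genes` | 200 | i.i.d. Gaussian null genes |

The exponential baseline is chosen for closed-form checkability (the
Kaplan–Meier curve of the low component must track $e^{-\lambda_0 t}$);
the analysis itself only assumes proportional hazards. Cohort seeds are
derived from the master seed by a deterministic substream mix, so any
subset of cohorts regenerates bit-identically. Cohort sizes mirror a
realistic multi-cohort study — a ~500-patient discovery dataset among
smaller series — and the genome-wide BI ranking is run on the discovery
cohort, where the maximum null BI over 200 genes stays clearly below the
target's.

What the generator deliberately does **not** emulate: RNA-seq count noise
and library-size effects, batch effects, gene–gene correlation among null
genes, copy-number coupling to expression, and non-proportional hazards.
Passing tests on this generator therefore demonstrate that the estimators
and gates behave as designed under the assumed model — not that the model
captures every pathology of real cohorts.

## Orchestration

`run_pipeline(run_config(...))` executes simulate → bimodal screen →
survival meta-analysis → genotype screen → associations → GSEA, writes
every table as TSV, and finishes with a manifest of output files and MD5
hashes plus a log of seed and thresholds. All randomness flows from the
single config seed through named substreams, so identical configs
reproduce identical manifests; a stage failure aborts with the stage named
and a `FAILED` marker. The package's functions are the interface — the
pipeline is small enough that no workflow engine or shell entry point is
warranted.

## Problem sizes used in validation

The shipped checks run at deliberately desk-scale sizes chosen to make the
statistical properties visible while keeping the suite quick: mixture
recovery at n = 2000; dichotomization-power and meta-calibration studies
at 10 cohorts × 150–300 patients with 100–200 replicates; Mann–Whitney
and GSEA null calibrations at 500–1000 replicate p-values; and 50–100
full end-to-end seeds of the default study. These sizes are the package's
own validation design; all of them scale up by changing the corresponding
arguments.

## Known limitations

* The equal-variance two-component model is the screening tool, not a
  claim about the data-generating process; genes with unequal mode
  variances or more than two modes are outside its scope.
* BI has a non-trivial null distribution (see above); rankings are
  meaningful, raw thresholds near zero are not.
* Multivariate Cox models are per-cohort only; pooled multivariate
  meta-analysis is not provided.
* Immune-infiltrate scores and similar covariates are consumed as given;
  no deconvolution is implemented.
* The meta-analysis excludes non-converged per-cohort fits rather than
  stabilizing them (e.g. by penalization); the exclusion log makes this
  visible.
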