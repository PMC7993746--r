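---
title: "The mPS pipeline: model, design choices, and what the synthetic cohorts do and do not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mPS pipeline: model, design choices, and what the synthetic cohorts do and do not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpscore)
```

## The molecular prognostic score

The molecular prognostic score (mPS) is a weighted sum of binary per-gene
scores over a fixed gene panel. For a sample $i$ and a panel of $G$ genes,

$$\mathrm{mPS}_i = \sum_{g=1}^{G} S_{gi}\, w_g,$$

where $w_g > 0$ is the gene's weight and $S_{gi} \in \{0,1\}$ is its
Gene-Score: the gene's expression is dichotomized at the cohort median
(strictly above = high state, ties low) and exactly one of the two states
maps to score 1, chosen by the direction of the gene's hazard ratio. The
package ships a published 21-gene clear cell renal cell carcinoma (ccRCC)
panel (`panel_table2()`, weights summing to 74.616) and can construct new
panels from any expression + overall-survival cohort.

Panel construction proceeds in two stages:

1. **Screen.** Every gene is split at its cohort median; the high and low
   groups are compared by log-rank test, and the hazard ratio
   HR(high vs low) comes from a Cox proportional-hazards fit on the binary
   indicator. In parallel, tumor-vs-normal differential expression is
   assessed with limma's moderated t-statistics (BH-adjusted p < 0.05 and
   |log2FC| > 2). The candidate set is the intersection of the survival
   hits and the DE hits.
2. **Select and weight.** Candidate genes are binarized to Gene-Scores,
   a random forest (500 trees, depth at most 10, stratified 10-fold
   cross-validation, impurity-decrease importance averaged over folds)
   classifies 3-year vital status from the scores and ranks the genes, and
   a small feed-forward neural network (inputs → 4 ReLU → 2 ReLU → 2
   softmax, cross-entropy loss, full-batch Adam, learning rate 0.001,
   1000 epochs) is trained on the selected genes. Each gene's weight is
   the L1 norm of its outgoing first-layer weight vector.

Scored samples are stratified by fixed thresholds (the published scheme:
low < 22 ≤ median < 30 ≤ high, or a two-group split at 22 for small
cohorts), and evaluated with Kaplan–Meier curves and log-rank tests,
univariate → multivariate Cox modelling, Harrell's concordance index, and
a points-based nomogram for 3-/5-year survival with bootstrap-corrected
calibration.

## Orientation: score 1 is the favorable state

The direction convention is a single constant of the package: **score 1
marks the prognostically favorable expression state** — the low state for
a gene with HR(high vs low) > 1, the high state for HR < 1 — so a larger
mPS always predicts longer survival. This matches the published
multivariable result for the 21-gene panel (mPS high vs low HR 0.46,
i.e. high mPS is protective) and the observation that the low-mPS
subgroup carries more genomic abnormality and worse outcome. The printed
step-function table accompanying the original panel reads the opposite way and
cannot be reconciled with those results; we treat the protective-high
orientation as authoritative. Consumers of `concordance_index()` must
therefore pass `higher = "survival"` for mPS values.

A gene with HR exactly 1 carries no direction; it is tie-broken to the
low-state-favorable orientation and the decision is logged.

## The synthetic cohort generator

Real TCGA/ICGC cohorts are not redistributable at desk scale, so every
stage is exercised against synthetic cohorts with known planted structure
(`simulation_config()` / `generate_cohort()`). The generator's defaults
are the study conditions the package is tested under:

| parameter | default | meaning |
|---|---|---|
| `n_tumor`, `n_normal` | 531, 72 | cohort sizes of the ccRCC discovery data |
| `n_genes` | 1000 | gene universe (desk-scale stand-in for the transcriptome) |
| `n_prognostic`, `n_de` | 30, 30 | planted survival-associated and tumor-vs-normal genes (maximally overlapping) |
| `planted_log_hr` | log 2 | per-gene high-vs-low log hazard ratio |
| `planted_log2fc` | 2.5 | tumor-minus-normal shift of DE genes (log2) |
| `risk_separation` | 6 | separation of the risk-readout modes, in noise SDs |
| `baseline_scale`, `baseline_shape` | 8000 d, 1.1 | Weibull baseline (3-year baseline survival ≈ 0.90) |
| `censor_rate` | 0.68 | target censoring fraction (the discovery cohort was 67.6% alive) |
| `noise_sd` | 1 | per-gene expression SD (log2) |

**Expression** is per-gene Gaussian on the log2 scale. DE genes get an
additive `planted_log2fc` shift in tumors.

**Survival** follows a Weibull proportional-hazards model. The planted
prognostic signal acts through a *single latent binary risk state* that
splits the tumor cohort exactly in half; planted genes are well-separated
expression readouts of that state, and the log hazard adds
`planted_log_hr` for risk-high samples plus the clinical covariate
contributions. This design is deliberate: because each planted gene's
above-median indicator coincides with the risk state, the unadjusted
per-gene median-split Cox fit is *correctly specified* and recovers
`planted_log_hr` without bias. The alternative — summing independent
per-gene hazard contributions — makes the marginal per-gene hazard ratio
unrecoverable by any unadjusted screen: with 30 independent planted
indicators at HR 2 each, non-collapsibility attenuates the marginal
estimates to ≈ 1.4, so "the screen recovers the planted HR" would be
false by construction rather than a property of the screen. The omitted
clinical covariates still attenuate the per-gene HR by ≈ 9% at the
default published-scale effect sizes — the same marginalization effect a
genome-wide screen faces on real data; set `covariate_betas` to zero for
an exactly unbiased check.

**Censoring** is independent administrative-style censoring,
C ~ Uniform(0, U), with U tuned by root-finding so the realized censoring
fraction matches `censor_rate`. Exponential censoring tuned to
ccRCC-like censoring fractions concentrates follow-up so early that
essentially no sample remains under observation at the 3-year label
horizon, which would collapse the classifier-training stage; uniform
censoring hits the same fraction while retaining multi-year follow-up,
as staggered-accrual studies do.

**Clinical covariates** are independent draws with ccRCC-typical
prevalences (half older than 60, two-thirds male, grade 3/4 in ~53%,
stage III/IV in ~39%, M1 in ~15%, with unknown/NX/MX fractions), and
their default log hazard ratios mirror a published multivariable ccRCC
model (age 1.58, stage 2.18, M1 1.83, hemoglobin 1.60, platelet 1.74).
Prevalences for the three lab values are not published and were fixed
once at clinically plausible values (low hemoglobin 0.35, elevated
platelet 0.12, low calcium 0.25).

**What the generator does not emulate:** RNA-seq count distributions,
library-size or batch effects, gene–gene correlation beyond the planted
risk module, non-proportional hazards, informative censoring, or real
TCGA marginals. Passing tests on these cohorts therefore demonstrate
*algorithmic correctness and statistical calibration* of the pipeline —
unbiased hazard recovery, type-I error control, CI coverage, concordance
and calibration behavior — not clinical performance on real data.

## Stage-level design choices

- **Survival screen p-value.** Genes pass the screen on the *unadjusted*
  log-rank p < 0.05; multiplicity control is applied only in the DE arm
  (BH), matching how the original gene funnel was reported. Both log-rank
  and Cox–Wald p-values are returned per gene.
- **Median ties** go to the low group, making "strictly above the median"
  the definition of the high state everywhere (screen, Gene-Scores,
  scoring of new cohorts).
- **Moderated t.** Differential expression delegates to limma (`lmFit` /
  `eBayes` / BH), i.e. gene-wise variances are shrunk toward a pooled
  prior with limma's own prior-df estimate.
- **Random forest depth** is controlled through
  `maxnodes = 2^max_depth` (the forest implementation exposes a
  terminal-node bound, not a depth bound; at 2^10 nodes the constraint is
  loose for desk-scale cohorts, as intended by a depth-10 setting).
  Importances are averaged over the forests trained on each of the 10
  stratified training splits.
- **Importance cutoff.** The raw mean-decrease-in-impurity cutoff 0.5 is
  kept as the default, but it is a scale-dependent quantity: it depends
  on cohort size, class balance and feature correlation. For synthetic
  builds the package's workflows use the alternative top-k mode with
  k = 21, the published panel size. With planted genes that are readouts
  of a common risk state, importance mass is split across correlated
  features and the raw cutoff of the original cohort does not transfer.
- **3-year labels.** Samples censored before the 3-year horizon have
  unknown status and are excluded from RF/NN training rather than
  imputed.
- **Gene-weight collapse.** The trained first layer has 4 outgoing
  weights per gene; the published panel gives one positive scalar per
  gene. The package collapses by the L1 norm (default; `l2` and `sum`
  are available and logged). A gene whose whole outgoing row is zero is
  flagged and dropped from the panel with a warning.
- **Scoring new cohorts.** Per-gene medians are recomputed within the
  cohort being scored (as the published panel was applied to the external
  validation cohort); a frozen `median_reference()` from the construction
  cohort is an explicit option. Missing panel genes are an error in
  strict mode; permissive mode imputes the median (low) state, and more
  than 20% missing genes is always an error.
- **Stratification thresholds** are constants of a scheme, never
  re-estimated, with half-open bins exactly as published (22/30, or 22
  for two groups). For freshly trained panels, whose weight scale is not
  commensurate with the published one, the pipeline can split at the
  cohort median mPS instead (`strata = "median"`).
- **Cox details.** Efron tie handling; the standard ccRCC dichotomies fixed at parse
  time (older/younger, G3&4 vs G1&2, III&IV vs I&II, T3&4 vs T1&2,
  N1 vs N0, M1 vs M0, low vs normal hemoglobin/calcium, elevated vs
  normal platelet); unknown/NX/MX levels are excluded listwise per model
  with `n_used` reported; non-convergence and separation raise errors.
  mPS enters Cox models and the nomogram as the high-vs-low dichotomy.
- **Nomogram.** Points are
  $100\,|\beta_j|\,\mathrm{range}_j / \max_k |\beta_k|\,\mathrm{range}_k$
  (range 1 for dichotomies); total points map affinely back to the linear
  predictor; survival predictions use the Breslow baseline
  $S_0(t)^{\exp(\mathrm{lp})}$ evaluated at 3 and 5 years (horizons
  beyond follow-up are dropped). Harrell's C on the fitting cohort is
  attached and logged with the conventional "≥ 0.70 is a good fit"
  annotation — a log message, never a gate.
- **Calibration** bins samples by predicted survival (tertiles by
  default) and compares against the Kaplan–Meier estimate at the horizon
  per bin. With `n_boot > 0` (default 200, seeded) the Cox model is refit
  on bootstrap resamples and the per-bin optimism of
  (observed − predicted) is subtracted from the apparent curve.
- **Harrell's C** is computed over comparable pairs (the strictly earlier
  time has an event), with prediction ties counting 0.5, and an explicit
  orientation flag. The implementation is the package's own and is
  cross-checked against `survival::concordance` in the test suite.
- **Determinism.** Every stochastic step takes an explicit seed;
  `run_mps_pipeline()` expands one global seed into per-stage seeds via a
  fixed affine map (`stage_seed()`), writes per-stage manifests (inputs,
  outputs, config hash, seed, record counts), and reproduces byte-identical
  outputs under a fixed config.

## Numerical notes

- Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$,
  bias-corrected moments, full-batch gradients; weights are
  He-initialized (SD $\sqrt{2/\text{fan-in}}$), biases start at zero;
  softmax probabilities are clipped at $10^{-12}$ inside the loss; a
  non-finite loss aborts with the epoch index.
- The censoring horizon and any other root-finding use `uniroot` at
  tolerance $10^{-10}$ on a log grid.
- Baseline survival lookups are right-continuous step functions equal to
  1 before the first event time.
- Empty split groups (constant genes) are flagged per gene and excluded
  from screening results rather than raising errors mid-screen.

## Problem sizes used by the shipped workflows

The numbered scripts under `analysis/` run the pipeline at the default
cohort scale (531 tumors / 72 normals, 1000 genes, 30 planted). The test
suite and `scripts/acceptance.R` use 150–600 tumors and 30–2000 genes:
large enough that type-I error, hazard-recovery bias, CI coverage and
calibration are measured with useful precision, small enough that the
whole suite runs in about a minute. The aggregate planted effect for
end-to-end runs is HR 3.2 between latent risk groups, the magnitude
implied by the published univariate high-vs-low mPS hazard ratio (0.31).

## Known limitations

- A freshly trained panel's weights are *not* comparable to the published
  weights; retraining on the original data with unknown seeds is out of
  scope, and the published 21-gene panel is shipped as data instead.
- The binary latent risk state caps the achievable concordance of any
  derived score near $0.5 + 0.5\,\mathrm{HR}/(1+\mathrm{HR})$; synthetic
  C-indices in the low 0.6s are a property of the design, not a defect of
  the scoring.
- The evaluation layer implements proportional-hazards diagnostics only;
  time-dependent AUC, competing risks and comparisons against other
  published signatures are out of scope.
- `concordance_index()` ignores pairs with exactly tied event times, so
  it can differ in the last decimals from implementations that count
  them; the cross-check test uses tie-free data.
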