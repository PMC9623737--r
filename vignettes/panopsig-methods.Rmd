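---
title: "Stratifying tumors by a PANoptosis signature and distilling prognostic markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying tumors by a PANoptosis signature and distilling prognostic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panopsig)
```

## The scientific problem

Programmed cell death (PCD) resistance is a hallmark of cancer, but the
prognostic roles of individual PCD genes are blurred by redundancy and
crosstalk between pyroptosis, apoptosis and necroptosis. PANoptosis is an
integrated, inflammasome-linked PCD pathway whose components span all three
branches. `panopsig` operationalizes PANoptosis as a 27-gene expression
signature — 9 cytosolic sensors/upstream regulators (`ADAR`, `AIM2`, `MEFV`,
`NLRC4`, `NLRP1`, `NLRP3`, `NLRP9`, `TNFRSF1A`, `ZBP1`), 2 adaptors (`FADD`,
`PYCARD`) and 16 effectors (the caspases plus `DFNA5`, `GSDMD`, `MLKL`,
`RIPK1`, `RIPK3`, `TNF`) — and asks two questions of a bulk expression cohort
with overall-survival follow-up:

1. Do tumors stratify into PANoptosis-high / -medium / -low groups with
   different survival?
2. Which minimal subset of the 27 genes carries the prognostic signal, and in
   which direction?

## Stratification model

Samples are clustered on the signature block with **subsampled consensus
clustering**: in each repeat a fraction of samples (default 0.8, all genes
retained) is drawn without replacement and Ward-clustered (`ward.D2` on
Euclidean sample distances) into *k* groups; the consensus matrix records,
for every sample pair, the fraction of co-draws in which the pair
co-clustered. Final labels cut a complete-linkage tree of `1 - consensus` at
*k*. The production default is 5000 repeats (tests and examples use 30–200;
the consensus matrix is already stable at a few hundred repeats for the
cohort sizes simulated here).

The cluster count is chosen over `k = 3..6` by the **Calinski–Harabasz
index** — between-cluster over within-cluster dispersion, df-scaled —
evaluated on signature expression with the consensus-derived partition.
Evaluating the index on the consensus-matrix rows instead is available
behind the `evaluate_on` flag; expression space is the default because the
index is defined for point clouds and the expression geometry is what the
strata are interpreted in. The cluster with the highest mean signature
expression is labeled `high`, the lowest `low`, everything else `medium`;
exact mean ties are broken toward the larger cluster (and logged) so the
extreme strata stay well-populated.

Each sample also receives a **PANoptosis score**: a single-sample enrichment
score of the signature against the rest of the transcriptome. Two
random-walk statistics are implemented:

* `gsva`: per-gene Gaussian-kernel CDF across samples (bandwidth `sd/4`),
  per-sample symmetric rank statistic `|p/2 - rank|`, weighted
  Kolmogorov–Smirnov walk, `ES = max positive - max negative deviation`
  (weight exponent `tau = 1`).
* `ssgsea`: within-sample expression ranks, integrated difference between
  the `rank^alpha`-weighted ECDF of signature genes and the ECDF of the
  rest (`alpha = 0.25`), optionally range-normalized across samples. This is
  the estimator used per cell in the single-cell path.

Both are invariant to gene relabeling and to a constant shift applied to the
whole matrix. A constant added to a *single* sample is not an exact
invariance of the gsva statistic (per-gene bandwidths differ, so one
sample's shift can reorder genes within that sample); in practice the effect
is negligible, and the rank step makes the ssgsea statistic exactly
location-free per sample.

## Survival screening

Follow-up is cleaned the way registry cohorts usually are: below 1 day
removed, administratively censored at 10 years (3650 days; 365-day years).
The high-vs-low contrast is summarized by a univariate Cox hazard ratio on
the stratum indicator (medium excluded) with the log-rank p-value as
primary (the Cox Wald p is also reported, since "chi-square test" is used
for both conventions in the applied literature). A cohort is retained when
`p < 0.05` and the combined stratum size exceeds 100, after pre-excluding
comparisons with zero events in either stratum, where the hazard ratio is
not estimable. Cox machinery (Efron ties by default, Breslow available for
closed-form cross-checks), Kaplan–Meier curves, and the scaled-Schoenfeld
proportional-hazards diagnostic are delegated to the `survival` package
behind the package's interfaces.

## Marker selection

**Step 1 — differential expression.** Three moderated-t contrasts (limma
`lmFit`/`eBayes`): (a) high vs low, (b) high vs normal, (c) low vs normal.
A gene is DE when `|logFC| > 0.5` and BH-adjusted `p < 0.05`. Genes DE in
(a) are *primary* markers; otherwise DE in (b) or (c), *secondary*; the
rest are excluded from modeling. The FDR default is 0.05 (the threshold
attached to the classification rule); both thresholds are configurable.

**Step 2 — three survival models on the training split (80/20,
event-stratified).**

* *Univariate Cox* per gene, BH-adjusted Wald p.
* *Elastic-net Cox stability selection*: `cv.glmnet(family = "cox")` run
  `n_runs = 100` times, each run with its own event-stratified 5-fold
  assignment seeded from the master seed; lambda maximizes the mean
  cross-validated Harrell concordance (no 1-SE rule); a gene is selected
  when its coefficient is nonzero at that lambda. Genes selected in at
  least 50% of runs (inclusive) are *stable*. Mixing is `alpha = 0.5` —
  elastic net rather than pure lasso, because the signature block is
  correlated and the lasso's selections are degenerate under correlated
  covariates; `alpha = 1` remains available for ablation.
* *Random survival forest* (`ranger`, log-rank splitting): hyperparameters
  by cross-validated concordance over a small grid, permutation variable
  importance with confidence intervals from repeated 0.632-subsample
  refits; the top `k = 10` genes by importance (ties toward the higher
  lower bound) are retained, mirroring a "top-10 importance" readout.

The **Top gene set** is the intersection: univariate-significant genes that
are stable with an elastic-net coefficient sign matching the univariate
direction and sit in the importance top 10. Sign agreement matters: a gene
can be selected often yet carry a coefficient opposite to its marginal
hazard direction (a correlated-covariate artifact), and such genes are
dropped. The direction of effect (detrimental `HR > 1` vs beneficial
`HR < 1`) is recorded per gene.

## Evaluation

* **Harrell's concordance**: pairs are evaluable when the earlier observed
  time is an event; concordant when that subject has the higher risk; tied
  risks count 0.5. The implementation is checked against exhaustive pair
  enumeration.
* **Time-dependent AUC**: cumulative-case / dynamic-control estimator with
  inverse-probability-of-censoring weights from the censoring Kaplan–Meier
  curve; without censoring before `t` it collapses to the Mann–Whitney AUC
  of risk against the event-by-`t` indicator (the package tests both
  identities).
* **External validation**: genes are z-scored within each cohort, so a
  linear risk model is invariant to per-gene affine platform shifts; model
  genes missing from the cohort are imputed at 0 (the post-z-scoring mean)
  with the count logged, and validation refuses to score a cohort missing
  more than half of the model genes.

## The synthetic cohort generator

The generator produces the statistical structure the analysis assumes, plus
ground truth, so every stage is testable offline:

* a 3-level ordinal latent activity (`-1, 0, +1`, i.e. low/medium/high) with
  per-level shift `delta` in noise-SD units (default 2);
* signature genes load on the latent level and on a per-sample shared
  factor (`shared_sd = 0.35` by default, noise SD 1), giving a visibly
  positive within-signature Pearson correlation (~0.1) with no group
  structure and much stronger correlation once group structure is added.
  The factor lies along the same all-genes direction as the group shift, so
  its SD trades correlation strength against cluster recoverability; 0.35
  keeps the three groups resolvable at `delta = 2` while `shared_sd = 0.5`
  (within-signature r ~ 0.2) is the setting used for the correlated
  marker-selection stress test;
* background genes are baseline plus independent noise; baselines are drawn
  Unif(4, 9) on a log2-like scale, matching the dynamic range of
  quantile-normalized log2 RNA-seq;
* survival is exponential (constant baseline hazard, 1/1000 events/day —
  median survival roughly two years at baseline) with hazard
  `exp(sum beta_g (x_g - baseline_g))` over planted genes; censoring is an
  independent exponential whose rate is solved by `uniroot` so the expected
  censored fraction matches the request (default 0.3, a typical
  registry-cohort censoring level);
* matched normals share gene baselines, with an optional `tumor_shift` on
  signature baselines to plant differential-expression truth;
* external cohorts are re-drawn from the same latent model, then per-gene
  affine-distorted and optionally stripped of genes, emulating array
  platforms;
* single-cell counts are negative-binomial with cell-type-specific
  signature activity and log-normal library sizes.

What the generator does **not** emulate: batch effects, copy-number or
mutational structure, realistic count-depth distributions for bulk data, or
non-proportional hazards (a Weibull-like extension would need only a shape
parameter, but constant hazard is the simplest model satisfying the
proportional-hazards assumption the pipeline tests under). Passing tests on
these cohorts therefore demonstrates correctness of the machinery and
recoverability of planted signal under the stated model, not performance on
real tumors.

## Numerical choices and degenerate inputs

* Quantile normalization averages tied ranks (the classic microarray rule)
  and is idempotent to 1e-12; the log2 offset defaults to 1 for count-like
  input and 0 for already-log data.
* Duplicate gene symbols collapse by row-mean; symbol-less rows are dropped.
* Zero-variance genes are flagged at transform time, excluded (with a
  warning) from gsva scoring, and rejected by the correlation matrix.
* `cox_fit` refuses constant covariates and warns on extreme coefficients
  (monotone likelihood); the clinical-adjusted model rejects collinear
  encodings via a rank check.
* Stability thresholds are inclusive (`>=`), matching the "at least 50%"
  rule; an all-zero stability profile yields an (explicitly messaged)
  empty stable set, and an empty three-model intersection is returned empty
  rather than padded.
* All stochastic stages take explicit integer seeds and restore the
  caller's RNG state; a fixed config reproduces a pipeline report exactly.

## Problem sizes used by the test-suite

The packaged checks run at desk scale, chosen to keep the full suite within
a coffee break while leaving the recovery margins wide: cluster recovery at
n = 300 with 200 consensus repeats over 10 seeds; stability selection at
n = 600 with 100 runs x 5 folds and a 25-point lambda grid over 10 master
seeds; null calibration with 200 permutation replicates; direction fidelity
over 20 seeds per direction; external-consistency checks at n = 500. The
production defaults (5000 consensus repeats and the full lambda path) are
the package defaults in `default_config()`.

## Known limitations

* The gsva statistic is quadratic in samples per gene (kernel CDF); for
  cohorts much beyond a few thousand samples the ssgsea method is the
  practical choice.
* The forest importance CIs are subsampling quantiles, not a
  jackknife-variance construction; they are used for rank tie-breaking, not
  formal inference.
* The univariate filter does not remove genes that are marginally
  prognostic only through correlation with causal genes — by design, since
  marginal association is what a univariate survival screen measures; the
  stability and importance filters carry that burden.
* Real-data entry points accept local TSV/GMT/MTX files only; no download
  clients are included.
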