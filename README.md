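# panopsig

Pan-cancer stratification and prognostic marker selection with a
27-gene PANoptosis cell-death signature.

## What it does

PANoptosis is an innate-immune inflammatory programmed-cell-death pathway
that integrates pyroptosis, apoptosis and necroptosis components. `panopsig`
turns a bulk expression cohort (genes × samples, quantile-normalized log2)
with overall-survival follow-up into:

1. **Strata** — samples are consensus-clustered on the 27-gene signature
   (subsampled Ward clustering, co-clustering consensus matrix, cluster
   count by the Calinski–Harabasz index over k = 3..6) and labeled
   PANoptosis **high / medium / low** by mean signature expression.
2. **Scores** — a per-sample PANoptosis score from single-sample gene-set
   enrichment (`gsva` Gaussian-kernel random walk or `ssgsea` weighted-ECDF
   statistic).
3. **Prognostic screen** — Kaplan–Meier curves, log-rank test and a Cox
   hazard ratio for high vs low (HR > 1: high stratum does worse), with the
   cohort screening rule p < 0.05 and N1 + N2 > 100 after pre-excluding
   zero-event strata.
4. **Markers** — moderated differential expression (high-vs-low,
   high-vs-normal, low-vs-normal) classifies primary/secondary markers;
   then three survival models on an 80/20 event-stratified split —
   per-gene univariate Cox, 100-run elastic-net Cox stability selection
   (gene kept when selected in ≥ 50% of cross-validated runs), and a
   random survival forest with permutation importance — are intersected
   into the **Top** gene set with a direction of effect per gene.
5. **Validation** — Harrell's concordance and IPCW time-dependent AUC on
   the held-out split and on external cohorts (within-cohort z-scoring
   makes linear risk models invariant to per-gene platform shifts).

A synthetic-cohort generator with planted ground truth (latent 3-level
activity, correlated signature block, proportional-hazards survival with
planted coefficients, platform-shifted external cohorts, negative-binomial
single cells) makes the whole pipeline testable without any downloads.

## Worked example

```r
library(panopsig)

sig <- panoptosis_signature()
length(sig$genes)
#> [1] 27

co <- simulate_bulk_cohort(300, n_background = 50, delta = 2,
                           planted_genes = c("ZBP1", "CASP8", "GSDMD"),
                           beta = 0.15, seed = 1)
expr_sig <- co$expression[sig$genes, ]

sel <- select_cluster_count(expr_sig, n_resamples = 200, seed = 1)
sel$k
#> [1] 3
lab <- label_clusters(sel$results[[as.character(sel$k)]]$labels, expr_sig)
cmp <- compare_strata(lab, clean_followup(co$survival))
round(cmp$hr, 2); signif(cmp$p, 3)
#> [1] 5.98
#> [1] 2.93e-21
```

The chosen cluster count recovers the three planted activity levels, and
the hazard ratio is far above 1 because the planted coefficients make high
signature activity detrimental: patients in the high stratum die faster
than those in the low stratum. Flipping the sign of
`beta` flips the direction (HR < 1), mirroring cancers where high signature
activity is protective.

The full pipeline is one call:

```r
report <- run_pipeline(list(
  seed = 1,
  simulate = list(n_samples = 300, n_background = 100, delta = 2,
                  planted_genes = c("ZBP1", "CASP8", "GSDMD"), beta = 0.8,
                  tumor_shift = 1, seed = 1),
  n_resamples = 200, n_runs = 25, rsf_B = 10, min_samples = 100
), out_dir = "results/demo")
report$top$gene
```

which writes a JSON + TSV bundle (strata, scores, comparison table,
marker classes, stability profile, importance profile, Top set, validation
metrics).

## Package layout

- `R/signature.R` — the 27-gene signature and GMT I/O
- `R/ingest.R` — expression/clinical readers, quantile normalization, log2
- `R/simulate.R` — synthetic cohorts with planted truth
- `R/scoring.R` — consensus clustering, cluster-count selection,
  strata labeling, gsva/ssgsea enrichment, correlation matrix
- `R/survival_core.R` — follow-up cleaning, KM, log-rank, Cox, PH
  diagnostics, stratum comparison and cohort screening
- `R/markers.R` — moderated DE, marker classes, elastic-net path and
  stability selection, forest importance, Top-set intersection
- `R/evaluation.R` — splits, concordance, time-dependent AUC,
  cross-validation, external validation
- `R/sc.R` — single-cell log-normalization, variable genes, per-cell
  scores, per-type summaries
- `R/pipeline.R` — end-to-end orchestration and report serialization

See `vignettes/panopsig-methods.Rmd` for the model, parameter rationale,
and the limits of what the synthetic cohorts demonstrate.
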