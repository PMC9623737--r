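Package: panopsig
Title: PANoptosis Gene-Signature Stratification and Prognostic Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies bulk tumor expression cohorts by a 27-gene PANoptosis
    cell-death signature using subsampled consensus clustering, scores samples
    by single-sample gene-set enrichment (gsva and ssGSEA random-walk
    statistics), tests the prognostic impact of the resulting high/medium/low
    strata (Kaplan-Meier, log-rank, Cox proportional hazards with Schoenfeld
    diagnostics), classifies primary and secondary markers by moderated
    differential expression, and distills a minimal "Top" prognostic gene set
    by intersecting univariate Cox, stability-selected elastic-net Cox, and
    random-survival-forest variable importance. Includes evaluation tools
    (Harrell's concordance, IPCW time-dependent AUC, event-stratified
    splits/cross-validation), a minimal single-cell scoring path, and a
    synthetic-cohort generator with planted ground truth for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    limma,
    Matrix,
    ranger,
    stats,
    survival,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
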