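# End-to-end orchestration: simulate or ingest -> cluster/score -> survival
# screen -> marker classification -> three-model selection -> validation.

#' Default pipeline configuration
#'
#' Production defaults: 5000 consensus resamples, k in 3..6, 100 stability
#' runs with 5-fold CV and a 0.5 frequency threshold, elastic-net mixing 0.5,
#' 80/20 event-stratified split, 10-year follow-up horizon, DE thresholds
#' |logFC| > 0.5 and FDR < 0.05. Any entry can be overridden through
#' [run_pipeline()]'s config.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_resamples = 5000, k_min = 3, k_max = 6, subsample_fraction = 0.8,
    score_method = "gsva",
    min_days = 1, horizon_years = 10,
    p_threshold = 0.05, min_samples = 100,
    lfc_thr = 0.5, fdr_thr = 0.05,
    n_runs = 100, n_folds = 5, stability_threshold = 0.5, alpha = 0.5,
    nlambda = 50,
    rsf_ntree = 500, rsf_B = 100, vimp_k = 10,
    train_fraction = 0.8,
    auc_times_years = c(2, 4, 5)
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(default_config(), config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

#' Run the full stratification / marker-selection pipeline
#'
#' Stages, in order: load or simulate a cohort; restrict to the signature and
#' consensus-cluster it (choosing k by the Calinski-Harabasz criterion);
#' label high/medium/low strata and score samples by single-sample
#' enrichment; clean follow-up and test the prognostic impact of high vs low
#' (with the cohort screening rule); classify primary/secondary markers by
#' moderated differential expression against strata and normals; split
#' train/test, run the univariate Cox, stability-selected elastic-net Cox and
#' random-survival-forest models on the training set and intersect them into
#' the Top gene set; fit a multivariate Cox risk model on the Top genes and
#' validate it on the held-out test set (and on an external cohort when
#' provided).
#'
#' @param config A named list (or YAML file path) overriding
#'   [default_config()]. Inputs are given either as file paths
#'   (`expression_path`, `clinical_path`, `signature_path`, optionally
#'   `normals_path`, `external_expression_path`, `external_clinical_path`) or
#'   as a `simulate` sub-list of [simulate_bulk_cohort()] arguments
#'   (optionally `simulate_external` for [simulate_external_cohort()]).
#' @param out_dir Optional directory; when given, [write_report()] is called.
#' @return A `pipeline_report` list: `config`, `config_hash`, `k`, `strata`
#'   table, `scores`, `comparison`, `screen`, `adjusted_fit` table,
#'   `markers`, `stability`, `vimp`, `top`, `validation` (internal and, when
#'   available, external rows), `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  if (is.null(cfg$simulate) && is.null(cfg$expression_path))
    stop("config must provide either `simulate` or input paths")

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    cohort <- do.call(simulate_bulk_cohort, cfg$simulate)
    sig <- cohort$truth$signature
    expr <- cohort$expression
    surv <- cohort$survival
    normals <- cohort$normals
    external <- if (!is.null(cfg$simulate_external))
      do.call(simulate_external_cohort, c(list(base = cohort), cfg$simulate_external))
  } else {
    for (p in c("expression_path", "clinical_path", "signature_path"))
      if (!file.exists(cfg[[p]])) stop("missing input file: ", cfg[[p]])
    expr <- read_expression(cfg$expression_path)
    surv <- read_clinical(cfg$clinical_path)
    sig <- read_signature(cfg$signature_path)
    normals <- if (!is.null(cfg$normals_path)) read_expression(cfg$normals_path)
    external <- NULL
    if (!is.null(cfg$external_expression_path)) {
      external <- list(expression = read_expression(cfg$external_expression_path),
                       survival = read_clinical(cfg$external_clinical_path))
    }
    if (isTRUE(cfg$quantile_normalize)) {
      expr <- log2_transform(quantile_normalize(expr), offset = cfg$log_offset %||% 1)
    }
  }
  sig_present <- intersect(sig$genes, rownames(expr))
  if (length(sig_present) < 3) stop("signature genes absent from expression matrix")
  expr_sig <- expr[sig_present, , drop = FALSE]

  # --- stage: clustering & scoring ----------------------------------------
  sel <- select_cluster_count(expr_sig, k_min = cfg$k_min, k_max = cfg$k_max,
                              n_resamples = cfg$n_resamples,
                              subsample_fraction = cfg$subsample_fraction,
                              seed = cfg$seed)
  labeling <- label_clusters(sel$results[[as.character(sel$k)]]$labels, expr_sig)
  scores <- enrichment_score(expr, sig, method = cfg$score_method)

  # --- stage: survival screen ---------------------------------------------
  surv_clean <- clean_followup(surv, min_days = cfg$min_days,
                               horizon_years = cfg$horizon_years)
  comparison <- compare_strata(labeling, surv_clean)
  comparison$cohort <- cfg$cohort_id %||% "cohort"
  screen <- screen_cohorts(comparison, p_threshold = cfg$p_threshold,
                           min_samples = cfg$min_samples)
  adj <- tryCatch(
    clinical_adjusted_fit(scores, surv_clean, surv_clean)$coefficients,
    error = function(e) NULL)

  # --- stage: marker classification ---------------------------------------
  markers <- NULL
  st <- labeling$stratum
  hi_ids <- intersect(names(st)[st == "high"], colnames(expr))
  lo_ids <- intersect(names(st)[st == "low"], colnames(expr))
  if (!is.null(normals) && length(hi_ids) >= 2 && length(lo_ids) >= 2) {
    all_expr <- cbind(expr, normals[rownames(expr), , drop = FALSE])
    n_ids <- colnames(normals)
    res_a <- moderated_de(all_expr, hi_ids, lo_ids)
    res_b <- moderated_de(all_expr, hi_ids, n_ids)
    res_c <- moderated_de(all_expr, lo_ids, n_ids)
    cls <- classify_markers(res_a, res_b, res_c, lfc_thr = cfg$lfc_thr,
                            fdr_thr = cfg$fdr_thr)
    markers <- cls[cls$gene %in% sig_present, , drop = FALSE]
  }
  model_genes <- if (!is.null(markers) && any(markers$class != "excluded"))
    markers$gene[markers$class != "excluded"] else sig_present

  # --- stage: three-model selection on the training split -----------------
  split <- split_train_test(surv_clean, fraction = cfg$train_fraction,
                            seed = cfg$seed)
  X <- t(expr[model_genes, , drop = FALSE])
  tr <- match(split$train, surv_clean$sample_id)
  te <- match(split$test, surv_clean$sample_id)
  X_tr <- X[split$train, , drop = FALSE]
  surv_tr <- surv_clean[tr, , drop = FALSE]
  univ <- univariate_cox(X_tr, surv_tr)
  stab <- coxnet_stability(X_tr, surv_tr, n_runs = cfg$n_runs,
                           n_folds = cfg$n_folds,
                           threshold = cfg$stability_threshold,
                           alpha = cfg$alpha, nlambda = cfg$nlambda,
                           seed = cfg$seed)
  vimp <- rsf_importance(X_tr, surv_tr, ntree_grid = cfg$rsf_ntree,
                         B = cfg$rsf_B, k = cfg$vimp_k, seed = cfg$seed)
  top <- intersect_top_genes(univ, stab, vimp, k = cfg$vimp_k,
                             p_threshold = cfg$p_threshold)

  # --- stage: validation ---------------------------------------------------
  validation <- NULL
  final_genes <- if (nrow(top) > 0) top$gene else
    stab$gene[stab$stable]  # fall back to the stable set
  if (length(final_genes) >= 1) {
    mv <- cox_fit(scale(X_tr[, final_genes, drop = FALSE]), surv_tr)
    model <- risk_model(final_genes, mv$coefficients$beta)
    times_d <- cfg$auc_times_years * 365
    times_ok <- function(sv) times_d[times_d < max(sv$time_days)]
    validation <- validate_external(
      model, t(X[split$test, , drop = FALSE]), surv_clean[te, , drop = FALSE],
      times = times_ok(surv_clean[te, , drop = FALSE]), cohort_id = "internal_test")
    if (!is.null(external)) {
      ve <- validate_external(model, external$expression, external$survival,
                              times = times_ok(external$survival),
                              cohort_id = "external")
      common <- intersect(names(validation), names(ve))
      validation <- rbind(validation[common], ve[common])
    }
    attr(validation, "model") <- model
  }

  report <- list(
    version = as.character(utils::packageVersion("panopsig")),
    config = cfg, config_hash = config_hash(cfg),
    k = sel$k, ch_index = sel$ch_index,
    strata = data.frame(sample_id = names(st), stratum = as.character(st),
                        stringsAsFactors = FALSE),
    scores = data.frame(sample_id = names(scores), es = as.numeric(scores),
                        stringsAsFactors = FALSE),
    comparison = comparison,
    screen_selected = nrow(screen$selected) > 0,
    adjusted_fit = adj,
    markers = markers,
    stability = as.data.frame(stab),
    vimp = as.data.frame(vimp),
    top = as.data.frame(top),
    validation = validation
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> k = %d; screen %s; Top set: %s\n", x$k,
              if (x$screen_selected) "selected" else "excluded",
              if (nrow(x$top)) paste(x$top$gene, collapse = ", ") else "(empty)"))
  if (!is.null(x$validation)) print(x$validation, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a pipeline report (JSON + TSV bundle)
#'
#' `report.json` holds the full report (config, hash, tool version, tables);
#' each table is also written as TSV.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  json$config$simulate$signature <- NULL  # not serializable; regenerable
  class(json) <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  for (nm in c("strata", "scores", "comparison", "markers", "stability",
               "vimp", "top", "validation")) {
    tb <- report[[nm]]
    if (!is.null(tb) && is.data.frame(tb))
      utils::write.table(tb, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
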