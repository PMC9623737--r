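# Train/test splitting, Harrell's concordance, IPCW time-dependent AUC,
# cross-validation harness, and external-cohort validation.

#' Event-stratified train/test split
#'
#' @param surv Survival data.frame (`sample_id`, `event`).
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List: `train` and `test` sample-id character vectors (disjoint,
#'   exhaustive; events and non-events split separately).
#' @export
split_train_test <- function(surv, fraction = 0.8, seed = 1L) {
  stopifnot(nrow(surv) >= 5, fraction > 0, fraction < 1)
  with_seed(seed, {
    train <- character()
    for (e in unique(surv$event)) {
      ids <- surv$sample_id[surv$event == e]
      if (length(ids) < 2) stop("event stratum too small to split")
      n_tr <- round(fraction * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      train <- c(train, sample(ids, n_tr))
    }
    list(train = sort(train), test = sort(setdiff(surv$sample_id, train)))
  })
}

#' Harrell's concordance index
#'
#' A pair is evaluable when the subject with the earlier observed time had an
#' event; the pair is concordant when that subject carries the higher risk
#' score. Tied risks count 0.5. Time-tied pairs are not evaluable.
#'
#' @param risk Numeric risk scores (higher = worse).
#' @param surv Survival data.frame aligned with `risk`.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_ci <- function(risk, surv) {
  stopifnot(length(risk) == nrow(surv), all(is.finite(risk)))
  t <- surv$time_days
  e <- surv$event
  n <- length(t)
  # vectorized over ordered pairs (i earlier than j, i an event)
  conc <- 0
  total <- 0
  for (i in which(e == 1)) {
    later <- t > t[i]
    if (!any(later)) next
    total <- total + sum(later)
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (total == 0) stop("no evaluable pairs")
  conc / total
}

#' Time-dependent AUC (IPCW, cumulative cases / dynamic controls)
#'
#' At horizon `t`, cases are subjects with an observed event by `t` (weighted
#' by the inverse censoring-survival at their event time) and controls are
#' subjects still under observation past `t` (weighted by the inverse
#' censoring-survival at `t`). The AUC is the weighted probability that a
#' random case outranks a random control (ties 0.5). With no censoring before
#' `t` the weights collapse to 1 and the value equals the Mann-Whitney AUC of
#' risk against the event-by-t indicator.
#'
#' @param risk Numeric risk scores (higher = worse).
#' @param surv Survival data.frame aligned with `risk`.
#' @param times Numeric horizons in the same units as `time_days`.
#' @return Named numeric vector of AUC(t).
#' @export
auc_at <- function(risk, surv, times) {
  stopifnot(length(risk) == nrow(surv), all(is.finite(risk)))
  t <- surv$time_days
  e <- surv$event
  if (any(times <= 0) || any(times > max(t)))
    stop("requested times must lie within follow-up range")
  # censoring KM: G(t) = P(C > t); left-continuous evaluation for cases
  cens_fit <- survival::survfit(survival::Surv(t, 1 - e) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  G_minus <- function(u) vapply(u, function(x) G(max(x - 1e-9, 0)), numeric(1))
  out <- vapply(times, function(tt) {
    case <- which(t <= tt & e == 1)
    ctrl <- which(t > tt)
    if (length(case) == 0 || length(ctrl) == 0)
      stop("no cases or no controls at t = ", tt)
    w_case <- 1 / G_minus(t[case])
    w_ctrl <- rep(1 / G(tt), length(ctrl))
    num <- 0
    for (k in seq_along(case)) {
      cmp <- sign(risk[case[k]] - risk[ctrl]) / 2 + 0.5  # 1, 0.5, 0
      num <- num + w_case[k] * sum(w_ctrl * cmp)
    }
    num / (sum(w_case) * sum(w_ctrl))
  }, numeric(1))
  names(out) <- as.character(times)
  out
}

#' Cross-validated survival-model performance
#'
#' Event-stratified fold assignment; `fit_fun(X_train, surv_train)` must
#' return a function mapping a covariate matrix to risk scores, which is
#' evaluated on the held-out fold by Harrell's concordance.
#'
#' @param X Samples x covariates matrix.
#' @param surv Survival data.frame aligned with `X` rows.
#' @param fit_fun Model-fitting closure (see Details).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List: `fold_ci` (per-fold concordance), `mean_ci`, `folds`
#'   (assignment vector).
#' @export
cross_validate <- function(X, surv, fit_fun, n_folds = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == nrow(surv), n_folds >= 2, n_folds <= n)
  folds <- with_seed(seed, stratified_folds(surv$event, n_folds))
  fold_ci <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    if (sum(surv$event[!tr]) == 0) return(NA_real_)
    predict_risk <- fit_fun(X[tr, , drop = FALSE], surv[tr, , drop = FALSE])
    harrell_ci(predict_risk(X[!tr, , drop = FALSE]), surv[!tr, , drop = FALSE])
  }, numeric(1))
  list(fold_ci = fold_ci, mean_ci = mean(fold_ci, na.rm = TRUE), folds = folds)
}

# event-stratified fold labels (uses the current RNG stream)
stratified_folds <- function(event, n_folds) {
  folds <- integer(length(event))
  for (e in unique(event)) {
    idx <- which(event == e)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Linear risk model
#'
#' A gene-coefficient container scoring new cohorts by `z(x) %*% beta` after
#' within-cohort z-scoring.
#'
#' @param genes Character vector of model genes.
#' @param beta Numeric coefficients parallel to `genes`.
#' @return A `risk_model`.
#' @export
risk_model <- function(genes, beta) {
  stopifnot(length(genes) == length(beta))
  structure(list(genes = as.character(genes), beta = as.numeric(beta)),
            class = "risk_model")
}

#' Score a cohort with a linear risk model
#'
#' Genes are z-scored within the cohort; model genes missing from the cohort
#' are imputed at 0 (the post-z-scoring cohort mean) and counted.
#'
#' @param model A `risk_model`.
#' @param expr Genes x samples matrix.
#' @param max_missing Maximum tolerated fraction of missing model genes.
#' @return Named risk vector with attribute `n_missing`.
#' @export
risk_score <- function(model, expr, max_missing = 0.5) {
  present <- model$genes %in% rownames(expr)
  if (mean(!present) > max_missing)
    stop(sprintf("%d/%d model genes missing from cohort (> %.0f%%)",
                 sum(!present), length(model$genes), 100 * max_missing))
  g <- model$genes[present]
  z <- t(scale(t(expr[g, , drop = FALSE])))
  z[is.na(z)] <- 0  # zero-variance genes contribute nothing
  s <- as.vector(crossprod(z, model$beta[present]))
  names(s) <- colnames(expr)
  attr(s, "n_missing") <- sum(!present)
  s
}

#' Validate a risk model on an external cohort
#'
#' @param model A `risk_model` (or a fitting result with `genes`/`beta`).
#' @param expr External genes x samples matrix (preprocessed: quantile
#'   normalized, log2).
#' @param surv External survival data.frame (`sample_id` matching columns).
#' @param times AUC horizons in days (optional).
#' @param cohort_id Label carried into the report.
#' @return A one-row `validation_report` data.frame: `cohort`, `n`, `events`,
#'   `n_missing_genes`, `ci`, plus one `auc_<t>` column per horizon.
#' @export
validate_external <- function(model, expr, surv, times = NULL,
                              cohort_id = "external") {
  ids <- intersect(colnames(expr), surv$sample_id)
  if (length(ids) == 0) stop("no overlapping samples between expr and surv")
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]
  s <- risk_score(model, expr[, ids, drop = FALSE])
  rep_ <- data.frame(cohort = cohort_id, n = length(ids),
                     events = sum(surv$event),
                     n_missing_genes = attr(s, "n_missing"),
                     ci = harrell_ci(as.numeric(s), surv),
                     stringsAsFactors = FALSE)
  if (!is.null(times)) {
    auc <- auc_at(as.numeric(s), surv, times)
    for (i in seq_along(times)) rep_[[paste0("auc_", times[i])]] <- auc[i]
  }
  rep_
}
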