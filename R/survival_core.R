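# Follow-up cleaning, Kaplan-Meier, log-rank, Cox models, proportional-hazards
# diagnostics, and the cohort-screening rules used to pick cancers where the
# signature strata carry significant prognostic value.

#' Clean follow-up times
#'
#' Removes patients with less than `min_days` of follow-up and
#' administratively censors everyone beyond the horizon (default 10 years =
#' 3650 days): time truncated to the horizon, event set to 0.
#'
#' @param surv Survival data.frame with `time_days` and `event`.
#' @param min_days Minimum follow-up in days (default 1).
#' @param horizon_years Censoring horizon in years (365-day years).
#' @return Cleaned survival data.frame.
#' @export
clean_followup <- function(surv, min_days = 1, horizon_years = 10) {
  stopifnot(all(c("time_days", "event") %in% names(surv)))
  out <- surv[surv$time_days >= min_days, , drop = FALSE]
  if (nrow(out) == 0L) stop("no patients left after follow-up cleaning")
  horizon <- horizon_years * 365
  over <- out$time_days > horizon
  out$event[over] <- 0
  out$time_days[over] <- horizon
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function.
#'
#' @param surv Survival data.frame (`time_days`, `event`).
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (S(t), non-increasing, S(0) = 1 implicitly).
#' @export
km_estimate <- function(surv) {
  stopifnot(nrow(surv) >= 1)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = surv)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected over pooled risk sets, 1 df chi-square.
#'
#' @param surv_a,surv_b Survival data.frames for the two groups.
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(surv_a, surv_b) {
  stopifnot(nrow(surv_a) > 0, nrow(surv_b) > 0)
  if (sum(surv_a$event) + sum(surv_b$event) == 0)
    stop("no events in either group; log-rank undefined")
  df <- rbind(
    data.frame(time_days = surv_a$time_days, event = surv_a$event, g = 0L),
    data.frame(time_days = surv_b$time_days, event = surv_b$event, g = 1L)
  )
  sd_ <- survival::survdiff(survival::Surv(time_days, event) ~ g, data = df)
  list(chisq = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood (via
#' [survival::coxph()]); Wald confidence intervals.
#'
#' @param X Covariate matrix (samples x covariates) or data.frame.
#' @param surv Survival data.frame aligned with `X` rows.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: data.frame-like list with `coefficients` table (beta,
#'   HR, CI bounds, se, p), `loglik`, `ties`, and the underlying `model`.
#' @export
cox_fit <- function(X, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == nrow(surv))
  const <- apply(X, 2L, function(v) stats::var(v) == 0)
  if (any(const)) stop("constant covariate(s): ",
                       paste(colnames(X)[const], collapse = ", "))
  dat <- data.frame(time_days = surv$time_days, event = surv$event, X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  s <- summary(fit)
  co <- data.frame(
    term = rownames(s$coefficients),
    beta = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(!is.finite(co$beta)) || any(abs(co$beta) > 15))
    warning("extreme Cox coefficients; possible monotone likelihood/separation")
  structure(list(coefficients = co, loglik = fit$loglik[2], ties = ties,
                 model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> ties = %s, partial logLik = %.3f\n", x$ties, x$loglik))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Correlates each covariate's scaled Schoenfeld residuals with transformed
#' event time (score-type test, via [survival::cox.zph()]).
#'
#' @param fit A `cox_fit`.
#' @param time_transform `"km"` (default) or `"identity"`.
#' @return data.frame: `term`, `chisq`, `df`, `p`, with the GLOBAL row last.
#' @export
ph_test <- function(fit, time_transform = c("km", "identity")) {
  stopifnot(inherits(fit, "cox_fit"))
  time_transform <- match.arg(time_transform)
  if (fit$model$nevent < 2) stop("need >= 2 events for the PH diagnostic")
  z <- survival::cox.zph(fit$model, transform = time_transform)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare high vs low signature strata
#'
#' Univariate Cox on the high-vs-low indicator (medium excluded) gives the
#' hazard ratio; the primary p-value is the log-rank test (the Cox Wald p is
#' also reported). HR > 1 means the high stratum does worse.
#'
#' @param labeling A `cluster_labeling` (or per-sample factor/character of
#'   low/medium/high strata, named by sample).
#' @param surv Survival data.frame with `sample_id`.
#' @return A one-row data.frame: `n_high` (N1), `n_low` (N2), `events_high`,
#'   `events_low`, `hr`, `ci_lower`, `ci_upper`, `p` (log-rank), `p_wald`,
#'   `flag` (`"ok"` or `"zero_events"`).
#' @export
compare_strata <- function(labeling, surv) {
  stratum <- if (inherits(labeling, "cluster_labeling")) labeling$stratum else labeling
  stopifnot(!is.null(names(stratum)), all(surv$sample_id %in% names(stratum)) ||
              all(names(stratum) %in% surv$sample_id))
  surv <- surv[surv$sample_id %in% names(stratum), , drop = FALSE]
  st <- as.character(stratum[surv$sample_id])
  hi <- surv[st == "high", , drop = FALSE]
  lo <- surv[st == "low", , drop = FALSE]
  if (nrow(hi) == 0 || nrow(lo) == 0) stop("both strata must be non-empty")
  out <- data.frame(n_high = nrow(hi), n_low = nrow(lo),
                    events_high = sum(hi$event), events_low = sum(lo$event),
                    hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                    p = NA_real_, p_wald = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  if (out$events_high == 0 || out$events_low == 0) {
    out$flag <- "zero_events"
    return(out)
  }
  both <- rbind(hi, lo)
  ind <- matrix(as.numeric(c(rep(1, nrow(hi)), rep(0, nrow(lo)))),
                dimnames = list(NULL, "high_vs_low"))
  cf <- cox_fit(ind, both)
  lr <- logrank_test(hi, lo)
  out$hr <- cf$coefficients$hr
  out$ci_lower <- cf$coefficients$ci_lower
  out$ci_upper <- cf$coefficients$ci_upper
  out$p <- lr$p
  out$p_wald <- cf$coefficients$p
  out
}

#' Screen cohort comparisons for prognostic relevance
#'
#' Pre-excludes comparisons with zero events in either stratum, then keeps
#' those with `p < p_threshold` and `n_high + n_low > min_samples`.
#'
#' @param comparisons data.frame of [compare_strata()] rows (one per cohort;
#'   a `cohort` id column is carried through if present).
#' @param p_threshold Significance cutoff (default 0.05).
#' @param min_samples Minimum combined stratum size, exclusive (default 100).
#' @return List: `selected` (rows passing), `excluded` (rows with a `reason`
#'   column: `zero_events`, `p`, or `size`).
#' @export
screen_cohorts <- function(comparisons, p_threshold = 0.05, min_samples = 100) {
  reason <- rep(NA_character_, nrow(comparisons))
  zero <- comparisons$flag == "zero_events" |
    comparisons$events_high == 0 | comparisons$events_low == 0
  reason[zero] <- "zero_events"
  small <- !zero & (comparisons$n_high + comparisons$n_low) <= min_samples
  reason[small] <- "size"
  insig <- !zero & !small & !(comparisons$p < p_threshold)
  reason[insig] <- "p"
  keep <- is.na(reason)
  excluded <- comparisons[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(selected = comparisons[keep, , drop = FALSE], excluded = excluded)
}

#' Clinical-covariate-adjusted Cox model for a signature score
#'
#' Multivariate Cox including the per-sample enrichment score alongside
#' clinical covariates (age numeric; gender one-hot dropping the first level;
#' stage/grade as ordered integers when parseable).
#'
#' @param score Named numeric vector of per-sample scores.
#' @param clinical data.frame with `sample_id` plus covariates
#'   (`age`, `gender`, `stage` as available).
#' @param surv Survival data.frame with `sample_id`.
#' @return A `cox_fit`; the score's row in `coefficients` is named `score`.
#' @export
clinical_adjusted_fit <- function(score, clinical, surv) {
  stopifnot(!is.null(names(score)))
  ids <- intersect(surv$sample_id, names(score))
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  X <- data.frame(score = as.numeric(score[ids]))
  if ("age" %in% names(clinical)) X$age <- as.numeric(clinical$age)
  if ("gender" %in% names(clinical)) {
    lev <- sort(unique(as.character(clinical$gender)))
    for (l in lev[-1]) X[[paste0("gender_", l)]] <- as.numeric(clinical$gender == l)
  }
  if ("stage" %in% names(clinical)) {
    stg <- suppressWarnings(as.numeric(gsub("[^0-9]", "", as.character(clinical$stage))))
    if (!anyNA(stg)) X$stage <- stg
  }
  qr_rank <- qr(scale(as.matrix(X), scale = FALSE))$rank
  if (qr_rank < ncol(X)) stop("collinear covariate encoding")
  cox_fit(as.matrix(X), surv)
}
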