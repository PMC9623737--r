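# Two-step marker filter: (1) moderated differential expression classifying
# primary / secondary / excluded markers; (2) consensus of univariate Cox,
# repeated elastic-net Cox stability selection, and random-survival-forest
# importance, intersected into the "Top" prognostic gene set.

#' Moderated two-group differential expression
#'
#' Per-gene linear model with empirical-Bayes variance shrinkage (limma
#' lmFit/eBayes); `logFC` is `mean(group1) - mean(group2)` in log2 units.
#' With `shrink = FALSE` the ordinary equal-variance two-sample t-statistic
#' is returned (the zero-prior-df limit of the moderated t).
#'
#' @param expr Genes x samples log2 matrix.
#' @param group1,group2 Sample-id (column) vectors, >= 2 each, disjoint.
#' @param shrink Apply empirical-Bayes shrinkage (default TRUE).
#' @return data.frame: `gene`, `logFC`, `t`, `p`, `fdr` (Benjamini-Hochberg).
#' @export
moderated_de <- function(expr, group1, group2, shrink = TRUE) {
  stopifnot(length(group1) >= 2, length(group2) >= 2,
            length(intersect(group1, group2)) == 0,
            all(c(group1, group2) %in% colnames(expr)))
  m <- expr[, c(group1, group2), drop = FALSE]
  grp <- c(rep(1, length(group1)), rep(0, length(group2)))
  design <- cbind(Intercept = 1, group1_vs_group2 = grp)
  fit <- limma::lmFit(m, design)
  if (shrink) {
    fit <- limma::eBayes(fit)
    tt <- limma::topTable(fit, coef = "group1_vs_group2", number = Inf,
                          sort.by = "none")
    out <- data.frame(gene = rownames(m), logFC = tt$logFC, t = tt$t,
                      p = tt$P.Value, fdr = tt$adj.P.Val,
                      stringsAsFactors = FALSE)
  } else {
    se <- fit$stdev.unscaled[, "group1_vs_group2"] * fit$sigma
    tstat <- fit$coefficients[, "group1_vs_group2"] / se
    p <- 2 * stats::pt(abs(tstat), df = fit$df.residual, lower.tail = FALSE)
    out <- data.frame(gene = rownames(m),
                      logFC = fit$coefficients[, "group1_vs_group2"],
                      t = tstat, p = p, fdr = bh_adjust(p),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`min cummin(p * m / rank)`).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, pointwise >= input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify primary / secondary / excluded markers
#'
#' A gene is differentially expressed (DE) in a comparison when
#' `|logFC| > lfc_thr` and `fdr < fdr_thr`. Genes DE in comparison (a)
#' high-vs-low are `primary`; genes not primary but DE in (b) high-vs-normal
#' or (c) low-vs-normal are `secondary`; the rest are `excluded`.
#'
#' @param res_a,res_b,res_c [moderated_de()] results sharing a gene universe
#'   (a: high vs low, b: high vs normal, c: low vs normal).
#' @param lfc_thr Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_thr FDR threshold (default 0.05).
#' @return data.frame: `gene`, `class` (primary/secondary/excluded), plus
#'   per-comparison DE flags `de_a`, `de_b`, `de_c`.
#' @export
classify_markers <- function(res_a, res_b, res_c, lfc_thr = 0.5, fdr_thr = 0.05) {
  if (!identical(res_a$gene, res_b$gene) || !identical(res_a$gene, res_c$gene))
    stop("DE results must share the same gene universe (same order)")
  de <- function(r) abs(r$logFC) > lfc_thr & r$fdr < fdr_thr
  a <- de(res_a); b <- de(res_b); cc <- de(res_c)
  cls <- ifelse(a, "primary", ifelse(b | cc, "secondary", "excluded"))
  data.frame(gene = res_a$gene, class = cls, de_a = a, de_b = b, de_c = cc,
             stringsAsFactors = FALSE)
}

#' Per-gene univariate Cox table
#'
#' One Cox model per gene on the cleaned survival data, with BH-adjusted
#' Wald p-values.
#'
#' @param X Samples x genes matrix.
#' @param surv Survival data.frame aligned with rows of `X`.
#' @return data.frame: `gene`, `beta`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `fdr`.
#' @export
univariate_cox <- function(X, surv) {
  X <- as.matrix(X)
  rows <- lapply(colnames(X), function(g) {
    cf <- cox_fit(X[, g, drop = FALSE], surv)$coefficients
    data.frame(gene = g, beta = cf$beta, hr = cf$hr, ci_lower = cf$ci_lower,
               ci_upper = cf$ci_upper, p = cf$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Elastic-net Cox regularization path
#'
#' Cyclic coordinate descent on the penalized partial likelihood
#' (`lambda * [alpha * L1 + (1 - alpha)/2 * L2]`), log-spaced lambda grid
#' from the smallest lambda zeroing every coefficient (via [glmnet::glmnet()];
#' covariates standardized internally, coefficients reported on the
#' standardized scale).
#'
#' @param X Samples x genes matrix.
#' @param surv Survival data.frame aligned with rows of `X`.
#' @param alpha Elastic-net mixing (1 = lasso; default 0.5).
#' @param nlambda Grid size.
#' @param lambda Optional explicit grid.
#' @return List: `lambda`, `beta` (genes x lambda coefficient matrix on the
#'   standardized scale), `fit` (glmnet object).
#' @export
coxnet_path <- function(X, surv, alpha = 0.5, nlambda = 100, lambda = NULL) {
  X <- as.matrix(X)
  y <- survival::Surv(surv$time_days, surv$event)
  Xs <- scale(X)
  fit <- glmnet::glmnet(Xs, y, family = "cox", alpha = alpha,
                        nlambda = nlambda, lambda = lambda,
                        standardize = FALSE)
  list(lambda = fit$lambda, beta = as.matrix(fit$beta), fit = fit)
}

#' Stability selection for elastic-net Cox
#'
#' Runs the cross-validated elastic-net Cox model `n_runs` times, each with
#' its own fold assignment seeded from the master seed; per run, lambda is
#' chosen to maximize the mean cross-validated Harrell concordance, and a
#' gene is "selected" when its coefficient is nonzero at that lambda.
#' Selection frequencies, mean nonzero coefficients, and sign consistency are
#' aggregated; genes with frequency >= `threshold` are flagged stable.
#'
#' @param X Samples x genes matrix.
#' @param surv Survival data.frame aligned with rows of `X`.
#' @param n_runs Number of repeated runs (default 100).
#' @param n_folds Cross-validation folds (default 5).
#' @param threshold Stability frequency threshold, inclusive (default 0.5).
#' @param alpha Elastic-net mixing (default 0.5).
#' @param nlambda Lambda grid size (default 50).
#' @param seed Master seed; run r uses `seed + r`.
#' @return A `stability_profile`: data.frame `gene`, `frequency`,
#'   `mean_beta` (mean nonzero standardized coefficient), `sign_consistency`,
#'   `stable`; attributes `n_runs`, `threshold`, `best_run` (coefficients of
#'   the run with the highest CV concordance).
#' @export
coxnet_stability <- function(X, surv, n_runs = 100, n_folds = 5,
                             threshold = 0.5, alpha = 0.5, nlambda = 50,
                             seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= n_folds, n == nrow(surv))
  y <- survival::Surv(surv$time_days, surv$event)
  Xs <- scale(X)
  genes <- colnames(X)
  sel <- matrix(0, length(genes), n_runs, dimnames = list(genes, NULL))
  coefs <- matrix(0, length(genes), n_runs, dimnames = list(genes, NULL))
  best_cvm <- -Inf
  best_coef <- NULL
  for (r in seq_len(n_runs)) {
    foldid <- with_seed(seed + r, stratified_folds(surv$event, n_folds))
    cv <- glmnet::cv.glmnet(Xs, y, family = "cox", alpha = alpha,
                            nlambda = nlambda, foldid = foldid,
                            type.measure = "C", standardize = FALSE)
    b <- as.vector(stats::coef(cv, s = "lambda.min"))
    sel[, r] <- b != 0
    coefs[, r] <- b
    cvm <- max(cv$cvm)
    if (cvm > best_cvm) { best_cvm <- cvm; best_coef <- b }
  }
  freq <- rowMeans(sel)
  mean_beta <- vapply(seq_along(genes), function(i) {
    nz <- coefs[i, sel[i, ] == 1]
    if (length(nz)) mean(nz) else 0
  }, numeric(1))
  sign_cons <- vapply(seq_along(genes), function(i) {
    nz <- coefs[i, sel[i, ] == 1]
    if (!length(nz)) return(NA_real_)
    max(mean(nz > 0), mean(nz < 0))
  }, numeric(1))
  out <- data.frame(gene = genes, frequency = freq, mean_beta = mean_beta,
                    sign_consistency = sign_cons,
                    stable = freq >= threshold, stringsAsFactors = FALSE)
  if (!any(out$stable)) message("no gene reached the stability threshold")
  structure(out, n_runs = n_runs, threshold = threshold,
            best_run = stats::setNames(as.vector(best_coef), genes),
            best_cv_ci = best_cvm, class = c("stability_profile", "data.frame"))
}

# risk from a ranger survival forest: ensemble cumulative hazard summed over
# the event-time grid
ranger_risk <- function(fit, X) {
  pr <- stats::predict(fit, data = as.data.frame(X))
  rowSums(pr$chf)
}

#' Random-survival-forest fit with permutation importance
#'
#' Survival forest with log-rank splitting (via [ranger::ranger()]).
#' Hyperparameters (`mtry`, `num_trees`, `min_node_size`) are chosen by
#' cross-validated concordance over a grid; permutation variable importance
#' of the refit forest gets confidence intervals from `B` subsample
#' (`subsample_ratio`, default 0.632) refits. Ranks break ties by the lower
#' confidence bound.
#'
#' @param X Samples x genes matrix.
#' @param surv Survival data.frame aligned with rows of `X`.
#' @param mtry_grid,ntree_grid,nodesize_grid Hyperparameter grids.
#' @param n_folds CV folds for the grid search (default 3).
#' @param B Subsample replicates for importance CIs (default 100).
#' @param subsample_ratio Fraction of samples per replicate.
#' @param k Size of the reported top set (default 10; truncated to the number
#'   of genes).
#' @param seed Integer seed.
#' @return A `vimp_profile`: data.frame `gene`, `importance`, `ci_lower`,
#'   `ci_upper`, `rank`, `top` (rank <= k); attributes `best_params`,
#'   `forest` (the refit ranger object), `cv_ci`.
#' @export
rsf_importance <- function(X, surv,
                           mtry_grid = NULL, ntree_grid = 500,
                           nodesize_grid = c(5, 15),
                           n_folds = 3, B = 100, subsample_ratio = 0.632,
                           k = 10, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(mtry_grid)) mtry_grid <- unique(pmax(1, round(c(sqrt(p), p / 3))))
  if (min(nodesize_grid) >= nrow(X)) stop("n smaller than nodesize")
  dat <- data.frame(time_days = surv$time_days, event = surv$event, X,
                    check.names = FALSE)
  grid <- expand.grid(mtry = mtry_grid, num_trees = ntree_grid,
                      min_node_size = nodesize_grid)
  fit_one <- function(d, mtry, num_trees, min_node_size, importance = "none",
                      s) {
    ranger::ranger(survival::Surv(time_days, event) ~ ., data = d,
                   mtry = mtry, num.trees = num_trees,
                   min.node.size = min_node_size, splitrule = "logrank",
                   importance = importance, seed = s, num.threads = 1)
  }
  # single-combination grids need no search
  cv_scores <- if (nrow(grid) == 1L) NA_real_ else vapply(seq_len(nrow(grid)), function(gi) {
    cv <- cross_validate(X, surv, function(Xtr, str) {
      d <- data.frame(time_days = str$time_days, event = str$event, Xtr,
                      check.names = FALSE)
      f <- fit_one(d, grid$mtry[gi], grid$num_trees[gi],
                   grid$min_node_size[gi], s = seed + gi)
      function(Xte) ranger_risk(f, Xte)
    }, n_folds = n_folds, seed = seed + 1000L * gi)
    cv$mean_ci
  }, numeric(1))
  best <- if (nrow(grid) == 1L) grid else grid[which.max(cv_scores), ]
  forest <- fit_one(dat, best$mtry, best$num_trees, best$min_node_size,
                    importance = "permutation", s = seed)
  imp <- forest$variable.importance[colnames(X)]

  m <- max(2L, floor(subsample_ratio * nrow(X)))
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(X), m)
      f <- fit_one(dat[idx, , drop = FALSE], best$mtry, best$num_trees,
                   best$min_node_size, importance = "permutation",
                   s = seed + b)
      f$variable.importance[colnames(X)]
    }, numeric(p))
  })
  ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975))
  ord <- order(-imp, -ci[1, ])  # ties toward higher lower bound
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  k_eff <- min(k, p)
  out <- data.frame(gene = colnames(X), importance = unname(imp),
                    ci_lower = ci[1, ], ci_upper = ci[2, ], rank = rk,
                    top = rk <= k_eff, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, best_params = best, forest = forest,
            cv_ci = if (all(is.na(cv_scores))) NA_real_ else max(cv_scores),
            class = c("vimp_profile", "data.frame"))
}

#' Intersect the three survival models into the "Top" gene set
#'
#' `Top = {univariate BH-adjusted p < p_threshold}` intersected with
#' `{stable genes whose mean elastic-net coefficient sign matches the
#' univariate direction}` and `{VIMP rank <= k}`. The direction of effect
#' (detrimental HR > 1 / beneficial HR < 1) is recorded per gene.
#'
#' @param univariate [univariate_cox()] table.
#' @param stability A `stability_profile`.
#' @param vimp A `vimp_profile`.
#' @param k VIMP rank cutoff (default 10).
#' @param p_threshold Univariate adjusted-p cutoff (default 0.05).
#' @return A `top_gene_set`: data.frame `gene`, `direction`
#'   (detrimental/beneficial), `univariate_hr`, `stability_frequency`,
#'   `vimp_rank`; attribute `support` lists the per-model gene sets. Empty
#'   (0-row) when the intersection is empty.
#' @export
intersect_top_genes <- function(univariate, stability, vimp, k = 10,
                                p_threshold = 0.05) {
  universe <- univariate$gene
  if (!setequal(universe, stability$gene) || !setequal(universe, vimp$gene))
    stop("the three models must share a gene universe")
  u_set <- univariate$gene[univariate$fdr < p_threshold]
  uni_sign <- stats::setNames(sign(univariate$beta), univariate$gene)
  s_ok <- stability$stable &
    sign(stability$mean_beta) == uni_sign[stability$gene]
  s_set <- stability$gene[s_ok]
  v_set <- vimp$gene[vimp$rank <= min(k, nrow(vimp))]
  top <- intersect(intersect(u_set, s_set), v_set)
  if (length(top) == 0) message("empty Top set: no gene supported by all three models")
  out <- data.frame(
    gene = top,
    direction = ifelse(uni_sign[top] > 0, "detrimental", "beneficial"),
    univariate_hr = univariate$hr[match(top, univariate$gene)],
    stability_frequency = stability$frequency[match(top, stability$gene)],
    vimp_rank = vimp$rank[match(top, vimp$gene)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, support = list(univariate = u_set, stability = s_set,
                                vimp = v_set),
            class = c("top_gene_set", "data.frame"))
}
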