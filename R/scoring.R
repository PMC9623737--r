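# Consensus clustering on the signature block, cluster-count selection by the
# Calinski-Harabasz criterion, high/medium/low stratum labeling, and
# single-sample enrichment (gsva / ssGSEA random-walk statistics).

#' Subsampled consensus clustering
#'
#' Repeatedly draws a random sample subset without replacement, clusters it
#' hierarchically (Ward, Euclidean distance on samples) into `k` groups, and
#' records pairwise co-clustering. `consensus[i, j]` is the number of times i
#' and j fell in the same cluster divided by the number of resamples drawing
#' both. Final labels come from complete-linkage clustering of
#' `1 - consensus` cut at `k`.
#'
#' @param expr_sig Signature genes x samples matrix.
#' @param k Number of clusters (>= 2).
#' @param n_resamples Number of subsampling repeats (default 5000, the
#'   production setting; tests use far fewer).
#' @param subsample_fraction Fraction of samples drawn per repeat.
#' @param inner_linkage hclust method for the per-resample clustering.
#' @param seed Integer seed.
#' @return A `consensus_result`: list with `k`, `consensus` (symmetric matrix
#'   in `[0,1]`, unit diagonal), `labels` (named integer vector),
#'   `n_resamples`, `subsample_fraction`.
#' @export
consensus_cluster <- function(expr_sig, k, n_resamples = 5000,
                              subsample_fraction = 0.8,
                              inner_linkage = "ward.D2", seed = 1L) {
  res <- consensus_cluster_multi(expr_sig, k_values = k,
                                 n_resamples = n_resamples,
                                 subsample_fraction = subsample_fraction,
                                 inner_linkage = inner_linkage, seed = seed)
  res[[as.character(k)]]
}

# Consensus matrices for several k from the same resamples: one Ward tree per
# resample, cut at every k.
consensus_cluster_multi <- function(expr_sig, k_values, n_resamples = 200,
                                    subsample_fraction = 0.8,
                                    inner_linkage = "ward.D2", seed = 1L) {
  stopifnot(is.matrix(expr_sig), n_resamples >= 1)
  n <- ncol(expr_sig)
  if (any(k_values < 2)) stop("k must be >= 2")
  if (any(k_values > n)) stop("k exceeds the number of samples")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  m <- max(2L, floor(subsample_fraction * n))
  ids <- colnames(expr_sig)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  conn <- array(0, dim = c(n, n, length(k_values)))
  draw <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      hc <- stats::hclust(stats::dist(t(expr_sig[, idx, drop = FALSE])),
                          method = inner_linkage)
      draw[idx, idx] <- draw[idx, idx] + 1
      for (ki in seq_along(k_values)) {
        cl <- stats::cutree(hc, k = k_values[ki])
        same <- outer(cl, cl, "==")
        conn[idx, idx, ki] <- conn[idx, idx, ki] + same
      }
    }
  })
  out <- lapply(seq_along(k_values), function(ki) {
    cons <- conn[, , ki] / pmax(draw, 1)
    cons[draw == 0] <- 0
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    hc_final <- stats::hclust(stats::as.dist(1 - cons), method = "complete")
    labels <- stats::cutree(hc_final, k = k_values[ki])
    names(labels) <- ids
    structure(list(k = k_values[ki], consensus = cons, labels = labels,
                   n_resamples = n_resamples,
                   subsample_fraction = subsample_fraction),
              class = "consensus_result")
  })
  names(out) <- as.character(k_values)
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d, %d samples, %d resamples (fraction %.2f)\n",
              x$k, length(x$labels), x$n_resamples, x$subsample_fraction))
  print(table(x$labels))
  invisible(x)
}

#' Calinski-Harabasz index of a partition
#'
#' Between-cluster over within-cluster dispersion, degrees-of-freedom scaled:
#' `(B / (k - 1)) / (W / (n - k))` where B and W are the between- and
#' within-cluster sums of squared Euclidean distances to centroids.
#'
#' @param x Observations x features numeric matrix.
#' @param labels Cluster assignment per observation.
#' @return The index (Inf for perfectly tight non-trivial clusters).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) stop("need 2 <= k < n for the Calinski-Harabasz index")
  grand <- colMeans(x)
  W <- 0
  B <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    W <- W + sum(sweep(xg, 2, cg)^2)
    B <- B + nrow(xg) * sum((cg - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the cluster count by the Calinski-Harabasz criterion
#'
#' Runs subsampled consensus clustering for every `k` in `k_min:k_max`
#' (sharing resamples across k) and returns the k whose consensus-derived
#' partition maximizes the Calinski-Harabasz index, evaluated by default on
#' signature expression (samples as points); `evaluate_on = "consensus"`
#' evaluates it on the consensus-matrix rows instead.
#'
#' @inheritParams consensus_cluster
#' @param k_min,k_max Candidate range (defaults 3 and 6).
#' @param evaluate_on `"expression"` (default) or `"consensus"`.
#' @return List: `k` (chosen count), `ch_index` (named vector over
#'   candidates), `results` (list of `consensus_result` per k).
#' @export
select_cluster_count <- function(expr_sig, k_min = 3, k_max = 6,
                                 n_resamples = 5000, subsample_fraction = 0.8,
                                 inner_linkage = "ward.D2",
                                 evaluate_on = c("expression", "consensus"),
                                 seed = 1L) {
  evaluate_on <- match.arg(evaluate_on)
  if (k_min > k_max) stop("k_min must be <= k_max")
  kk <- k_min:k_max
  res <- consensus_cluster_multi(expr_sig, kk, n_resamples = n_resamples,
                                 subsample_fraction = subsample_fraction,
                                 inner_linkage = inner_linkage, seed = seed)
  ch <- vapply(res, function(r) {
    if (length(unique(r$labels)) < 2) return(NA_real_)
    pts <- if (evaluate_on == "expression") t(expr_sig) else r$consensus
    calinski_harabasz(pts, r$labels)
  }, numeric(1))
  if (all(is.na(ch))) stop("all candidate partitions are degenerate")
  k_opt <- kk[which.max(ch)]
  list(k = k_opt, ch_index = ch, results = res)
}

#' Label clusters as high / medium / low signature strata
#'
#' The cluster with the highest mean signature expression becomes `high`,
#' the lowest `low`; all intermediate clusters are `medium`. Exact ties in
#' cluster means are broken toward the larger cluster, with a message.
#'
#' @param labels Named cluster assignment (from [consensus_cluster()]).
#' @param expr_sig Signature genes x samples matrix covering the samples.
#' @return A `cluster_labeling`: list with `stratum` (named per-sample factor
#'   low/medium/high), `cluster_means` (data.frame cluster, mean_expression,
#'   size, stratum).
#' @export
label_clusters <- function(labels, expr_sig) {
  cl <- sort(unique(labels))
  if (length(cl) < 3) stop("need >= 3 clusters for high/medium/low labeling")
  stopifnot(all(names(labels) %in% colnames(expr_sig)))
  means <- vapply(cl, function(g)
    mean(expr_sig[, names(labels)[labels == g], drop = FALSE]), numeric(1))
  sizes <- as.vector(table(factor(labels, levels = cl)))
  if (length(unique(means)) < length(means)) {
    if (all(means == means[1]))
      stop("all cluster means tied; strata undefined")
    message("tied cluster means; breaking ties toward the larger cluster")
  }
  # ties at either extreme go to the larger cluster
  low_i <- which(means == min(means))
  low_i <- low_i[which.max(sizes[low_i])]
  high_i <- which(means == max(means))
  high_i <- high_i[which.max(sizes[high_i])]
  stratum_by_cluster <- rep("medium", length(cl))
  stratum_by_cluster[low_i] <- "low"
  stratum_by_cluster[high_i] <- "high"
  names(stratum_by_cluster) <- as.character(cl)
  stratum <- factor(stratum_by_cluster[as.character(labels)],
                    levels = c("low", "medium", "high"))
  names(stratum) <- names(labels)
  structure(list(
    stratum = stratum,
    cluster_means = data.frame(cluster = cl, mean_expression = means,
                               size = sizes, stratum = stratum_by_cluster,
                               stringsAsFactors = FALSE)
  ), class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("<cluster_labeling>\n")
  print(x$cluster_means, row.names = FALSE)
  invisible(x)
}

# Gaussian-kernel CDF statistic per gene: z[i, j] = mean_k Phi((x_ij - x_ik)/h_i),
# bandwidth h_i = sd_i / 4. Constant genes are excluded upstream.
gauss_kcdf <- function(expr) {
  t(apply(expr, 1L, function(v) {
    h <- stats::sd(v) / 4
    vapply(v, function(x) mean(stats::pnorm((x - v) / h)), numeric(1))
  }))
}

# One-sample gsva walk: genes ordered by decreasing kcdf statistic; weight
# |p/2 - rank|^tau on set genes, uniform steps on the rest.
# ES = max positive deviation + min negative deviation (max.diff).
gsva_walk <- function(z_col, in_set, tau) {
  p <- length(z_col)
  ord <- order(z_col, decreasing = TRUE)
  r <- abs(p / 2 - seq_len(p))  # symmetric rank statistic along the ordering
  inset_ord <- in_set[ord]
  w <- ifelse(inset_ord, r^tau, 0)
  step_in <- w / sum(w)
  step_out <- ifelse(inset_ord, 0, 1 / (p - sum(in_set)))
  nu <- cumsum(step_in - step_out)
  max(c(0, nu)) + min(c(0, nu))
}

# One-sample ssGSEA walk: ranks of expression within the sample (highest
# expression = rank p), genes walked in decreasing order; integrated
# difference of the weighted in-set ECDF and the out-set ECDF.
ssgsea_walk <- function(x_col, in_set, alpha) {
  p <- length(x_col)
  r <- rank(x_col, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  inset_ord <- in_set[ord]
  w <- ifelse(inset_ord, r[ord]^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset_ord) / (p - sum(in_set))
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores
#'
#' `method = "gsva"`: per-gene expression statistics via a Gaussian-kernel
#' CDF across samples (bandwidth `sd/4`), converted per sample to a symmetric
#' rank statistic; a weighted Kolmogorov-Smirnov random walk over genes
#' ordered by that statistic yields
#' `ES = max positive deviation - max negative deviation`.
#' `method = "ssgsea"`: per-sample gene ranks; `ES` is the integrated
#' difference between the weighted ECDF of set genes (weight `rank^alpha`)
#' and the ECDF of non-set genes, optionally range-normalized across samples.
#'
#' A high score means the set sits above the rest of the transcriptome in
#' that sample (here: the PANoptosis score).
#'
#' @param expr Genes x samples matrix (log2 scale for bulk; normalized values
#'   for single cells).
#' @param signature A `gene_signature` (or character vector of genes).
#' @param method `"gsva"` or `"ssgsea"`.
#' @param tau gsva random-walk weight exponent (default 1).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param normalize Range-normalize ssGSEA scores across samples.
#' @return Named numeric vector of per-sample enrichment scores with
#'   attribute `method`.
#' @export
enrichment_score <- function(expr, signature, method = c("gsva", "ssgsea"),
                             tau = 1, alpha = 0.25, normalize = TRUE) {
  method <- match.arg(method)
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  stopifnot(is.matrix(expr))
  const <- apply(expr, 1L, function(v) stats::sd(v) == 0)
  if (method == "gsva" && any(const)) {
    warning(sum(const), " constant gene row(s) excluded from gsva scoring")
    expr <- expr[!const, , drop = FALSE]
  }
  in_set <- rownames(expr) %in% genes
  if (sum(in_set) < 2) stop("fewer than 2 signature genes present in the matrix")
  if (all(in_set)) stop("signature covers the whole matrix; no background genes")
  es <- if (method == "gsva") {
    z <- gauss_kcdf(expr)
    apply(z, 2L, gsva_walk, in_set = in_set, tau = tau)
  } else {
    raw <- apply(expr, 2L, ssgsea_walk, in_set = in_set, alpha = alpha)
    if (normalize && diff(range(raw)) > 0) raw / diff(range(raw)) else raw
  }
  names(es) <- colnames(expr)
  attr(es, "method") <- method
  es
}

#' Pairwise Pearson correlation of signature genes
#'
#' @param expr_sig Signature genes x samples matrix (>= 3 samples).
#' @return List: `r` (gene x gene correlation matrix) and `p` (two-sided
#'   t-test p-values; diagonal 0).
#' @export
signature_correlation <- function(expr_sig) {
  stopifnot(is.matrix(expr_sig), ncol(expr_sig) >= 3)
  v <- apply(expr_sig, 1L, stats::sd)
  if (any(v == 0)) stop("zero-variance gene(s): ",
                        paste(rownames(expr_sig)[v == 0], collapse = ", "))
  r <- stats::cor(t(expr_sig))
  n <- ncol(expr_sig)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(r = r, p = p)
}
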