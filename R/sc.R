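# Minimal single-cell path: library-size log-normalization, variance-
# stabilized variable-gene ranking, per-cell signature enrichment, and
# per-cell-type dot-plot statistics.

#' Library-size log-normalization of counts
#'
#' `value = log(1 + count * scale / cell_total)` (natural log by default,
#' the LogNormalize convention; `base` configurable). The zero pattern is
#' preserved exactly.
#'
#' @param counts Genes x cells non-negative count matrix.
#' @param scale Scale factor (default 10000).
#' @param base Log base (default `exp(1)`).
#' @return Normalized matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 10000, base = exp(1)) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero-total cell(s): ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  log1p(sweep(counts, 2L, scale / totals, "*")) / log(base)
}

#' Variable-gene selection (vst)
#'
#' Ranks genes by standardized variance after a mean-variance trend fit:
#' loess of log10(variance) on log10(mean) over non-constant genes, counts
#' standardized by the trend SD and clipped at `sqrt(n_cells)`, then the
#' variance of the clipped standardized counts. Returns the top `n` genes.
#'
#' @param counts Genes x cells raw count matrix.
#' @param n Number of genes to return (default 3000; all genes with a
#'   warning when fewer are available).
#' @param span loess span (default 0.3).
#' @return Character vector of gene names, ranked by decreasing
#'   standardized variance.
#' @export
variable_genes <- function(counts, n = 3000, span = 0.3) {
  stopifnot(is.matrix(counts))
  mu <- rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  usable <- mu > 0 & v > 0
  if (sum(usable) < 2) stop("not enough variable genes to fit a trend")
  lo <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = span,
                     degree = 2)
  sd_exp <- sqrt(10^stats::predict(lo))
  clip <- sqrt(ncol(counts))
  std_var <- rep(0, nrow(counts))
  names(std_var) <- rownames(counts)
  idx <- which(usable)
  for (j in seq_along(idx)) {
    i <- idx[j]
    z <- (counts[i, ] - mu[i]) / sd_exp[j]
    z <- pmin(pmax(z, -clip), clip)
    std_var[i] <- stats::var(z)
  }
  ord <- order(std_var, decreasing = TRUE)
  if (n > nrow(counts)) {
    warning("n exceeds the number of genes; returning all genes ranked")
    n <- nrow(counts)
  }
  rownames(counts)[ord[seq_len(n)]]
}

#' Per-cell signature enrichment
#'
#' ssGSEA scores per cell on normalized values (see [enrichment_score()]).
#'
#' @param norm Genes x cells normalized matrix (from [lognormalize()]).
#' @param signature A `gene_signature`.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Range-normalize across cells (default TRUE).
#' @return Named numeric vector of per-cell scores.
#' @export
per_cell_enrichment <- function(norm, signature, alpha = 0.25, normalize = TRUE) {
  enrichment_score(norm, signature, method = "ssgsea", alpha = alpha,
                   normalize = normalize)
}

#' Per-cell-type summaries (dot-plot statistics)
#'
#' Per gene and cell type: mean normalized expression and the percentage of
#' cells with a positive value. When per-cell `scores` are supplied, their
#' per-type means are reported as well.
#'
#' @param norm Genes x cells normalized matrix.
#' @param cell_types Character/factor vector of type labels per cell.
#' @param scores Optional named per-cell score vector.
#' @return List: `by_gene` (data.frame gene, cell_type, mean_expression,
#'   pct_expressing) and `by_type` (data.frame cell_type, n_cells,
#'   mean_score or NA).
#' @export
summarize_by_type <- function(norm, cell_types, scores = NULL) {
  stopifnot(length(cell_types) == ncol(norm))
  types <- unique(as.character(cell_types))
  if (any(table(cell_types) == 0)) stop("empty cell type")
  by_gene <- do.call(rbind, lapply(types, function(ty) {
    m <- norm[, cell_types == ty, drop = FALSE]
    data.frame(gene = rownames(norm), cell_type = ty,
               mean_expression = rowMeans(m),
               pct_expressing = 100 * rowMeans(m > 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  by_type <- data.frame(cell_type = types,
                        n_cells = as.vector(table(factor(cell_types, types))),
                        mean_score = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    stopifnot(length(scores) == ncol(norm))
    by_type$mean_score <- vapply(types, function(ty)
      mean(scores[cell_types == ty]), numeric(1))
  }
  list(by_gene = by_gene, by_type = by_type)
}
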