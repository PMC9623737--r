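#' Read an expression matrix (genes x samples)
#'
#' Reads a delimited text file whose first column holds gene symbols and whose
#' header holds sample identifiers. Rows with an empty gene symbol are dropped
#' (genes without symbols are excluded from all downstream analysis), and rows
#' sharing a symbol are collapsed by row-mean.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return Numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample IDs).
#' @export
read_expression <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >=1 sample")
  genes <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  keep <- nzchar(genes) & !is.na(genes)
  vals <- vals[keep, , drop = FALSE]
  genes <- genes[keep]
  if (anyDuplicated(genes)) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(vals) <- genes
  vals
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param gene_col Name of the gene-symbol column in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, gene_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Expects columns `sample_id`, `time_days`, `event` plus optional covariates
#' (`age`, `gender`, `stage`). `event` may be coded 0/1 or with text labels
#' mapped through `event_coding` (e.g. `c(Dead = 1, Alive = 0)`).
#'
#' @param path TSV file path.
#' @param event_coding Optional named numeric vector mapping text labels to
#'   0/1.
#' @return data.frame survival table.
#' @export
read_clinical <- function(path, event_coding = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "time_days", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(event_coding)) {
    ev <- event_coding[as.character(df$event)]
    if (anyNA(ev)) stop("event labels not covered by event_coding: ",
                        paste(unique(df$event[is.na(ev)]), collapse = ", "))
    df$event <- as.numeric(ev)
  }
  df$time_days <- as.numeric(df$time_days)
  if (is.character(df$event))
    stop("event must be binary 0/1 after coding (supply event_coding for text labels)")
  df$event <- as.numeric(df$event)
  if (any(df$time_days < 0, na.rm = TRUE)) stop("negative follow-up times")
  if (!all(df$event %in% c(0, 1))) stop("event must be binary 0/1 after coding")
  df
}

#' Write a clinical table as TSV
#' @param surv data.frame survival table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize samples of an expression matrix
#'
#' Forces every sample (column) to share the same distribution: the sorted
#' values of each column are replaced by the cross-sample mean of sorted
#' values; ties within a sample receive the mean of their rank targets (the
#' classic microarray algorithm, delegated to [limma::normalizeQuantiles()]).
#'
#' @param m Numeric genes x samples matrix; no missing values.
#' @return Matrix of the same shape with equalized column distributions.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 1L)
  if (anyNA(m)) stop("missing values not allowed in quantile normalization")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform and flag degenerate genes
#'
#' Applies `log2(x + offset)` and flags zero-variance genes (attribute
#' `"zero_variance"`, a character vector of gene names). Use `offset = 1` for
#' count-like inputs and `offset = 0` for data already on a positive
#' continuous scale.
#'
#' @param m Non-negative numeric matrix.
#' @param offset Pseudocount added before the log (default 1).
#' @return Transformed matrix with attribute `zero_variance`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(is.matrix(m))
  if (any(m < 0, na.rm = TRUE)) stop("negative values cannot be log2-transformed")
  out <- log2(m + offset)
  v <- apply(out, 1L, stats::var)
  attr(out, "zero_variance") <- rownames(out)[!is.na(v) & v == 0]
  out
}

#' Harmonize gene symbols through a mapping table
#'
#' Upper-cases symbols and applies an optional user-supplied old->new mapping
#' (two-column data.frame `from`, `to`); rows mapping onto an existing symbol
#' are collapsed by mean. No live lookups are performed.
#'
#' @param m Expression matrix.
#' @param map Optional data.frame with columns `from` and `to`.
#' @return Matrix with harmonized, unique rownames.
#' @export
harmonize_symbols <- function(m, map = NULL) {
  g <- toupper(rownames(m))
  if (!is.null(map)) {
    stopifnot(all(c("from", "to") %in% names(map)))
    idx <- match(g, toupper(map$from))
    g[!is.na(idx)] <- toupper(map$to[idx[!is.na(idx)]])
  }
  if (anyDuplicated(g)) {
    m <- rowsum(m, group = g, reorder = FALSE) /
      as.vector(table(factor(g, levels = unique(g))))
    g <- unique(g)
  }
  rownames(m) <- g
  m
}
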