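#' PANoptosis gene signature
#'
#' The 27-gene PANoptosis signature used throughout the package, assembled
#' from the experimental cell-death literature: cytosolic sensors and upstream
#' regulators, adaptors, and effectors of the integrated
#' pyroptosis/apoptosis/necroptosis (PANoptosis) pathway.
#'
#' @return A `gene_signature` object: list with `name`, character vector
#'   `genes` (27 unique HGNC symbols) and `roles`, a character vector
#'   parallel to `genes` with values `"sensor/upstream regulator"`,
#'   `"adaptor"` or `"effector"`.
#' @examples
#' sig <- panoptosis_signature()
#' length(sig$genes)  # 27
#' table(sig$roles)
#' @export
panoptosis_signature <- function() {
  sensors <- c("ADAR", "AIM2", "MEFV", "NLRC4", "NLRP1", "NLRP3", "NLRP9",
               "TNFRSF1A", "ZBP1")
  adaptors <- c("FADD", "PYCARD")
  effectors <- c("CASP1", "CASP10", "CASP12", "CASP2", "CASP3", "CASP4",
                 "CASP5", "CASP6", "CASP7", "CASP8", "DFNA5", "GSDMD",
                 "MLKL", "RIPK1", "RIPK3", "TNF")
  gene_signature(
    name  = "PANoptosis",
    genes = c(sensors, adaptors, effectors),
    roles = c(rep("sensor/upstream regulator", length(sensors)),
              rep("adaptor", length(adaptors)),
              rep("effector", length(effectors)))
  )
}

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene symbols (whitespace trimmed).
#' @param roles Optional character vector of per-gene role labels; defaults to
#'   `"unknown"`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes, roles = NULL) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("signature has no genes")
  if (anyDuplicated(genes)) stop("duplicate genes in signature: ",
                                 paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(roles)) roles <- rep("unknown", length(genes))
  if (length(roles) != length(genes)) stop("roles must be parallel to genes")
  structure(list(name = as.character(name)[1], genes = genes,
                 roles = as.character(roles)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes\n", x$name, length(x$genes)))
  tb <- table(x$roles)
  for (r in names(tb)) cat(sprintf("  %-26s %d\n", r, tb[[r]]))
  invisible(x)
}

#' Read a gene set from a GMT file
#'
#' Each GMT line is `name <tab> description <tab> gene1 <tab> gene2 ...`.
#' Only the first line is used. Gene symbols are whitespace-trimmed; roles can
#' be supplied via a two-column annotation table (gene, role), otherwise they
#' default to `"unknown"`.
#'
#' @param path GMT file path.
#' @param roles Optional data.frame with columns `gene` and `role`.
#' @return A `gene_signature`.
#' @export
read_signature <- function(path, roles = NULL) {
  stopifnot(file.exists(path))
  line <- readLines(path, warn = FALSE)
  line <- line[nzchar(trimws(line))]
  if (length(line) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(line[1], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3L) stop("malformed GMT line (need name, description, >=1 gene)")
  genes <- trimws(fields[-(1:2)])
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("GMT gene list is empty")
  role_vec <- NULL
  if (!is.null(roles)) {
    stopifnot(all(c("gene", "role") %in% names(roles)))
    role_vec <- roles$role[match(genes, roles$gene)]
    role_vec[is.na(role_vec)] <- "unknown"
  }
  gene_signature(fields[1], genes, role_vec)
}

#' Write a gene signature as GMT
#'
#' @param sig A `gene_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  writeLines(paste(c(sig$name, "panopsig gene set", sig$genes), collapse = "\t"),
             path)
  invisible(path)
}
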