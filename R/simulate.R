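# Synthetic cohorts with planted ground truth: a 3-level latent activity
# factor drives a correlated signature block, survival follows a proportional
# hazards model with planted coefficients, censoring is independent
# exponential tuned to a requested fraction.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Exponential censoring rate hitting the requested censored fraction: subject
# i with event rate lambda_i is censored with probability c/(c + lambda_i);
# solve mean_i c/(c + lambda_i) = censor_rate for c.
solve_censor_rate <- function(lambda, censor_rate) {
  if (censor_rate <= 0) return(0)
  f <- function(cc) mean(cc / (cc + lambda)) - censor_rate
  stats::uniroot(f, lower = min(lambda) * 1e-8, upper = max(lambda) * 1e8,
                 tol = 1e-12)$root
}

#' Simulate a bulk expression cohort with survival ground truth
#'
#' Samples carry a latent activity level in \{-1, 0, +1\} (low/medium/high).
#' Signature-gene expression is
#' `baseline + loading * delta * noise_sd * level + shared factor + noise`,
#' where the per-sample shared factor induces positive within-signature
#' correlation; background genes are baseline plus independent noise. All
#' values are on a log2-like scale. Survival times are exponential with
#' hazard `baseline_hazard * exp(sum_g beta_g * (x_g - baseline_g))` and an
#' independent exponential censoring time whose rate is solved numerically to
#' hit `censor_rate`. Matched "normal tissue" samples are drawn at the gene
#' baselines minus `tumor_shift` for signature genes.
#'
#' @param n_samples Number of tumor samples (>= 30).
#' @param n_background Number of background (non-signature) genes.
#' @param signature A `gene_signature` (default [panoptosis_signature()]).
#' @param delta Group shift in noise-SD units (0 = no group structure).
#' @param loading Per-signature-gene loading on the latent level (recycled).
#' @param shared_sd SD of the per-sample shared factor on signature genes
#'   (default 0.35: visibly positive within-signature correlation while
#'   keeping the three latent groups resolvable at `delta = 2`; the factor
#'   lies along the same all-genes direction as the group shift, so larger
#'   values trade cluster recoverability for correlation strength).
#' @param noise_sd Independent noise SD (expression units).
#' @param baseline_range Range of per-gene baselines, log2 units.
#' @param planted_genes Signature genes carrying nonzero hazard coefficients.
#' @param beta Log-hazard per expression unit for each planted gene
#'   (recycled over `planted_genes`).
#' @param baseline_hazard Baseline event rate, events/day.
#' @param censor_rate Target censored fraction in `[0, 1)`.
#' @param n_normals Number of matched normal samples.
#' @param tumor_shift Offset of tumor signature baselines over normals
#'   (log2 units); plants differential-expression truth vs normals.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `panopsig_cohort`: list with `expression` (genes x samples
#'   matrix), `survival` (data.frame: sample_id, time_days, event, age,
#'   gender, stage), `normals` (genes x normals matrix) and `truth`
#'   (generating parameters, per-sample `group_label`, per-gene `true_beta`).
#' @export
simulate_bulk_cohort <- function(n_samples,
                                 n_background = 500,
                                 signature = panoptosis_signature(),
                                 delta = 2,
                                 loading = 1,
                                 shared_sd = 0.35,
                                 noise_sd = 1,
                                 baseline_range = c(4, 9),
                                 planted_genes = character(),
                                 beta = 0.8,
                                 baseline_hazard = 1 / 1000,
                                 censor_rate = 0.3,
                                 n_normals = 30,
                                 tumor_shift = 0,
                                 seed = 1L) {
  stopifnot(inherits(signature, "gene_signature"))
  if (n_samples < 30) stop("n_samples must be >= 30")
  if (n_background < 0 || n_normals < 1) stop("non-positive sizes")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (!all(planted_genes %in% signature$genes))
    stop("planted_genes must be signature genes")

  sig_genes <- signature$genes
  p_sig <- length(sig_genes)
  bg_genes <- if (n_background > 0) sprintf("BG%04d", seq_len(n_background)) else character()
  genes <- c(sig_genes, bg_genes)
  loading <- rep_len(loading, p_sig)
  names(loading) <- sig_genes

  true_beta <- stats::setNames(numeric(length(genes)), genes)
  if (length(planted_genes))
    true_beta[planted_genes] <- rep_len(beta, length(planted_genes))

  with_seed(seed, {
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    level <- sample(rep_len(c(-1L, 0L, 1L), n_samples))
    baseline <- stats::setNames(
      stats::runif(length(genes), baseline_range[1], baseline_range[2]), genes)
    shared <- stats::rnorm(n_samples)

    x <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
                nrow = length(genes), dimnames = list(genes, sample_ids))
    x <- x + baseline
    x[sig_genes, ] <- x[sig_genes, ] +
      outer(loading, delta * noise_sd * level) +
      matrix(rep(shared_sd * shared, each = p_sig), nrow = p_sig) +
      tumor_shift

    lp <- as.vector(crossprod(x - baseline, true_beta))
    lambda <- baseline_hazard * exp(lp)
    t_event <- stats::rexp(n_samples, rate = lambda)
    c_rate <- solve_censor_rate(lambda, censor_rate)
    t_cens <- if (c_rate > 0) stats::rexp(n_samples, rate = c_rate) else rep(Inf, n_samples)
    surv <- data.frame(
      sample_id = sample_ids,
      time_days = pmax(pmin(t_event, t_cens), 1e-3),
      event = as.numeric(t_event <= t_cens),
      age = round(stats::rnorm(n_samples, 60, 10)),
      gender = sample(c("male", "female"), n_samples, replace = TRUE),
      stage = sample(1:4, n_samples, replace = TRUE),
      stringsAsFactors = FALSE
    )

    normal_ids <- sprintf("N%04d", seq_len(n_normals))
    normals <- matrix(stats::rnorm(length(genes) * n_normals, sd = noise_sd),
                      nrow = length(genes), dimnames = list(genes, normal_ids))
    normals <- normals + baseline

    truth <- list(
      group_label = stats::setNames(
        c("low", "medium", "high")[level + 2L], sample_ids),
      group_shift = delta,
      signature_loading = loading,
      true_beta = true_beta,
      baseline_hazard_rate = baseline_hazard,
      censor_rate = censor_rate,
      censor_rate_solved = c_rate,
      seed = seed,
      baseline = baseline,
      shared_sd = shared_sd,
      noise_sd = noise_sd,
      tumor_shift = tumor_shift,
      signature = signature
    )
    structure(list(expression = x, survival = surv, normals = normals,
                   truth = truth),
              class = "panopsig_cohort")
  })
}

#' @export
print.panopsig_cohort <- function(x, ...) {
  cat(sprintf("<panopsig_cohort> %d genes x %d samples, %d normals, %d planted genes\n",
              nrow(x$expression), ncol(x$expression), ncol(x$normals),
              sum(x$truth$true_beta != 0)))
  invisible(x)
}

#' Simulate a platform-shifted external validation cohort
#'
#' New samples are drawn from the same latent generative model as `base`
#' (same baselines, loadings and planted hazard coefficients), then each
#' gene is affine-distorted (`location + scale * x`, emulating a platform
#' shift) and listed genes are removed (emulating array annotation gaps).
#' Survival is generated from the undistorted expression, so the planted
#' prognostic signal is preserved.
#'
#' @param base A `panopsig_cohort` from [simulate_bulk_cohort()].
#' @param n_samples Number of external samples.
#' @param location_shift Per-gene additive offset (recycled).
#' @param scale_shift Per-gene multiplicative factor (recycled).
#' @param missing_genes Genes to drop from the external expression matrix.
#' @param seed Integer seed.
#' @return A `panopsig_cohort` (normals inherited from `base`, restricted to
#'   the retained genes).
#' @export
simulate_external_cohort <- function(base, n_samples,
                                     location_shift = 0, scale_shift = 1,
                                     missing_genes = character(),
                                     seed = 2L) {
  stopifnot(inherits(base, "panopsig_cohort"))
  tr <- base$truth
  if (!all(missing_genes %in% rownames(base$expression)))
    stop("missing_genes must be a subset of base genes")
  ext <- simulate_bulk_cohort(
    n_samples = n_samples,
    n_background = sum(!rownames(base$expression) %in% tr$signature$genes),
    signature = tr$signature, delta = tr$group_shift,
    loading = tr$signature_loading, shared_sd = tr$shared_sd,
    noise_sd = tr$noise_sd,
    planted_genes = names(tr$true_beta)[tr$true_beta != 0],
    beta = tr$true_beta[tr$true_beta != 0],
    baseline_hazard = tr$baseline_hazard_rate,
    censor_rate = tr$censor_rate, n_normals = ncol(base$normals),
    tumor_shift = tr$tumor_shift, seed = seed
  )
  # reuse the base baselines so the two cohorts share a generative model
  shift_b <- tr$baseline - ext$truth$baseline
  ext$expression <- ext$expression + shift_b
  ext$normals <- ext$normals + shift_b
  ext$truth$baseline <- tr$baseline
  ext$survival$sample_id <- sprintf("E%04d", seq_len(n_samples))
  colnames(ext$expression) <- ext$survival$sample_id
  names(ext$truth$group_label) <- ext$survival$sample_id

  g <- rownames(ext$expression)
  loc <- rep_len(location_shift, length(g))
  sc <- rep_len(scale_shift, length(g))
  ext$expression <- ext$expression * sc + loc
  keep <- !g %in% missing_genes
  ext$expression <- ext$expression[keep, , drop = FALSE]
  ext$normals <- ext$normals[keep, , drop = FALSE]
  ext
}

#' Simulate single-cell counts with cell-type-specific signature activity
#'
#' Negative-binomial counts whose signature-gene means scale with the cell
#' type's activity (`mu * exp(activity)`); per-cell library-size factors are
#' log-normal.
#'
#' @param n_cells_per_type Integer vector (recycled over `cell_types`).
#' @param cell_types Character vector of >= 2 type labels.
#' @param activity Named numeric vector (per type) of signature log-activity.
#' @param signature A `gene_signature`.
#' @param n_background Number of background genes.
#' @param mu_range Range of per-gene mean counts (drawn log-uniform).
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param libsize_sd SD of log library-size factors.
#' @param seed Integer seed.
#' @return List: `counts` (genes x cells integer matrix) and `cell_meta`
#'   (data.frame: cell_id, cell_type).
#' @export
simulate_single_cells <- function(n_cells_per_type, cell_types, activity,
                                  signature = panoptosis_signature(),
                                  n_background = 200,
                                  mu_range = c(0.1, 5),
                                  dispersion = 2,
                                  libsize_sd = 0.3,
                                  seed = 1L) {
  if (length(cell_types) < 2L) stop("need >= 2 cell types")
  if (any(n_cells_per_type <= 0)) stop("cell counts must be positive")
  stopifnot(all(cell_types %in% names(activity)), all(is.finite(activity)))
  n_per <- rep_len(n_cells_per_type, length(cell_types))
  genes <- c(signature$genes,
             if (n_background > 0) sprintf("BG%04d", seq_len(n_background)))
  with_seed(seed, {
    type_vec <- rep(cell_types, n_per)
    n_cells <- length(type_vec)
    cell_ids <- sprintf("C%05d", seq_len(n_cells))
    mu <- exp(stats::runif(length(genes), log(mu_range[1]), log(mu_range[2])))
    sf <- exp(stats::rnorm(n_cells, 0, libsize_sd))
    act <- activity[type_vec]
    mu_mat <- outer(mu, sf)
    is_sig <- genes %in% signature$genes
    mu_mat[is_sig, ] <- mu_mat[is_sig, ] * rep(exp(act), each = sum(is_sig))
    counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat, size = dispersion),
                     nrow = length(genes), dimnames = list(genes, cell_ids))
    list(counts = counts,
         cell_meta = data.frame(cell_id = cell_ids, cell_type = type_vec,
                                stringsAsFactors = FALSE))
  })
}

#' Dump a cohort's planted ground truth
#'
#' @param cohort A `panopsig_cohort`.
#' @return List with `planted` (data.frame gene, beta for nonzero-beta genes)
#'   and `groups` (data.frame sample_id, group_label).
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "panopsig_cohort"))
  tr <- cohort$truth
  nz <- tr$true_beta[tr$true_beta != 0]
  list(
    planted = data.frame(gene = names(nz), beta = unname(nz),
                         stringsAsFactors = FALSE),
    groups = data.frame(sample_id = names(tr$group_label),
                        group_label = unname(tr$group_label),
                        stringsAsFactors = FALSE)
  )
}

#' Write a truth report as JSON (round-trippable)
#' @param report List from [truth_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read a truth report written by [write_truth_report()]
#' @param path JSON path.
#' @return List with `planted` and `groups` data.frames.
#' @export
read_truth_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted <- as.data.frame(x$planted, stringsAsFactors = FALSE)
  x$groups <- as.data.frame(x$groups, stringsAsFactors = FALSE)
  x
}

#' Write a cohort's files (expression/clinical/normals TSV + signature GMT)
#'
#' @param cohort A `panopsig_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    normals = file.path(dir, "normals.tsv"),
    signature = file.path(dir, "signature.gmt")
  )
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$survival, paths["clinical"])
  write_expression(cohort$normals, paths["normals"])
  write_signature(cohort$truth$signature, paths["signature"])
  invisible(paths)
}

#' Write single-cell counts as MatrixMarket triplet + metadata TSV
#'
#' @param sc List from [simulate_single_cells()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_single_cells <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "counts.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cell_meta.tsv"))
  Matrix::writeMM(Matrix::Matrix(sc$counts, sparse = TRUE), paths["matrix"])
  writeLines(rownames(sc$counts), paths["genes"])
  utils::write.table(sc$cell_meta, paths["cells"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read single-cell counts written by [write_single_cells()]
#' @param dir Directory holding `counts.mtx`, `genes.tsv`, `cell_meta.tsv`.
#' @return List with `counts` (dense integer matrix) and `cell_meta`.
#' @export
read_single_cells <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.table(file.path(dir, "cell_meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  dimnames(m) <- list(genes, meta$cell_id)
  storage.mode(m) <- "integer"
  list(counts = m, cell_meta = meta)
}
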