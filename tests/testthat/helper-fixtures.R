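# Shared fixture builders; all randomness goes through explicit seeds.

toy_surv <- function(time, event, ids = NULL) {
  data.frame(sample_id = ids %||% paste0("s", seq_along(time)),
             time_days = time, event = event, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_surv <- function(n, seed, cens_frac = 0.3) {
  set.seed(seed)
  toy_surv(round(rexp(n, 1 / 100), 3), rbinom(n, 1, 1 - cens_frac))
}

small_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}
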