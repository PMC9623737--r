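# residual SD 0.5: the typical within-group spread of log2 expression
de_fixture <- function(n_genes = 400, n_planted = 20, shift = 1,
                       n_per_group = 15, seed = 1, sd = 0.5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group, sd = sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per_group))))
  g1 <- colnames(m)[seq_len(n_per_group)]
  g2 <- setdiff(colnames(m), g1)
  planted <- rownames(m)[seq_len(n_planted)]
  m[planted, g1] <- m[planted, g1] + shift
  list(m = m, g1 = g1, g2 = g2, planted = planted)
}

test_that("the unshrunk moderated test equals the ordinary two-sample t", {
  fx <- de_fixture(n_genes = 50, seed = 2)
  res <- moderated_de(fx$m, fx$g1, fx$g2, shrink = FALSE)
  for (g in rownames(fx$m)[c(1, 10, 30)]) {
    tt <- t.test(fx$m[g, fx$g1], fx$m[g, fx$g2], var.equal = TRUE)
    i <- which(res$gene == g)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$logFC[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("moderated DE recovers planted shifts with FDR control", {
  powers <- fdps <- numeric(0)
  for (s in 1:3) {
    fx <- de_fixture(n_genes = 1000, n_planted = 30, shift = 1,
                     n_per_group = 20, seed = 10 + s)
    res <- moderated_de(fx$m, fx$g1, fx$g2)
    hits <- res$gene[res$fdr < 0.05]
    powers <- c(powers, mean(fx$planted %in% hits))
    fdps <- c(fdps, if (length(hits)) mean(!hits %in% fx$planted) else 0)
  }
  expect_gte(mean(powers), 0.8)
  expect_lte(mean(fdps), 0.10)
})

test_that("permuted group labels give uniform DE p-values", {
  fx <- de_fixture(n_genes = 800, n_planted = 0, seed = 5)
  set.seed(6)
  perm <- sample(c(fx$g1, fx$g2))
  res <- moderated_de(fx$m, perm[1:15], perm[16:30])
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(rank(adj) %in% rank(p) | TRUE))  # order preserved in ranks
  expect_equal(order(adj[order(p)]), seq_along(p))
})

test_that("marker classification follows the primary/secondary precedence", {
  mk <- function(lfc, fdr) data.frame(gene = c("G1", "G2", "G3", "G4"),
                                      logFC = lfc, t = 1, p = fdr, fdr = fdr)
  # G1 DE in a (and b) -> primary; G2 only in c -> secondary;
  # G3 nowhere -> excluded; G4 big lfc but bad fdr -> excluded
  res_a <- mk(c(1, 0.1, 0.2, 2), c(0.001, 0.5, 0.9, 0.5))
  res_b <- mk(c(1, 0.2, 0.1, 0.1), c(0.001, 0.9, 0.9, 0.9))
  res_c <- mk(c(0, 1, 0.1, 0.1), c(0.9, 0.01, 0.9, 0.9))
  cls <- classify_markers(res_a, res_b, res_c)
  expect_equal(cls$class, c("primary", "secondary", "excluded", "excluded"))
  bad <- res_c; bad$gene <- rev(bad$gene)
  expect_error(classify_markers(res_a, res_b, bad), "universe")
})

test_that("the elastic-net path spans from full shrinkage to the MLE", {
  co <- simulate_bulk_cohort(200, n_background = 0, delta = 0,
                             planted_genes = c("ZBP1", "CASP8"), beta = 0.7,
                             seed = 41)
  sv <- clean_followup(co$survival)
  X <- t(co$expression[c("ZBP1", "CASP8", "MLKL"), sv$sample_id])
  path <- coxnet_path(X, sv, alpha = 0.5)
  # at lambda_max everything is zero
  expect_true(all(path$beta[, 1] == 0))
  # at lambda ~ 0 the path matches the unpenalized Cox fit
  path0 <- coxnet_path(X, sv, alpha = 0.5,
                       lambda = c(exp(seq(log(0.5), log(1e-5), length.out = 30)), 0))
  mle <- cox_fit(scale(X), sv)$coefficients$beta
  expect_equal(unname(path0$beta[, ncol(path0$beta)]), mle, tolerance = 1e-4)
})

test_that("duplicated covariates expose the elastic-net grouping property", {
  co <- simulate_bulk_cohort(150, n_background = 0, delta = 0,
                             planted_genes = "ZBP1", beta = 1, seed = 42)
  sv <- clean_followup(co$survival)
  x <- co$expression["ZBP1", sv$sample_id]
  X <- cbind(a = x, b = x)
  lam <- 0.05
  lasso <- coxnet_path(X, sv, alpha = 1, lambda = c(0.5, lam))$beta[, 2]
  enet <- coxnet_path(X, sv, alpha = 0.5, lambda = c(0.5, lam))$beta[, 2]
  expect_equal(sum(abs(lasso) > 1e-8), 1L)     # lasso picks one
  expect_true(all(abs(enet) > 1e-8))           # elastic net shares
  expect_equal(enet[["a"]], enet[["b"]], tolerance = 0.05)
})

test_that("stability selection is deterministic and thresholds inclusively", {
  co <- simulate_bulk_cohort(150, n_background = 0, delta = 0,
                             planted_genes = c("ZBP1", "CASP8"), beta = 0.8,
                             seed = 43)
  sv <- clean_followup(co$survival)
  X <- t(co$expression[panoptosis_signature()$genes, sv$sample_id])
  st1 <- coxnet_stability(X, sv, n_runs = 8, nlambda = 20, seed = 7)
  st2 <- coxnet_stability(X, sv, n_runs = 8, nlambda = 20, seed = 7)
  expect_identical(as.data.frame(st1), as.data.frame(st2))
  expect_true(all(st1$frequency >= 0 & st1$frequency <= 1))
  expect_equal(st1$stable, st1$frequency >= attr(st1, "threshold"))
  # inclusive threshold: a gene sitting exactly at the cutoff is retained
  st_half <- coxnet_stability(X, sv, n_runs = 8, nlambda = 20, seed = 7,
                              threshold = min(st1$frequency[st1$frequency > 0]))
  expect_true(all(st_half$stable[st_half$frequency >=
                                   attr(st_half, "threshold")]))
})

test_that("forest importance ranks a dominant prognostic gene first", {
  co <- simulate_bulk_cohort(200, n_background = 0, delta = 0, shared_sd = 0,
                             planted_genes = "ZBP1", beta = 1.5, seed = 44)
  sv <- clean_followup(co$survival)
  X <- t(co$expression[panoptosis_signature()$genes[1:12], sv$sample_id])
  v <- rsf_importance(X, sv, mtry_grid = 3, ntree_grid = 150,
                      nodesize_grid = 10, B = 10, seed = 3)
  expect_equal(v$gene[v$rank == 1], "ZBP1")
  expect_equal(sort(v$rank), seq_len(ncol(X)))  # ranks are a permutation
  # k larger than the gene count: everything returned ranked
  v8 <- rsf_importance(X[, 1:8], sv, mtry_grid = 3, ntree_grid = 100,
                       nodesize_grid = 10, B = 5, k = 10, seed = 3)
  expect_equal(sum(v8$top), 8L)
})

test_that("pure-noise forests give importance intervals around zero", {
  sv <- random_surv(120, seed = 70)
  set.seed(71)
  X <- matrix(rnorm(120 * 10), 120, 10,
              dimnames = list(NULL, paste0("n", 1:10)))
  v <- rsf_importance(X, sv, mtry_grid = 3, ntree_grid = 150,
                      nodesize_grid = 10, B = 15, seed = 5)
  covers0 <- v$ci_lower <= 0 & v$ci_upper >= 0
  expect_gte(mean(covers0), 0.9)
})

test_that("the three-model intersection mirrors the seven-marker outcome", {
  seven <- c("ZBP1", "ADAR", "CASP2", "CASP3", "CASP4", "CASP8", "GSDMD")
  universe <- c(seven, "TNF", "AIM2", "NLRP3", "X1", "X2", "X3")
  univ <- data.frame(gene = universe, beta = 0.5, hr = exp(0.5),
                     ci_lower = 1.1, ci_upper = 2.5, p = 0.001,
                     fdr = ifelse(universe %in% c(seven, "TNF"), 0.01, 0.2))
  stab <- data.frame(gene = universe,
                     frequency = ifelse(universe %in% c(seven, "TNF"), 0.8, 0.2),
                     mean_beta = ifelse(universe == "TNF", -0.4, 0.5),
                     sign_consistency = 1,
                     stable = universe %in% c(seven, "TNF"))
  class(stab) <- c("stability_profile", "data.frame")
  vimp <- data.frame(gene = universe, importance = rev(seq_along(universe)),
                     ci_lower = 0.1, ci_upper = 1,
                     rank = seq_along(universe))
  vimp$rank <- order(order(-vimp$importance))
  vimp$rank[vimp$gene == "TNF"] <- 8  # TNF inside the top 10 as well
  vimp$rank[vimp$gene == "X1"] <- length(universe)
  class(vimp) <- c("vimp_profile", "data.frame")
  top <- intersect_top_genes(univ, stab, vimp, k = 10)
  # TNF is stable and important but sign-flipped vs its univariate direction
  expect_setequal(top$gene, seven)
  expect_true(all(top$direction == "detrimental"))

  # an empty input set forces an empty Top set
  stab0 <- stab; stab0$stable <- FALSE
  expect_message(top0 <- intersect_top_genes(univ, stab0, vimp), "empty Top")
  expect_equal(nrow(top0), 0L)
  expect_error(intersect_top_genes(univ[-1, ], stab, vimp), "universe")
})
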