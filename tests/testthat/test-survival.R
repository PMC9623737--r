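test_that("follow-up cleaning drops short and truncates long follow-up", {
  surv <- toy_surv(c(0, 100, 4000), c(1, 1, 1))
  cl <- clean_followup(surv)
  expect_equal(nrow(cl), 2L)                      # < 1 day removed
  expect_equal(cl$time_days, c(100, 3650))        # 10y = 3650 days
  expect_equal(cl$event, c(1, 0))                 # censored at horizon
  expect_error(clean_followup(toy_surv(0.5, 1)), "no patients")
})

test_that("Kaplan-Meier matches the hand product-limit and the risk-set oracle", {
  km <- km_estimate(toy_surv(c(1, 2, 3), c(1, 1, 0)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3))

  expect_true(all(km_estimate(toy_surv(c(5, 8, 2), c(0, 0, 0)))$surv == 1))

  all_ev <- km_estimate(toy_surv(c(3, 1, 4, 2), c(1, 1, 1, 1)))
  expect_equal(all_ev$surv[4], 0)

  for (s in 1:5) {
    sv <- random_surv(40, seed = 30 + s)
    km <- km_estimate(sv)
    orc <- oracle_km(sv$time_days, sv$event)
    expect_equal(km$surv[km$n_event > 0], orc$surv)
  }
})

test_that("log-rank test matches manual risk-set tabulation and is symmetric", {
  a <- toy_surv(c(1, 2), c(1, 1))
  b <- toy_surv(c(3, 4), c(1, 1))
  got <- logrank_test(a, b)
  orc <- oracle_logrank(a$time_days, a$event, b$time_days, b$event)
  expect_equal(got$chisq, orc$chisq)
  expect_equal(got$p, orc$p)
  expect_equal(logrank_test(b, a)$chisq, got$chisq)

  same <- toy_surv(c(1, 2, 3), c(1, 1, 0))
  ident <- logrank_test(same, same)
  expect_equal(ident$chisq, 0)
  expect_equal(ident$p, 1)
  expect_error(logrank_test(toy_surv(1, 0), toy_surv(2, 0)), "no events")

  for (s in 1:3) {
    g1 <- random_surv(25, seed = 50 + s)
    g2 <- random_surv(30, seed = 80 + s)
    expect_equal(logrank_test(g1, g2)$chisq,
                 oracle_logrank(g1$time_days, g1$event,
                                g2$time_days, g2$event)$chisq)
    # invariant to time-unit rescaling
    g1y <- g1; g1y$time_days <- g1y$time_days / 365
    g2y <- g2; g2y$time_days <- g2y$time_days / 365
    expect_equal(logrank_test(g1y, g2y)$chisq, logrank_test(g1, g2)$chisq)
  }
})

test_that("Cox fits hit the analytic toy and obey rank/sign invariances", {
  surv <- toy_surv(c(1, 3, 2, 4), c(1, 1, 1, 1))
  X <- matrix(c(1, 1, 0, 0), dimnames = list(NULL, "g"))
  cf <- cox_fit(X, surv, ties = "breslow")
  expect_equal(cf$coefficients$beta, log((1 + sqrt(17)) / 2), tolerance = 1e-4)
  expect_equal(cf$coefficients$hr, (1 + sqrt(17)) / 2, tolerance = 1e-4)
  expect_true(cf$coefficients$ci_lower < cf$coefficients$hr &&
                cf$coefficients$hr < cf$coefficients$ci_upper)

  # rank invariance: doubling all times changes nothing
  surv2 <- surv; surv2$time_days <- surv2$time_days * 2
  expect_equal(cox_fit(X, surv2, ties = "breslow")$coefficients$beta,
               cf$coefficients$beta)
  # flipping the indicator flips beta exactly
  expect_equal(cox_fit(1 - X, surv, ties = "breslow")$coefficients$beta,
               -cf$coefficients$beta)
  expect_error(cox_fit(matrix(1, 4, 1), surv), "constant")
})

test_that("null covariates stay within 2 SE most of the time", {
  hits <- 0
  for (s in 1:20) {
    sv <- random_surv(120, seed = 200 + s)
    set.seed(s)
    X <- matrix(rnorm(120), dimnames = list(NULL, "noise"))
    co <- cox_fit(X, sv)$coefficients
    hits <- hits + (abs(co$beta) < 2 * co$se)
  }
  expect_gte(hits, 18)
})

test_that("the Schoenfeld diagnostic is calibrated and detects violations", {
  # under proportional hazards the per-covariate test rejects ~5%
  rej <- 0
  for (s in 1:60) {
    sv <- random_surv(80, seed = 400 + s)
    set.seed(s)
    X <- matrix(rnorm(80), dimnames = list(NULL, "x"))
    z <- ph_test(cox_fit(X, sv))
    rej <- rej + (z$p[z$term == "x"] < 0.05)
  }
  expect_lt(rej / 60, 0.17)

  # a strong time-varying effect is detected in the majority of seeds
  det <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 300
    x <- rnorm(n)
    # effect reverses over time: early hazard up, late hazard down
    t1 <- rexp(n, 0.02 * exp(1.5 * x))
    t2 <- 40 + rexp(n, 0.02 * exp(-1.5 * x))
    tm <- ifelse(t1 < 40, t1, t2)
    sv <- toy_surv(tm, rep(1, n))
    z <- ph_test(cox_fit(matrix(x, dimnames = list(NULL, "x")), sv))
    det <- det + (z$p[z$term == "x"] < 0.05)
  }
  expect_gte(det, 6)
})

test_that("stratum comparison reports N1/N2, HR from Cox and p from log-rank", {
  co <- simulate_bulk_cohort(240, n_background = 10, delta = 2,
                             planted_genes = c("ZBP1", "CASP8", "GSDMD"),
                             beta = 0.6, seed = 31)
  st <- factor(co$truth$group_label, levels = c("low", "medium", "high"))
  names(st) <- names(co$truth$group_label)
  sv_cl <- clean_followup(co$survival)
  cmp <- compare_strata(st, sv_cl)
  expect_gt(cmp$hr, 1)  # planted detrimental activity
  expect_equal(cmp$n_high + cmp$n_low,
               sum(st[sv_cl$sample_id] != "medium"))
  hi <- clean_followup(co$survival)
  hi <- hi[st[hi$sample_id] != "medium", ]
  expect_equal(cmp$p, logrank_test(hi[st[hi$sample_id] == "high", ],
                                   hi[st[hi$sample_id] == "low", ])$p)

  co2 <- simulate_bulk_cohort(240, n_background = 10, delta = 2,
                              planted_genes = c("ZBP1", "CASP8", "GSDMD"),
                              beta = -0.6, seed = 32)
  st2 <- factor(co2$truth$group_label, levels = c("low", "medium", "high"))
  names(st2) <- names(co2$truth$group_label)
  cmp2 <- compare_strata(st2, clean_followup(co2$survival))
  expect_lt(cmp2$hr, 1)  # planted protective activity
})

test_that("cohort screening applies the event, size and p rules", {
  cmp <- data.frame(
    cohort = c("a", "b", "c", "d"),
    n_high = c(80, 40, 150, 60), n_low = c(70, 40, 60, 50),
    events_high = c(20, 10, 30, 0), events_low = c(15, 8, 20, 10),
    hr = c(2, 3, 1.1, 2), ci_lower = 1, ci_upper = 4,
    p = c(0.03, 0.001, 0.4, 0.01), p_wald = 0.05, flag = "ok",
    stringsAsFactors = FALSE
  )
  cmp$flag[4] <- "zero_events"
  sc <- screen_cohorts(cmp)
  expect_equal(sc$selected$cohort, "a")           # p<0.05 and N1+N2>100
  expect_equal(sc$excluded$reason[sc$excluded$cohort == "b"], "size")
  expect_equal(sc$excluded$reason[sc$excluded$cohort == "c"], "p")
  expect_equal(sc$excluded$reason[sc$excluded$cohort == "d"], "zero_events")
})

test_that("clinical-adjusted Cox recovers a planted score effect", {
  co <- simulate_bulk_cohort(300, n_background = 10, delta = 0,
                             planted_genes = c("ZBP1", "CASP8", "CASP3",
                                               "GSDMD", "ADAR"),
                             beta = 0.8, seed = 33)
  sv <- clean_followup(co$survival)
  lp <- as.vector(crossprod(co$expression - co$truth$baseline,
                            co$truth$true_beta))
  names(lp) <- co$survival$sample_id
  fit <- clinical_adjusted_fit(lp, sv, sv)
  sc_row <- fit$coefficients[fit$coefficients$term == "score", ]
  expect_gt(sc_row$ci_lower, 1)  # CI excludes 1

  # a covariate duplicating the score is a collinear encoding
  dup_clin <- data.frame(sample_id = sv$sample_id,
                         age = as.numeric(lp[sv$sample_id]))
  expect_error(clinical_adjusted_fit(lp, dup_clin, sv), "collinear")
})
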