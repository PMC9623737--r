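# Independent brute-force oracles, coded directly from the definitions as
# plain loops; they deliberately share no code with the package internals.

# gsva: Gaussian-kernel CDF statistic, symmetric rank weight |p/2 - rank|^tau
# along the per-sample ordering, KS walk, ES = max pos + max neg deviation.
oracle_gsva <- function(expr, set_genes, tau = 1) {
  p <- nrow(expr)
  z <- matrix(NA_real_, p, ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    for (j in seq_len(ncol(expr))) {
      z[i, j] <- mean(pnorm((expr[i, j] - expr[i, ]) / h))
    }
  }
  es <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    ord <- order(z[, j], decreasing = TRUE)
    in_set <- rownames(expr)[ord] %in% set_genes
    denom_in <- 0
    for (pos in which(in_set)) denom_in <- denom_in + abs(p / 2 - pos)^tau
    walk <- 0; best_pos <- 0; best_neg <- 0
    for (pos in seq_len(p)) {
      if (in_set[pos]) walk <- walk + abs(p / 2 - pos)^tau / denom_in
      else walk <- walk - 1 / (p - sum(in_set))
      if (walk > best_pos) best_pos <- walk
      if (walk < best_neg) best_neg <- walk
    }
    es[j] <- best_pos + best_neg
  }
  names(es) <- colnames(expr)
  es
}

# ssGSEA: within-sample expression ranks, weight rank^alpha on set genes,
# integrated difference of the two ECDFs, walked over decreasing ranks.
oracle_ssgsea <- function(expr, set_genes, alpha = 0.25, normalize = TRUE) {
  p <- nrow(expr)
  es <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j])
    ord <- order(r, decreasing = TRUE)
    in_set <- rownames(expr)[ord] %in% set_genes
    denom_in <- sum(r[ord][in_set]^alpha)
    n_out <- p - sum(in_set)
    cum_in <- 0; cum_out <- 0; total <- 0
    for (pos in seq_len(p)) {
      if (in_set[pos]) cum_in <- cum_in + r[ord][pos]^alpha / denom_in
      else cum_out <- cum_out + 1 / n_out
      total <- total + (cum_in - cum_out)
    }
    es[j] <- total
  }
  if (normalize && diff(range(es)) > 0) es <- es / diff(range(es))
  names(es) <- colnames(expr)
  es
}

# Harrell concordance by exhaustive pair enumeration.
oracle_concordance <- function(risk, time, event) {
  conc <- 0; total <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        total <- total + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  conc / total
}

# Product-limit estimator as an explicit product over risk sets.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- numeric(length(ts))
  cur <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    cur <- cur * (1 - d / at_risk)
    s[k] <- cur
  }
  data.frame(time = ts, surv = s)
}

# Two-group log-rank by manual risk-set tabulation (O - E over pooled sets).
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ts) {
    n <- sum(time >= tt); n1 <- sum(time >= tt & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Mann-Whitney AUC of risk against a binary outcome.
oracle_mw_auc <- function(risk, outcome) {
  pos <- risk[outcome == 1]; neg <- risk[outcome == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
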