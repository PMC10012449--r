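# Independent brute-force oracles used to cross-check the package's
# statistics. Each is deliberately written along a different algorithmic
# path than the implementation it checks.

# OLS via the normal equations, with t-tests on n - p df
ols_oracle <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  list(coef = beta, se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df)
}

# BH step-up by the literal definition (double loop over ranks)
bh_oracle <- function(p, m_total = length(p)) {
  o <- order(p)
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m_total * p[o[j]] / j), 0)
    adj[o[i]] <- min(vals)
  }
  adj
}

# upper-tail hypergeometric by explicit enumeration over overlap counts
hyper_tail_oracle <- function(k, K, N, n) {
  js <- max(k, 0):min(K, n)
  if (length(js) == 0 || k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# exact one-sided Mann-Whitney p via the null U distribution (pwilcox),
# valid when there are no ties
mw_pwilcox_oracle <- function(a, b) {
  u <- sum(outer(a, b, ">"))
  pwilcox(u - 1, length(a), length(b), lower.tail = FALSE)
}

# one-sided Fisher tail by enumerating all tables with fixed margins
fisher_tail_oracle <- function(a, K_rel, K_con, draws) {
  avals <- max(0, draws - K_con):min(K_rel, draws)
  probs <- choose(K_rel, avals) * choose(K_con, draws - avals) /
    choose(K_rel + K_con, draws)
  sum(probs[avals >= a])
}
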