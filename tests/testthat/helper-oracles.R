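# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# explicit per-trial cumulative probit log-likelihood
oracle_probit_loglik <- function(beta, tau, X, y) {
  ll <- 0
  for (i in seq_along(y)) {
    eta <- sum(X[i, ] * beta)
    bounds <- c(-Inf, tau, Inf)
    p <- pnorm(bounds[y[i] + 1] - eta) - pnorm(bounds[y[i]] - eta)
    ll <- ll + log(p)
  }
  ll
}

# cross-validated distances by an explicit double loop (identity covariance)
oracle_sdrdm <- function(arr, squared = FALSE) {
  n_runs <- dim(arr)[1]; n_cond <- dim(arr)[2]
  out <- matrix(0, n_cond, n_cond)
  for (i in seq_len(n_runs)) {
    for (p in seq_len(n_cond)) {
      for (q in seq_len(n_cond)) {
        a <- arr[i, p, ]
        b <- colMeans(matrix(arr[-i, q, ], ncol = dim(arr)[3]))
        d2 <- sum((a - b)^2)
        out[p, q] <- out[p, q] + if (squared) d2 else sqrt(d2)
      }
    }
  }
  out / n_runs
}

# OLS by explicit normal equations
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# selection probability by enumeration over all partner reports
oracle_selection_prob <- function(r, dist) {
  p <- 0
  for (rp in 1:6) {
    if (rp < r) p <- p + dist[rp]
    if (rp == r) p <- p + dist[rp] / 2
  }
  p
}

# default stimulus set: 4 coherence levels x trials_per, balanced directions
balanced_stimuli <- function(coherences, trials_per = 40L) {
  do.call(rbind, lapply(coherences, function(k) {
    data.frame(coherence = k,
               direction = rep(c(-1L, 1L), each = trials_per / 2))
  }))
}
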