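# MCMC convergence diagnostics: split-R-hat and effective sample size.
# draws: iterations x chains matrix for one parameter.

split_chains <- function(draws) {
  n <- nrow(draws)
  h <- floor(n / 2)
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1):n, , drop = FALSE])
}

# Split-R-hat (between/within chain variance ratio on half-chains).
rhat <- function(draws) {
  d <- split_chains(draws)
  n <- nrow(d); m <- ncol(d)
  if (n < 4) return(NA_real_)
  means <- colMeans(d)
  vars <- apply(d, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < 1e-300) return(1)  # degenerate chain (fixed parameter)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial monotone positive sequence on
# chain-averaged autocorrelations of the split chains.
ess <- function(draws) {
  d <- split_chains(draws)
  n <- nrow(d); m <- ncol(d)
  if (n < 4) return(NA_real_)
  vars <- apply(d, 2, stats::var)
  W <- mean(vars)
  if (W < 1e-300) return(n * m)
  max_lag <- min(n - 2, 500)
  acovs <- vapply(seq_len(m), function(j) {
    x <- d[, j] - mean(d[, j])
    vapply(0:max_lag, function(l) {
      sum(x[seq_len(n - l)] * x[(1 + l):n]) / n
    }, numeric(1))
  }, numeric(max_lag + 1))
  means <- colMeans(d)
  B_over_n <- stats::var(means)
  var_plus <- W * (n - 1) / n + B_over_n
  rho <- 1 - (W - rowMeans(acovs)) / var_plus  # rho[1] = lag 0 = 1
  # pair sums (Geyer): stop at first negative pair, enforce monotonicity
  tail_sum <- 0
  prev <- Inf
  t <- 2
  while (t + 1 <= length(rho)) {
    p <- rho[t] + rho[t + 1]
    if (p < 0) break
    p <- min(p, prev)
    tail_sum <- tail_sum + p
    prev <- p
    t <- t + 2
  }
  ess_val <- n * m / (1 + 2 * tail_sum)
  min(ess_val, n * m)
}
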