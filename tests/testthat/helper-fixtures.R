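# fixtures built in code; no stored data files

# two-condition toy: explicit outcomes per subject, balanced 2+2 design
toy_dataset <- function(control, treatment) {
  stopifnot(length(control) == length(treatment))
  rows <- lapply(seq_along(control), function(i) {
    nc <- length(control[[i]])
    nt <- length(treatment[[i]])
    data.frame(subject = sprintf("s%d", i), time = seq_len(nc + nt),
               condition = rep(c("control", "treatment"), c(nc, nt)),
               outcome = c(control[[i]], treatment[[i]]),
               stringsAsFactors = FALSE)
  })
  trial_dataset(do.call(rbind, rows),
                conditions = c("control", "treatment"),
                reference = "control")
}

# marginal Gaussian log-likelihood of the mixed model, written from the
# per-subject covariance sigma2*I + tau2*J + omega2*x x' — independent of
# the fitting code, used as a brute-force oracle
marginal_loglik <- function(dataset, mu0, beta0, tau2, omega2, sigma2) {
  dm <- design_matrix(dataset)
  ll <- 0
  for (s in unique(dm$subject)) {
    rows <- dm$subject == s
    y <- dm$y[rows]
    x <- dm$X[rows, 1]
    n <- length(y)
    V <- sigma2 * diag(n) + tau2 + omega2 * outer(x, x)
    r <- y - mu0 - beta0 * x
    U <- chol(V)
    z <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
  }
  ll
}

# GLS solution for (mu0, beta0) at fixed variance components: the Bayes
# posterior mean under a flat coefficient prior
gls_coefficients <- function(dataset, tau2, omega2, sigma2) {
  dm <- design_matrix(dataset)
  A <- matrix(0, 2, 2)
  b <- numeric(2)
  for (s in unique(dm$subject)) {
    rows <- dm$subject == s
    y <- dm$y[rows]
    x <- dm$X[rows, 1]
    W <- cbind(1, x)
    V <- sigma2 * diag(length(y)) + tau2 + omega2 * outer(x, x)
    Vi <- solve(V)
    A <- A + t(W) %*% Vi %*% W
    b <- b + t(W) %*% Vi %*% y
  }
  drop(solve(A, b))
}

# MCSE of a posterior mean from the summary table (sd / sqrt(ess))
posterior_mcse <- function(posterior, parameter) {
  s <- posterior$summary
  row <- s[s$parameter == parameter, ]
  row$sd / sqrt(row$ess)
}

posterior_mean <- function(posterior, parameter) {
  s <- posterior$summary
  s$mean[s$parameter == parameter]
}

# pooled draws of one parameter across chains
pooled_draws <- function(posterior, parameter) {
  as.vector(posterior$draws[, , parameter])
}

# fixed per-replicate MCMC seeds for the paired frequentist/Bayes runs
derive_seed_acc <- function(r) 900000L + r
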