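# A small dataset with real heterogeneity, reused across sampler tests
bayes_toy <- function() {
  simulate_dataset(scenario_spec(6, 6, seed = 55), 1)$dataset
}

test_that("with fixed variances the coefficient posterior matches GLS", {
  # conjugate closed-form oracle: under a flat coefficient prior and known
  # variance components the posterior mean of (mu0, beta0) is the
  # generalized-least-squares solution on the marginal covariance
  d <- bayes_toy()
  vfix <- list(tau2 = 1.2, omega2 = 0.6, sigma2 = 0.9)
  res <- fit_lme_bayes(d, prior = prior_spec(non_informative = TRUE),
                       chains = 2, warmup = 400, draws = 1500, seed = 17,
                       fixed_variances = vfix)
  gls <- gls_coefficients(d, vfix$tau2, vfix$omega2, vfix$sigma2)
  for (p in c("mu0", "beta0[treatment]")) {
    mcse <- posterior_mcse(res$posterior, p)
    target <- if (p == "mu0") gls[1] else gls[2]
    expect_lt(abs(posterior_mean(res$posterior, p) - target), 3 * mcse)
  }
})

test_that("the sampled mu0 marginal matches the analytic Normal posterior", {
  # 2-subject toy, all variances fixed: the joint posterior of (mu0, beta0)
  # is exactly Gaussian and computable by direct matrix algebra
  d <- toy_dataset(list(c(1.0, 1.8, 0.6), c(4.2, 5.0, 4.6)),
                   list(c(2.2, 1.4, 1.9), c(3.1, 2.5, 2.8)))
  vfix <- list(tau2 = 2, omega2 = 1, sigma2 = 0.5)
  prior_sd <- 10
  # thinned: 25000 post-warmup iterations per chain, every 10th retained
  res <- fit_lme_bayes(d, prior = prior_spec(effect_mean = 0,
                                             effect_sd = prior_sd,
                                             intercept_sd = prior_sd),
                       chains = 2, warmup = 500, draws = 25000, thin = 10,
                       seed = 23, fixed_variances = vfix)

  dm <- design_matrix(d)
  A <- diag(1 / prior_sd^2, 2)
  b <- numeric(2)
  for (s in unique(dm$subject)) {
    rows <- dm$subject == s
    x <- dm$X[rows, 1]
    W <- cbind(1, x)
    V <- vfix$sigma2 * diag(length(x)) + vfix$tau2 +
      vfix$omega2 * outer(x, x)
    A <- A + t(W) %*% solve(V, W)
    b <- b + t(W) %*% solve(V, dm$y[rows])
  }
  S <- solve(A)
  post_mean <- drop(S %*% b)

  draws <- pooled_draws(res$posterior, "mu0")
  expect_length(draws, 5000)
  ks <- suppressWarnings(
    ks.test(draws, "pnorm", mean = post_mean[1], sd = sqrt(S[1, 1])))
  expect_gt(ks$p.value, 0.01)
})

test_that("an upper truncation bound is respected by every retained draw", {
  d <- bayes_toy()
  res <- suppressWarnings(
    fit_lme_bayes(d, prior = prior_spec(effect_mean = -1, effect_sd = 5,
                                        effect_upper = 0),
                  chains = 2, warmup = 200, draws = 400, seed = 31))
  draws <- pooled_draws(res$posterior, "beta0[treatment]")
  expect_true(all(draws <= 0))
  # individual effects are NOT truncated: only the population mean is
  subj_draws <- pooled_draws(res$posterior, "beta_i[s01,treatment]")
  expect_true(length(subj_draws) == length(draws))
})

test_that("a bound far in the tail still produces finite, valid draws", {
  # inverse-CDF truncation must not degenerate when nearly all prior mass
  # sits above the bound (strongly positive data, bound at 0)
  d <- toy_dataset(list(c(1, 1.2), c(0.8, 1.1), c(1.1, 0.7)),
                   list(c(9, 9.4), c(8.7, 9.1), c(9.2, 8.8)))
  res <- fit_lme_bayes(d, prior = prior_spec(effect_mean = 0, effect_sd = 100,
                                             effect_upper = 0),
                       chains = 2, warmup = 200, draws = 300, seed = 41)
  draws <- pooled_draws(res$posterior, "beta0[treatment]")
  expect_true(all(is.finite(draws)))
  expect_true(all(draws <= 0))
})

test_that("identical seed and settings give identical posteriors", {
  d <- bayes_toy()
  pr <- prior_spec(effect_mean = -1, effect_sd = 5)
  cmp <- compare_priors(d, priors = list(one = pr, two = pr),
                        chains = 2, warmup = 100, draws = 200, seed = 13)
  expect_identical(cmp$fits$one$posterior$draws, cmp$fits$two$posterior$draws)
  r2 <- fit_lme_bayes(d, prior = pr, chains = 2, warmup = 100, draws = 200,
                      seed = 13)
  expect_identical(r2$posterior$draws, cmp$fits$one$posterior$draws)
})

test_that("a vanishing prior SD pins the population effect to the prior mean", {
  d <- bayes_toy()
  res <- fit_lme_bayes(d, prior = prior_spec(effect_mean = 5,
                                             effect_sd = 1e-4),
                       chains = 2, warmup = 200, draws = 300, seed = 19)
  expect_equal(unname(res$fit$beta0[["treatment"]]), 5, tolerance = 1e-2)
})

test_that("subject relabeling leaves population posteriors unchanged (MC error)", {
  # randomness is consumed in subject order within each iteration, so a
  # relabeled run is a different stream: population summaries must agree
  # up to Monte-Carlo error, not bit-exactly
  d <- bayes_toy()
  r1 <- fit_lme_bayes(d, chains = 2, warmup = 300, draws = 700, seed = 29)
  raw <- d$data
  relabel <- setNames(paste0("z", seq_along(d$subjects)), d$subjects)
  raw$subject <- unname(relabel[raw$subject])
  d2 <- trial_dataset(raw, conditions = d$conditions)
  r2 <- fit_lme_bayes(d2, chains = 2, warmup = 300, draws = 700, seed = 29)
  for (p in c("mu0", "beta0[treatment]", "sigma2")) {
    tol <- 3 * (posterior_mcse(r1$posterior, p) +
                  posterior_mcse(r2$posterior, p))
    expect_lt(abs(posterior_mean(r1$posterior, p) -
                    posterior_mean(r2$posterior, p)), tol + 0.02)
  }
})

test_that("replicating the data drives weak and truncated posteriors together", {
  # when the true effect is interior to the truncation region the data
  # dominate: the prior-induced gap between the two posteriors shrinks as
  # subjects accumulate
  p <- population_parameters(beta0 = -0.4, omega2 = 0.3, sigma2 = 1)
  small <- simulate_dataset(scenario_spec(4, 3, seed = 61, params = p),
                            1)$dataset
  big_raw <- do.call(rbind, lapply(1:8, function(k) {
    raw <- small$data
    raw$subject <- paste0(raw$subject, "_copy", k)
    raw
  }))
  big <- trial_dataset(big_raw, conditions = small$conditions)

  gap <- function(dataset) {
    cmp <- suppressWarnings(compare_priors(
      dataset,
      priors = list(weak = prior_spec(effect_mean = -1, effect_sd = 5),
                    negative = prior_spec(effect_mean = -1, effect_sd = 5,
                                          effect_upper = 0)),
      chains = 2, warmup = 300, draws = 700, seed = 71))
    abs(cmp$fits$weak$fit$beta0[["treatment"]] -
          cmp$fits$negative$fit$beta0[["treatment"]])
  }
  expect_lt(gap(big), gap(small))
})

test_that("posterior bookkeeping is structurally sound", {
  d <- bayes_toy()
  res <- fit_lme_bayes(d, chains = 3, warmup = 100, draws = 200, seed = 37)
  arr <- res$posterior$draws
  expect_equal(dim(arr)[1:2], c(200L, 3L))
  expect_true(all(arr[, , "sigma2"] > 0))
  expect_true(all(arr[, , "tau2"] > 0))
  s <- res$posterior$summary
  expect_true(all(c("mean", "sd", "q2.5", "q97.5", "rhat", "ess") %in%
                    names(s)))
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_error(fit_lme_bayes(d, chains = 2, warmup = 50, draws = 50),
               "seed is required")

  f1 <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(res$posterior, f1)
  dr <- read.csv(f1, check.names = FALSE)
  expect_equal(nrow(dr), 600)
  expect_true(all(dimnames(arr)[[3]] %in% names(dr)))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(res$posterior, f2)
  expect_equal(nrow(read.csv(f2)), nrow(s))
})
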