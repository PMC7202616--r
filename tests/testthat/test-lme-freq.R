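test_that("degenerate noiseless data gives exact coefficients, floor variances", {
  d <- toy_dataset(list(c(5, 5), c(5, 5), c(5, 5)),
                   list(c(3, 3), c(3, 3), c(3, 3)))
  fit <- fit_lme_ml(d)
  expect_equal(fit$mu0, 5, tolerance = 1e-6)
  expect_equal(unname(fit$beta0["treatment"]), -2, tolerance = 1e-6)
  expect_lt(fit$tau2, 1e-6)
  expect_lt(unname(fit$omega2["treatment"]), 1e-6)
  expect_lt(fit$sigma2, 1e-6)
  # every estimator agrees on identical, noiseless subjects
  ipd <- fit_ipd(d)
  expect_equal(ipd$mu0, fit$mu0, tolerance = 1e-6)
  expect_equal(ipd$beta0, fit$beta0, tolerance = 1e-6)
})

test_that("attained log-likelihood matches a brute-force surface maximization", {
  # independent oracle: own marginal log-likelihood, coarse grid over the
  # log-variances with closed-form GLS coefficients at each node, then a
  # Nelder-Mead polish of all five parameters
  d <- toy_dataset(list(c(1.2, 2.1), c(4.9, 6.2), c(8.8, 10.1)),
                   list(c(3.4, 4.1), c(8.2, 9.4), c(13.0, 14.2)))
  fit <- fit_lme_ml(d)

  best <- -Inf
  best_par <- NULL
  for (lt in seq(-8, 3, by = 1)) for (lo in seq(-8, 3, by = 1))
    for (ls in seq(-6, 2, by = 1)) {
      cf <- gls_coefficients(d, exp(lt), exp(lo), exp(ls))
      ll <- marginal_loglik(d, cf[1], cf[2], exp(lt), exp(lo), exp(ls))
      if (ll > best) {
        best <- ll
        best_par <- c(cf, lt, lo, ls)
      }
    }
  polish <- optim(best_par, function(p) {
    -marginal_loglik(d, p[1], p[2], exp(p[3]), exp(p[4]), exp(p[5]))
  }, method = "Nelder-Mead",
  control = list(maxit = 5000, reltol = 1e-14))
  oracle_ll <- -polish$value

  expect_lt(abs(fit$diagnostics$loglik - oracle_ll), 1e-4)
})

test_that("empirical-Bayes predictions match direct Gaussian conditioning", {
  # closed-form oracle: E[(mu_i, beta_i) | y_i] from the joint covariance
  # of effects and outcomes, at fixed population parameters
  d <- toy_dataset(list(c(1, 2), c(7, 9)), list(c(4, 3), c(2, 1)))
  pars <- nof1lme:::new_fit_result(
    "manual", mu0 = 3, beta0 = c(treatment = -1.5), tau2 = 2,
    omega2 = c(treatment = 0.8), sigma2 = 1.3,
    subjects = data.frame(subject = c("s1", "s2")))
  pred <- predict_subject_effects(d, pars)

  dm <- design_matrix(d)
  for (i in 1:2) {
    rows <- dm$subject == paste0("s", i)
    x <- dm$X[rows, 1]
    Z <- cbind(1, x)
    D <- diag(c(2, 0.8))
    V <- Z %*% D %*% t(Z) + 1.3 * diag(4)
    cov_cy <- D %*% t(Z)  # cov((u_i, b_dev_i), y_i)
    mean_y <- 3 - 1.5 * x
    dev <- drop(cov_cy %*% solve(V, dm$y[rows] - mean_y))
    expect_equal(pred$intercept[i], 3 + dev[1], tolerance = 1e-10)
    expect_equal(pred$effect_treatment[i], -1.5 + dev[2], tolerance = 1e-10)
  }
})

test_that("shrinkage limits behave: complete at omega2=0, none as sigma2->0", {
  d <- toy_dataset(list(c(1, 2), c(7, 9), c(4, 4)),
                   list(c(4, 3), c(2, 1), c(6, 5)))
  base <- nof1lme:::new_fit_result(
    "manual", mu0 = 2, beta0 = c(treatment = -1), tau2 = 1,
    omega2 = c(treatment = 0.5), sigma2 = 1,
    subjects = data.frame(subject = paste0("s", 1:3)))

  zero_omega <- base
  zero_omega$omega2 <- c(treatment = 0)
  pred0 <- predict_subject_effects(d, zero_omega)
  expect_equal(pred0$effect_treatment, rep(-1, 3))

  tiny_sigma <- base
  tiny_sigma$sigma2 <- 1e-10
  pred1 <- predict_subject_effects(d, tiny_sigma)
  own_diff <- vapply(1:3, function(i) {
    rows <- d$data$subject == paste0("s", i)
    mean(d$data$outcome[rows & d$data$condition == "treatment"]) -
      mean(d$data$outcome[rows & d$data$condition == "control"])
  }, numeric(1))
  expect_equal(pred1$effect_treatment, own_diff, tolerance = 1e-4)
})

test_that("mixed-model predictions shrink toward the population effect", {
  subject_ols <- function(dataset) {
    d <- dataset$data
    vapply(dataset$subjects, function(s) {
      rows <- d$subject == s
      mean(d$outcome[rows & d$condition == "treatment"]) -
        mean(d$outcome[rows & d$condition == "control"])
    }, numeric(1))
  }
  for (seed in c(11, 12, 13)) {
    sim <- simulate_dataset(scenario_spec(12, 5, seed = seed), 1)
    fit <- fit_lme_ml(sim$dataset)
    eb <- predict_subject_effects(sim$dataset, fit)
    ols <- subject_ols(sim$dataset)
    b0 <- unname(fit$beta0["treatment"])
    # dispersion shrinkage at the ML parameters: the EB effects are
    # strictly less spread around the population effect than the raw
    # per-subject contrasts (the joint intercept+slope predictor can move
    # an individual subject slightly outward, so the guarantee is on the
    # dispersion, not each subject separately)
    expect_lt(sd(eb$effect_treatment), sd(ols))
    expect_lt(mean((eb$effect_treatment - b0)^2), mean((ols - b0)^2))

    # with a diffuse intercept prior the slope prediction is a pure scalar
    # shrinkage of the subject contrast, so the per-subject inequality is
    # exact on balanced data
    diffuse <- fit
    diffuse$tau2 <- 1e6
    eb2 <- predict_subject_effects(sim$dataset, diffuse)
    expect_true(all(abs(eb2$effect_treatment - b0) <= abs(ols - b0) + 1e-6))
  }
})

test_that("the likelihood is invariant to relabeling and reordering", {
  sim <- simulate_dataset(scenario_spec(6, 5, seed = 21), 1)
  fit1 <- fit_lme_ml(sim$dataset)
  d <- sim$dataset$data
  relabel <- setNames(paste0("z", 6:1), unique(d$subject))
  d$subject <- unname(relabel[d$subject])
  d <- d[sample(nrow(d)), ]
  d$time <- ave(d$time, d$subject, FUN = seq_along)  # keep times unique
  fit2 <- fit_lme_ml(trial_dataset(d, conditions = c("control", "treatment")))
  expect_equal(fit2$diagnostics$loglik, fit1$diagnostics$loglik,
               tolerance = 1e-6)
  expect_equal(fit2$beta0, fit1$beta0, tolerance = 1e-6)
})

test_that("non-identifiable designs are rejected", {
  # only one subject ever receives the treatment
  d <- trial_dataset(data.frame(
    subject = rep(c("a", "b"), each = 4), time = rep(1:4, 2),
    condition = c("control", "control", "treatment", "treatment",
                  rep("control", 4)),
    outcome = rnorm(8)), conditions = c("control", "treatment"))
  expect_error(fit_lme_ml(d), "not identifiable")
})
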