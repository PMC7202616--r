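#' Per-subject ordinary least squares fit
#'
#' First step of the two-step individual-participant-data (IPD)
#' meta-analysis: each subject's outcomes are regressed on the condition
#' indicators by OLS. With dummy-coded conditions this is the one-way
#' condition-means model, so the intercept is the subject's reference-
#' condition mean and each effect is a difference of condition means. The
#' residual variance uses denominator (observations - parameters) and is
#' undefined (`NA`) when that is zero.
#'
#' An effect for condition `k` is estimable only if the subject has at least
#' one non-missing observation in both the reference condition and `k`;
#' otherwise it is returned as `NA`.
#'
#' @param outcome Numeric outcomes for one subject (may contain `NA`).
#' @param condition Condition labels aligned with `outcome`.
#' @param conditions Condition set, reference first.
#' @param subject_id Optional label carried into the result.
#' @return A list of class `subject_fit`: `subject`, `intercept`, `effects`
#'   (named per non-reference condition), `sigma2`, `n_obs`, `df`.
#' @export
fit_subject_ols <- function(outcome, condition, conditions,
                            subject_id = NA_character_) {
  keep <- !is.na(outcome)
  if (!any(keep)) stop("subject has zero non-missing observations")
  y <- outcome[keep]
  cond <- condition[keep]
  ref <- conditions[1]
  nonref <- conditions[-1]

  means <- tapply(y, factor(cond, levels = conditions), mean)
  intercept <- unname(means[[ref]])
  effects <- vapply(nonref, function(k) {
    if (is.na(means[[k]]) || is.na(intercept)) NA_real_
    else means[[k]] - intercept
  }, numeric(1))

  observed <- conditions[!is.na(means)]
  rss <- sum(vapply(observed, function(k) {
    yk <- y[cond == k]
    sum((yk - mean(yk))^2)
  }, numeric(1)))
  df <- length(y) - length(observed)
  sigma2 <- if (df > 0) rss / df else NA_real_

  structure(list(subject = subject_id, intercept = intercept,
                 effects = effects, sigma2 = sigma2,
                 n_obs = length(y), df = df),
            class = "subject_fit")
}

#' Aggregate per-subject fits into a population estimate
#'
#' Second step of the IPD meta-analysis: population parameters are
#' (weighted) means of the subject-level estimates, with unit weights by
#' default. Between-subject SDs are the weighted sample SDs of the raw
#' per-subject estimates (they are not model parameters under this
#' estimator, which is the source of their upward bias: sampling error of
#' each subject's OLS effect inflates the observed dispersion). The residual
#' variance is the weighted mean of the per-subject residual variances that
#' are defined. Per-subject predictions are the raw OLS estimates, with no
#' shrinkage.
#'
#' Subjects lacking a condition contribute to the intercept aggregation but
#' not to that condition's effect aggregation; their count is reported in
#' `diagnostics$n_effect_used`.
#'
#' @param fits List of [fit_subject_ols()] results.
#' @param weights Optional nonnegative per-subject weights (default: unit
#'   weights, the benchmark convention). Inverse-variance weighting can be
#'   supplied explicitly.
#' @param conditions Condition set, reference first.
#' @return A population fit of class `nof1_fit` with method label `"IPD"`.
#' @export
aggregate_ipd <- function(fits, weights = NULL, conditions) {
  n <- length(fits)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("need one weight per subject fit")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("all weights are zero")
  nonref <- conditions[-1]

  eff <- do.call(rbind, lapply(fits, function(f) f$effects))
  n_estimable <- sum(apply(!is.na(eff), 1, any))
  if (n_estimable < 2) {
    stop("need at least 2 subjects with estimable effects; have ", n_estimable)
  }

  ic <- vapply(fits, function(f) f$intercept, numeric(1))
  s2 <- vapply(fits, function(f) f$sigma2, numeric(1))
  ok_ic <- !is.na(ic)
  mu0 <- weighted_mean(ic[ok_ic], weights[ok_ic])
  tau <- weighted_sd(ic[ok_ic], weights[ok_ic])
  ok_s2 <- !is.na(s2)
  sigma2 <- if (any(ok_s2)) weighted_mean(s2[ok_s2], weights[ok_s2]) else NA_real_

  beta0 <- omega2 <- stats::setNames(numeric(length(nonref)), nonref)
  n_eff_used <- stats::setNames(integer(length(nonref)), nonref)
  for (k in nonref) {
    ok <- !is.na(eff[, k])
    n_eff_used[k] <- sum(ok)
    if (sum(ok) < 2) stop("fewer than 2 subjects with an estimable effect for ", k)
    beta0[k] <- weighted_mean(eff[ok, k], weights[ok])
    omega2[k] <- weighted_sd(eff[ok, k], weights[ok])^2
  }

  subjects <- data.frame(subject = vapply(fits, function(f) f$subject,
                                          character(1)),
                         intercept = ic, stringsAsFactors = FALSE)
  for (k in nonref) subjects[[paste0("effect_", k)]] <- eff[, k]

  new_fit_result("IPD", mu0 = mu0, beta0 = beta0, tau2 = tau^2,
                 omega2 = omega2, sigma2 = sigma2, subjects = subjects,
                 diagnostics = list(converged = TRUE,
                                    n_effect_used = n_eff_used,
                                    weights = weights))
}

#' Two-step IPD meta-analysis of a trial dataset
#'
#' Convenience wrapper: [fit_subject_ols()] per subject on the non-missing
#' observations, then [aggregate_ipd()].
#'
#' @param dataset A [trial_dataset()].
#' @param weights Optional per-subject weights (default unit).
#' @return A population fit of class `nof1_fit`.
#' @export
fit_ipd <- function(dataset, weights = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d <- dataset$data
  fits <- lapply(dataset$subjects, function(s) {
    rows <- d$subject == s
    fit_subject_ols(d$outcome[rows], d$condition[rows],
                    conditions = dataset$conditions, subject_id = s)
  })
  aggregate_ipd(fits, weights = weights, conditions = dataset$conditions)
}
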