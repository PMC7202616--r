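#' Frequentist linear mixed model by maximum likelihood
#'
#' One-step estimation of the hierarchical model: fixed intercept and one
#' fixed effect per non-reference condition, plus mutually independent
#' random intercepts and random condition effects per subject (diagonal
#' random-effects covariance; no intercept-slope correlation). Per subject,
#' the marginal outcome covariance is
#' \eqn{\sigma^2 I + \tau^2 J + \sum_k \omega_k^2 x_k x_k^T}
#' where \eqn{x_k} is the subject's indicator column for condition `k` and
#' `J` the all-ones matrix. Estimation is by maximum likelihood (ML) through
#' [lme4::lmer()]; REML is available as an option (variance estimates differ
#' at small subject counts). Variance components are constrained nonnegative
#' and may be estimated at the zero boundary.
#'
#' @param dataset A [trial_dataset()] with at least 2 subjects and at least
#'   2 subjects observed in each non-reference condition (else the model is
#'   not identifiable and an error is raised).
#' @param reml Use REML instead of ML. Default `FALSE` (ML).
#' @return A fit of class `nof1_fit`, method label `"F-LME"` (or
#'   `"F-LME(REML)"`), with per-subject empirical-Bayes predictions in
#'   `$subjects` (absolute scale) and diagnostics including the attained
#'   log-likelihood and a convergence flag. Optimizer non-convergence is
#'   flagged, not fatal.
#' @export
fit_lme_ml <- function(dataset, reml = FALSE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dm <- design_matrix(dataset)
  if (length(unique(dm$subject)) < 2) stop("need at least 2 subjects")
  nonref <- dataset$conditions[-1]
  if (length(nonref) == 0) stop("need at least one non-reference condition")
  for (k in nonref) {
    n_obs_k <- length(unique(dm$subject[dm$X[, k] == 1]))
    if (n_obs_k < 2) {
      stop("not identifiable: fewer than 2 subjects observed in condition '",
           k, "'")
    }
  }

  K <- length(nonref)
  xnames <- paste0("x", seq_len(K))
  df <- data.frame(y = dm$y,
                   subject = factor(dm$subject, levels = dataset$subjects))
  for (j in seq_len(K)) df[[xnames[j]]] <- dm$X[, j]
  fixed <- paste(c("1", xnames), collapse = " + ")
  ranef_terms <- c("(1 | subject)",
                   sprintf("(0 + %s | subject)", xnames))
  form <- stats::as.formula(paste("y ~", fixed, "+",
                                  paste(ranef_terms, collapse = " + ")))

  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  omega2 <- stats::setNames(vapply(seq_len(K), function(j) {
    vc$vcov[vc$grp != "Residual" & vc$var1 == xnames[j]]
  }, numeric(1)), nonref)
  beta0 <- stats::setNames(unname(fe[xnames]), nonref)

  re <- lme4::ranef(fit)$subject
  subjects <- data.frame(subject = rownames(re),
                         intercept = unname(fe[1] + re[["(Intercept)"]]),
                         stringsAsFactors = FALSE)
  for (j in seq_len(K)) {
    dev <- if (xnames[j] %in% names(re)) re[[xnames[j]]] else 0
    subjects[[paste0("effect_", nonref[j])]] <- unname(fe[xnames[j]] + dev)
  }
  rownames(subjects) <- NULL

  conv_code <- fit@optinfo$conv$opt
  new_fit_result(if (reml) "F-LME(REML)" else "F-LME",
                 mu0 = unname(fe[1]), beta0 = beta0, tau2 = tau2,
                 omega2 = omega2, sigma2 = sigma2, subjects = subjects,
                 diagnostics = list(
                   converged = (conv_code == 0) && length(warn) == 0,
                   loglik = as.numeric(stats::logLik(fit)),
                   n_obs = nrow(df), warnings = warn, reml = reml))
}

#' Empirical-Bayes predictions of subject-level effects
#'
#' Best linear unbiased predictions (posterior means of the subject random
#' effects given that subject's data, at the supplied population parameter
#' values): for subject `i` with design `Z_i = [1, x_i1, ..., x_iK]` and
#' prior covariance `D = diag(tau2, omega2_1, ..., omega2_K)`, the deviation
#' vector has posterior mean
#' `solve(Z'Z/sigma2 + D^-1, Z'(y - mu0 - X beta0)/sigma2)`.
#' Predictions shrink each subject's raw contrast toward the population
#' value; with a zero heterogeneity variance the shrinkage is complete and
#' every subject prediction equals the population estimate. Results are on
#' the absolute scale (`beta0 + deviation`, `mu0 + deviation`).
#'
#' Works with any fit carrying population parameter estimates, so IPD
#' population parameters can also be used to produce shrunken predictions.
#'
#' @param dataset A [trial_dataset()].
#' @param fit A fit of class `nof1_fit` with finite variance estimates.
#' @return A data.frame: `subject`, `intercept`, one `effect_<condition>`
#'   column per non-reference condition.
#' @export
predict_subject_effects <- function(dataset, fit) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(fit, "nof1_fit"))
  dm <- design_matrix(dataset)
  nonref <- dataset$conditions[-1]
  K <- length(nonref)
  prior_var <- c(fit$tau2, as.numeric(fit$omega2[nonref]))
  floor <- 1e-10
  free <- prior_var > floor
  sigma2 <- fit$sigma2
  beta0 <- as.numeric(fit$beta0[nonref])

  out <- data.frame(subject = dataset$subjects, stringsAsFactors = FALSE)
  dev <- matrix(0, nrow = length(dataset$subjects), ncol = K + 1)
  for (i in seq_along(dataset$subjects)) {
    rows <- dm$subject == dataset$subjects[i]
    if (!any(rows) || !any(free)) next
    Z <- cbind(1, dm$X[rows, , drop = FALSE])
    r <- dm$y[rows] - fit$mu0 - dm$X[rows, , drop = FALSE] %*% beta0
    Za <- Z[, free, drop = FALSE]
    P <- crossprod(Za) / sigma2 + diag(1 / prior_var[free],
                                       nrow = sum(free))
    dev[i, free] <- solve(P, crossprod(Za, r) / sigma2)
  }
  out$intercept <- fit$mu0 + dev[, 1]
  for (j in seq_len(K)) {
    out[[paste0("effect_", nonref[j])]] <- beta0[j] + dev[, j + 1]
  }
  out
}
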