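#' Prior specification for the Bayesian mixed model
#'
#' Priors for the population-level parameters of the hierarchical model.
#' Population effects get independent Normal priors, optionally truncated
#' from above (e.g. an upper bound of 0 encodes the assumption that the
#' average subject loses weight: the population effect is restricted to be
#' zero or negative, while individual effects remain unrestricted).
#' Variance components get inverse-gamma priors (conjugate); the intercept
#' a vague Normal prior.
#'
#' @param effect_mean,effect_sd Prior mean and SD for each population
#'   effect; scalars are recycled across non-reference conditions, or supply
#'   vectors named by condition.
#' @param effect_upper Optional upper truncation bound per effect (`Inf` =
#'   no truncation). Scalar or named vector, as above.
#' @param intercept_mean,intercept_sd Normal prior on the population
#'   intercept (default vague: mean 0, SD 1000).
#' @param variance_shape,variance_rate Inverse-gamma shape/rate shared by
#'   all variance components (default 0.001/0.001, weakly informative).
#' @param non_informative If `TRUE`, overrides the coefficient priors with
#'   Normal(0, 1000^2) untruncated — diffuse enough that the posterior
#'   numerically matches the maximum-likelihood answer.
#' @return An object of class `prior_spec`.
#' @examples
#' # the weak prior used in the weight-loss demonstration, and its
#' # truncated ("negative") counterpart:
#' weak <- prior_spec(effect_mean = -1, effect_sd = 5)
#' negative <- prior_spec(effect_mean = -1, effect_sd = 5, effect_upper = 0)
#' @export
prior_spec <- function(effect_mean = 0, effect_sd = 1000,
                       effect_upper = Inf,
                       intercept_mean = 0, intercept_sd = 1000,
                       variance_shape = 0.001, variance_rate = 0.001,
                       non_informative = FALSE) {
  if (non_informative) {
    effect_mean <- 0; effect_sd <- 1000; effect_upper <- Inf
  }
  if (any(effect_sd <= 0) || intercept_sd <= 0) stop("prior SDs must be > 0")
  if (any(is.na(effect_upper))) stop("effect_upper must be a number or Inf")
  if (variance_shape <= 0 || variance_rate <= 0) {
    stop("variance prior shape/rate must be > 0")
  }
  structure(list(effect_mean = effect_mean, effect_sd = effect_sd,
                 effect_upper = effect_upper,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 variance_shape = variance_shape,
                 variance_rate = variance_rate,
                 non_informative = non_informative),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  if (x$non_informative) {
    cat("prior: non-informative (Normal(0, 1000^2) coefficients)\n")
  } else {
    cat(sprintf("prior: effect ~ Normal(%s, %s^2)%s\n",
                paste(x$effect_mean, collapse = ","),
                paste(x$effect_sd, collapse = ","),
                if (all(is.infinite(x$effect_upper))) "" else
                  paste0(" truncated at upper ",
                         paste(x$effect_upper, collapse = ","))))
  }
  cat(sprintf("       intercept ~ Normal(%g, %g^2); variances ~ IG(%g, %g)\n",
              x$intercept_mean, x$intercept_sd,
              x$variance_shape, x$variance_rate))
  invisible(x)
}

# recycle a scalar-or-named prior field across non-reference conditions
expand_prior_field <- function(value, nonref) {
  if (length(value) == 1) return(stats::setNames(rep(value, length(nonref)), nonref))
  if (!is.null(names(value)) && all(nonref %in% names(value))) {
    return(value[nonref])
  }
  if (length(value) == length(nonref)) return(stats::setNames(value, nonref))
  stop("prior field must be scalar or named per non-reference condition")
}

# Exact upper-truncated Normal draw by inverse-CDF in log space (no
# rejection loop; stable even when nearly all mass exceeds the bound).
rtruncnorm_upper <- function(n, mean, sd, upper) {
  if (is.infinite(upper)) return(stats::rnorm(n, mean, sd))
  lp <- stats::pnorm(upper, mean, sd, log.p = TRUE)
  u <- log(stats::runif(n)) + lp
  q <- stats::qnorm(u, log.p = TRUE)
  pmin(mean + sd * q, upper)
}

#' Bayesian linear mixed model by blocked Gibbs sampling
#'
#' Samples the posterior of the hierarchical model under a [prior_spec()]
#' with a blocked Gibbs sampler cycling through full conditionals:
#' (a) the population intercept (Normal) and each population effect
#' (Normal, or exact inverse-CDF truncated-Normal when an upper bound is
#' set); (b) per subject, the random intercept and condition-effect vector
#' jointly (multivariate Normal); (c) the variance components
#' (inverse-gamma). Multiple chains start from dispersed initial values.
#' With the default non-informative prior the posterior means numerically
#' reproduce the maximum-likelihood estimates of [fit_lme_ml()].
#'
#' Per-subject effects are never individually truncated: an upper bound on
#' a population effect restricts the population mean only, not the
#' individual effects.
#'
#' Within each iteration randomness is consumed in a fixed order: population
#' coefficients, then subjects in dataset order, then variances. Relabeling
#' subjects therefore permutes the stream, so population summaries are
#' invariant only up to Monte-Carlo error, not bit-exactly.
#'
#' @param dataset A [trial_dataset()] (same identifiability conditions as
#'   [fit_lme_ml()]).
#' @param prior A [prior_spec()]; default non-informative.
#' @param chains Number of chains (default 4).
#' @param warmup Discarded burn-in iterations per chain (default 1000).
#' @param draws Retained iterations per chain (default 1000).
#' @param thin Thinning interval (default 1).
#' @param seed RNG seed (required; one substream per chain).
#' @param fixed_variances Optional list with any of `tau2`, `omega2`,
#'   `sigma2` to hold fixed instead of sampling — used for conjugate
#'   validation and teaching, not routine analysis.
#' @return A list with `posterior` (class `nof1_posterior`: draws array
#'   `[iteration, chain, parameter]`, summary table with mean/SD/95%
#'   interval/split-R-hat/ESS, and the sampler settings) and `fit` (class
#'   `nof1_fit`, method `"B-LME"`, filled from posterior means). An R-hat
#'   above 1.05 on any parameter raises a convergence warning (not an
#'   error) and is flagged in the fit diagnostics.
#' @export
fit_lme_bayes <- function(dataset, prior = prior_spec(non_informative = TRUE),
                          chains = 4, warmup = 1000, draws = 1000, thin = 1,
                          seed, fixed_variances = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(prior, "prior_spec"))
  if (missing(seed)) stop("seed is required (no silent seeding)")
  dm <- design_matrix(dataset)
  subjects <- dataset$subjects
  N <- length(subjects)
  if (N < 2) stop("need at least 2 subjects")
  nonref <- dataset$conditions[-1]
  K <- length(nonref)
  if (K == 0) stop("need at least one non-reference condition")
  for (k in nonref) {
    if (length(unique(dm$subject[dm$X[, k] == 1])) < 2) {
      stop("not identifiable: fewer than 2 subjects observed in condition '",
           k, "'")
    }
  }

  pe_mean <- expand_prior_field(prior$effect_mean, nonref)
  pe_sd <- expand_prior_field(prior$effect_sd, nonref)
  pe_upper <- expand_prior_field(prior$effect_upper, nonref)
  a0 <- prior$variance_shape; b0 <- prior$variance_rate

  # per-subject sufficient statistics; Z_i = [1, x_i1 .. x_iK].
  # Hierarchically centered parameterization: the sampled subject vector
  # c_i = (a_i, b_i1..b_iK) is on the absolute scale with prior mean
  # (mu0, beta0) — this decouples mu0 from the likelihood and mixes far
  # better than sampling intercept deviations.
  n_tot <- length(dm$y)
  ZtZ <- Zty <- yty <- vector("list", N)
  for (i in seq_len(N)) {
    rows <- dm$subject == subjects[i]
    Z <- cbind(1, dm$X[rows, , drop = FALSE])
    yi <- dm$y[rows]
    ZtZ[[i]] <- crossprod(Z)
    Zty[[i]] <- drop(crossprod(Z, yi))
    yty[[i]] <- sum(yi * yi)
  }
  yty <- unlist(yty)

  par_names <- c("mu0", paste0("beta0[", nonref, "]"),
                 "tau2", paste0("omega2[", nonref, "]"), "sigma2",
                 paste0("mu_i[", subjects, "]"),
                 unlist(lapply(nonref, function(k)
                   paste0("beta_i[", subjects, ",", k, "]"))))
  n_par <- length(par_names)
  n_keep <- draws %/% thin
  out <- array(NA_real_, dim = c(n_keep, chains, n_par),
               dimnames = list(NULL, paste0("chain", seq_len(chains)),
                               par_names))

  # crude moment starts, jittered per chain for dispersion
  y_mean <- mean(dm$y); y_var <- stats::var(dm$y)

  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, 7000 + ch))
    mu0 <- y_mean + stats::rnorm(1, 0, sqrt(y_var) / 2)
    beta0 <- stats::rnorm(K, 0, sqrt(y_var) / 2)
    tau2 <- fixed_variances$tau2 %||% (y_var * stats::runif(1, 0.3, 3))
    omega2 <- rep(fixed_variances$omega2 %||%
                    (y_var * stats::runif(1, 0.3, 3)), K)
    sigma2 <- fixed_variances$sigma2 %||% (y_var * stats::runif(1, 0.3, 3))
    # c_i = (a_i, b_i1..b_iK), all on the absolute scale
    C <- matrix(0, nrow = N, ncol = K + 1)
    C[, 1] <- mu0
    C[, seq_len(K) + 1] <- rep(beta0, each = N)

    keep_row <- 0
    for (it in seq_len(warmup + draws)) {
      # (a) population coefficients (hyper-means of the subject effects)
      prec <- N / tau2 + 1 / prior$intercept_sd^2
      m <- (sum(C[, 1]) / tau2 +
              prior$intercept_mean / prior$intercept_sd^2) / prec
      mu0 <- stats::rnorm(1, m, sqrt(1 / prec))
      for (j in seq_len(K)) {
        prec_b <- N / omega2[j] + 1 / pe_sd[j]^2
        m_b <- (sum(C[, j + 1]) / omega2[j] + pe_mean[j] / pe_sd[j]^2) / prec_b
        beta0[j] <- rtruncnorm_upper(1, m_b, sqrt(1 / prec_b), pe_upper[j])
      }

      # (b) per-subject effects, jointly
      Dinv <- diag(1 / c(tau2, omega2), nrow = K + 1)
      dm_prior <- drop(Dinv %*% c(mu0, beta0))
      for (i in seq_len(N)) {
        P <- ZtZ[[i]] / sigma2 + Dinv
        h <- Zty[[i]] / sigma2 + dm_prior
        U <- chol(P)
        mu_c <- backsolve(U, forwardsolve(t(U), h))
        C[i, ] <- mu_c + backsolve(U, stats::rnorm(K + 1))
      }

      # (c) variance components
      if (is.null(fixed_variances$tau2)) {
        tau2 <- 1 / stats::rgamma(1, a0 + N / 2,
                                  rate = b0 + sum((C[, 1] - mu0)^2) / 2)
      }
      if (is.null(fixed_variances$omega2)) {
        for (j in seq_len(K)) {
          ss <- sum((C[, j + 1] - beta0[j])^2)
          omega2[j] <- 1 / stats::rgamma(1, a0 + N / 2, rate = b0 + ss / 2)
        }
      }
      if (is.null(fixed_variances$sigma2)) {
        sse <- sum(vapply(seq_len(N), function(i) {
          ci <- C[i, ]
          yty[i] - 2 * sum(ci * Zty[[i]]) + drop(ci %*% ZtZ[[i]] %*% ci)
        }, numeric(1)))
        sigma2 <- 1 / stats::rgamma(1, a0 + n_tot / 2,
                                    rate = b0 + max(sse, 0) / 2)
      }

      if (it > warmup && (it - warmup) %% thin == 0) {
        keep_row <- keep_row + 1
        out[keep_row, ch, ] <- c(mu0, beta0, tau2, omega2, sigma2,
                                 C[, 1] - mu0, C[, seq_len(K) + 1])
      }
    }
  }

  summ <- summarize_draws(out)
  settings <- list(chains = chains, warmup = warmup, draws = draws,
                   thin = thin, seed = seed, prior = prior,
                   fixed_variances = fixed_variances)
  posterior <- structure(list(draws = out, summary = summ,
                              settings = settings,
                              conditions = dataset$conditions,
                              subjects = subjects),
                         class = "nof1_posterior")

  pm <- stats::setNames(summ$mean, summ$parameter)
  subj_tab <- data.frame(subject = subjects,
                         intercept = pm["mu0"] +
                           pm[paste0("mu_i[", subjects, "]")],
                         stringsAsFactors = FALSE)
  for (k in nonref) {
    subj_tab[[paste0("effect_", k)]] <-
      unname(pm[paste0("beta_i[", subjects, ",", k, "]")])
  }
  rownames(subj_tab) <- NULL

  max_rhat <- suppressWarnings(max(summ$rhat, na.rm = TRUE))
  converged <- is.finite(max_rhat) && max_rhat <= 1.05
  if (!converged) {
    warning(sprintf("MCMC convergence warning: max split-R-hat = %.3f",
                    max_rhat))
  }
  fit <- new_fit_result("B-LME", mu0 = unname(pm["mu0"]),
                        beta0 = stats::setNames(
                          unname(pm[paste0("beta0[", nonref, "]")]), nonref),
                        tau2 = unname(pm["tau2"]),
                        omega2 = stats::setNames(
                          unname(pm[paste0("omega2[", nonref, "]")]), nonref),
                        sigma2 = unname(pm["sigma2"]),
                        subjects = subj_tab,
                        diagnostics = list(converged = converged,
                                           max_rhat = max_rhat,
                                           min_ess = suppressWarnings(
                                             min(summ$ess, na.rm = TRUE)),
                                           settings = settings))
  list(posterior = posterior, fit = fit)
}

# mean/sd/interval/diagnostics table from an [iter, chain, param] array
summarize_draws <- function(arr) {
  pn <- dimnames(arr)[[3]]
  res <- lapply(seq_along(pn), function(p) {
    d <- arr[, , p, drop = FALSE]
    dim(d) <- dim(arr)[1:2]
    v <- as.vector(d)
    data.frame(parameter = pn[p], mean = mean(v), sd = stats::sd(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)),
               rhat = rhat(d), ess = ess(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.nof1_posterior <- function(x, ...) {
  s <- x$settings
  cat(sprintf("posterior: %d chains x %d draws (warmup %d, thin %d), seed %d\n",
              s$chains, s$draws, s$warmup, s$thin, s$seed))
  pop <- x$summary[!grepl("_i\\[", x$summary$parameter), ]
  print(pop, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Export posterior draws to CSV
#'
#' One row per retained draw per chain, one column per parameter, plus
#' leading `chain` and `iteration` columns.
#'
#' @param posterior A `nof1_posterior` from [fit_lme_bayes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(posterior, path) {
  arr <- posterior$draws
  n_it <- dim(arr)[1]; n_ch <- dim(arr)[2]
  flat <- do.call(rbind, lapply(seq_len(n_ch), function(ch) {
    d <- arr[, ch, , drop = FALSE]
    dim(d) <- dim(arr)[c(1, 3)]
    colnames(d) <- dimnames(arr)[[3]]
    data.frame(chain = ch, iteration = seq_len(n_it), d,
               check.names = FALSE)
  }))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Export a posterior summary table to CSV
#'
#' Mean, SD, central 95% interval, split-R-hat and effective sample size
#' per parameter.
#'
#' @param posterior A `nof1_posterior`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  utils::write.csv(posterior$summary, path, row.names = FALSE)
  invisible(path)
}

#' Fit the same dataset under several priors
#'
#' Runs [fit_lme_bayes()] once per prior with identical MCMC settings and
#' the same seed, and tabulates population and per-subject estimates side
#' by side — the workflow used to contrast a weak prior with its truncated
#' counterpart.
#'
#' @param dataset A [trial_dataset()].
#' @param priors A named list of [prior_spec()] objects (>= 2).
#' @param chains,warmup,draws,thin,seed MCMC settings shared by all fits.
#' @return An object of class `nof1_prior_comparison`: `fits` (named list
#'   of [fit_lme_bayes()] results), `population` (long table: prior,
#'   parameter, mean, sd, q2.5, q97.5) and `subjects` (long table: prior,
#'   subject, condition, effect estimate).
#' @export
compare_priors <- function(dataset, priors, chains = 4, warmup = 1000,
                           draws = 1000, thin = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (length(priors) < 2) stop("need at least 2 priors to compare")
  if (is.null(names(priors)) || any(names(priors) == "")) {
    stop("priors must be a named list")
  }
  fits <- lapply(priors, function(pr) {
    fit_lme_bayes(dataset, prior = pr, chains = chains, warmup = warmup,
                  draws = draws, thin = thin, seed = seed)
  })
  pop <- do.call(rbind, lapply(names(fits), function(nm) {
    s <- fits[[nm]]$posterior$summary
    s <- s[!grepl("_i\\[", s$parameter),
           c("parameter", "mean", "sd", "q2.5", "q97.5")]
    cbind(prior = nm, s)
  }))
  nonref <- dataset$conditions[-1]
  subj <- do.call(rbind, lapply(names(fits), function(nm) {
    st <- fits[[nm]]$fit$subjects
    do.call(rbind, lapply(nonref, function(k) {
      data.frame(prior = nm, subject = st$subject, condition = k,
                 effect = st[[paste0("effect_", k)]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(pop) <- rownames(subj) <- NULL
  structure(list(fits = fits, population = pop, subjects = subj),
            class = "nof1_prior_comparison")
}

#' @export
print.nof1_prior_comparison <- function(x, ...) {
  cat("prior comparison across", length(x$fits), "priors\n")
  print(x$population[!grepl("^(tau2|omega2|sigma2)", x$population$parameter), ],
        digits = 4, row.names = FALSE)
  invisible(x)
}
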