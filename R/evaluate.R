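#' Root-mean-square error
#'
#' \eqn{\sqrt{\frac{1}{q}\sum_k (\hat\theta_k - \theta_k)^2}}: combines bias
#' and precision of a vector of estimates against the true values into a
#' single accuracy measure. Smaller is more accurate.
#'
#' @param estimates Numeric vector of estimates.
#' @param truths Numeric vector of true values, same length.
#' @return Nonnegative scalar.
#' @examples
#' rmse(c(1, 3), c(0, 0))  # sqrt(5)
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    stop("estimates and truths must have equal length")
  }
  if (length(estimates) == 0) stop("need at least one value")
  sqrt(mean((estimates - truths)^2))
}

method_labels <- c(ipd = "IPD", `f-lme` = "F-LME", `b-lme` = "B-LME")

normalize_methods <- function(methods) {
  m <- tolower(methods)
  m[m %in% c("lme", "flme", "freq")] <- "f-lme"
  m[m %in% c("bayes", "blme")] <- "b-lme"
  bad <- setdiff(m, names(method_labels))
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  unname(method_labels[m])
}

fit_one_method <- function(method, dataset, prior, mcmc, seed) {
  switch(method,
         "IPD" = fit_ipd(dataset),
         "F-LME" = fit_lme_ml(dataset),
         "B-LME" = fit_lme_bayes(dataset, prior = prior,
                                 chains = mcmc$chains %||% 2,
                                 warmup = mcmc$warmup %||% 300,
                                 draws = mcmc$draws %||% 500,
                                 seed = seed)$fit)
}

#' Run the parameter-recovery experiment for one scenario
#'
#' For each replicate: simulate one dataset, fit every requested method on
#' that same dataset (paired design), and record the per-replicate RMSE of
#' the per-subject treatment-effect predictions against the simulated
#' truth, together with all population parameter estimates. A replicate on
#' which any method fails is excluded from every method (pairwise
#' exclusion) and counted, so method comparisons stay paired. Deterministic
#' given the scenario seed.
#'
#' @param scenario A [scenario_spec()].
#' @param methods Subset of `c("IPD", "F-LME", "B-LME")` (case-insensitive).
#' @param replicates Optional override of `scenario$replicates` —
#'   the standard way to run a scaled-down version of a 1000-replicate
#'   scenario.
#' @param prior Prior for B-LME (default non-informative).
#' @param mcmc List of B-LME sampler settings (`chains`, `warmup`, `draws`);
#'   defaults are deliberately light (2 chains, 300 warmup, 500 draws) since
#'   the replicate loop multiplies their cost.
#' @return An object of class `nof1_comparison`: `results` (one row per
#'   replicate x method: `rmse_beta`, `omega_hat`, `mu0_hat`, `beta0_hat`,
#'   `tau2_hat`, `sigma2_hat`), `failures`, `scenario`, `elapsed` seconds.
#' @export
run_scenario <- function(scenario, methods = c("IPD", "F-LME"),
                         replicates = NULL,
                         prior = prior_spec(non_informative = TRUE),
                         mcmc = list()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  methods <- normalize_methods(methods)
  if (length(methods) == 0) stop("methods must be non-empty")
  reps <- replicates %||% scenario$replicates
  t0 <- proc.time()[["elapsed"]]

  rows <- list()
  failures <- list()
  for (r in seq_len(reps)) {
    sim <- simulate_dataset(scenario, r)
    truth <- sim$truth
    rep_rows <- list()
    failed <- FALSE
    for (m in methods) {
      fit <- tryCatch(
        fit_one_method(m, sim$dataset, prior, mcmc,
                       seed = derive_seed(scenario$seed, 500000 + r)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(replicate = r, method = m,
                     message = conditionMessage(fit),
                     stringsAsFactors = FALSE)
        failed <- TRUE
        break
      }
      st <- fit$subjects
      est <- st$effect_treatment[match(truth$subject, st$subject)]
      rep_rows[[m]] <- data.frame(
        replicate = r, method = m,
        rmse_beta = rmse(est, truth$beta_i),
        omega_hat = sqrt(unname(fit$omega2[["treatment"]])),
        mu0_hat = fit$mu0,
        beta0_hat = unname(fit$beta0[["treatment"]]),
        tau2_hat = fit$tau2, sigma2_hat = fit$sigma2,
        stringsAsFactors = FALSE)
    }
    if (!failed) rows <- c(rows, rep_rows)
  }

  results <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(replicate = integer(0), method = character(0),
               rmse_beta = numeric(0), omega_hat = numeric(0),
               mu0_hat = numeric(0), beta0_hat = numeric(0),
               tau2_hat = numeric(0), sigma2_hat = numeric(0))
  rownames(results) <- NULL
  structure(list(scenario = scenario, methods = methods,
                 results = results,
                 failures = if (length(failures) > 0)
                   do.call(rbind, failures) else NULL,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "nof1_comparison")
}

#' @export
print.nof1_comparison <- function(x, ...) {
  cat(sprintf("scenario %s: %d replicates x %d methods (%.1fs)\n",
              x$scenario$id, length(unique(x$results$replicate)),
              length(x$methods), x$elapsed))
  print(summary(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nof1_comparison <- function(object, ...) {
  r <- object$results
  out <- do.call(rbind, lapply(split(r, r$method), function(d) {
    data.frame(scenario = object$scenario$id, method = d$method[1],
               n_replicates = nrow(d),
               mean_rmse_beta = mean(d$rmse_beta),
               sd_rmse_beta = stats::sd(d$rmse_beta),
               mean_omega_hat = mean(d$omega_hat),
               mean_beta0 = mean(d$beta0_hat),
               mean_mu0 = mean(d$mu0_hat),
               mean_tau2 = mean(d$tau2_hat),
               mean_sigma2 = mean(d$sigma2_hat),
               n_failures = if (is.null(object$failures)) 0L else
                 length(unique(object$failures$replicate)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the benchmark over a scenario grid
#'
#' [run_scenario()] for every member of a grid (e.g. [scenario_grid()]),
#' with partial results retained if a scenario fails outright.
#'
#' @param grid List of [scenario_spec()] objects.
#' @param methods,replicates,prior,mcmc Passed to [run_scenario()].
#' @return An object of class `nof1_grid_result`: `comparisons` (named
#'   list), `errors` (per-scenario failure messages, if any).
#' @export
run_grid <- function(grid, methods = c("IPD", "F-LME"), replicates = NULL,
                     prior = prior_spec(non_informative = TRUE),
                     mcmc = list()) {
  if (length(grid) == 0) stop("grid must be non-empty")
  comparisons <- list()
  errors <- list()
  for (s in grid) {
    res <- tryCatch(run_scenario(s, methods = methods,
                                 replicates = replicates,
                                 prior = prior, mcmc = mcmc),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[s$id]] <- conditionMessage(res)
    } else {
      comparisons[[s$id]] <- res
    }
  }
  structure(list(comparisons = comparisons,
                 errors = if (length(errors) > 0) errors else NULL),
            class = "nof1_grid_result")
}

#' Tidy long-format summary of a grid run
#'
#' One row per scenario x method x statistic — the layout from which
#' distribution panels (RMSE by subjects x measurements) are redrawn.
#'
#' @param object A `nof1_grid_result` from [run_grid()].
#' @param ... Unused.
#' @return A data.frame with columns `scenario`, `method`, `statistic`,
#'   `value`.
#' @export
summary.nof1_grid_result <- function(object, ...) {
  wide <- do.call(rbind, lapply(object$comparisons, summary))
  stats_cols <- setdiff(names(wide), c("scenario", "method"))
  long <- do.call(rbind, lapply(stats_cols, function(s) {
    data.frame(scenario = wide$scenario, method = wide$method,
               statistic = s, value = as.numeric(wide[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long[order(match(long$scenario, names(object$comparisons)),
             long$method, long$statistic), ]
}

#' @export
print.nof1_grid_result <- function(x, ...) {
  cat(sprintf("grid run: %d scenarios", length(x$comparisons)))
  if (!is.null(x$errors)) cat(sprintf(" (%d failed)", length(x$errors)))
  cat("\n")
  wide <- do.call(rbind, lapply(x$comparisons, summary))
  print(wide[, c("scenario", "method", "n_replicates", "mean_rmse_beta",
                 "mean_omega_hat", "mean_beta0")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-replicate RMSE records of a grid run, stacked
#'
#' @param grid_result A `nof1_grid_result`.
#' @return A data.frame: `scenario`, `replicate`, `method`, `rmse_beta`,
#'   `omega_hat`, and the population estimates — one row per replicate per
#'   method, suitable for external plotting.
#' @export
replicate_records <- function(grid_result) {
  out <- do.call(rbind, lapply(grid_result$comparisons, function(cmp) {
    cbind(scenario = cmp$scenario$id, cmp$results)
  }))
  rownames(out) <- NULL
  out
}
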