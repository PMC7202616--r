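#' Population parameters of the hierarchical N-of-1 model
#'
#' The generating model for a two-condition series of N-of-1 trials is
#' \deqn{Y_{ij} = \mu_0 + \mu_i + X_{ij}\beta_i + \epsilon_{ij}}
#' with \eqn{\epsilon_{ij} \sim N(0, \sigma^2)}, subject intercept deviations
#' \eqn{\mu_i \sim N(0, \tau^2)} and subject treatment effects
#' \eqn{\beta_i \sim N(\beta_0, \omega^2)}, all mutually independent.
#'
#' Defaults are the benchmark study conditions: control mean 0 with
#' between-subject SD 1, average treatment effect -2 with between-subject
#' SD 0.5 (so the heterogeneity-to-noise SD ratios are 1:1 for intercepts
#' and 0.5:1 for treatment effects), and unit residual variance.
#'
#' @param mu0 Population intercept (control-condition mean).
#' @param tau2 Between-subject intercept variance, `>= 0`.
#' @param beta0 Population (average) treatment effect.
#' @param omega2 Between-subject treatment-effect variance, `>= 0`.
#' @param sigma2 Residual (within-subject) variance, `>= 0` (zero is only
#'   meaningful for generating degenerate noiseless data; estimation
#'   requires positive residual variance).
#' @return An object of class `population_parameters`.
#' @export
population_parameters <- function(mu0 = 0, tau2 = 1, beta0 = -2,
                                  omega2 = 0.25, sigma2 = 1) {
  if (tau2 < 0 || omega2 < 0) stop("variance components must be >= 0")
  if (sigma2 < 0) stop("residual variance must be >= 0")
  structure(list(mu0 = mu0, tau2 = tau2, beta0 = beta0,
                 omega2 = omega2, sigma2 = sigma2),
            class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat(sprintf(
    "population parameters: mu0=%g tau2=%g beta0=%g omega2=%g sigma2=%g\n",
    x$mu0, x$tau2, x$beta0, x$omega2, x$sigma2))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario fixes the trial-series size (`n_subjects` subjects, each with
#' `t_per_condition` measurements under control and the same number under
#' treatment), the generating [population_parameters()], the replicate count
#' and the root RNG seed. Per-replicate substreams are derived from
#' `(seed, replicate_index)`, so any replicate is reproducible in isolation
#' and runs over replicates `1..k` are prefixes of longer runs.
#'
#' @param n_subjects Number of subjects (independent N-of-1 trials), `>= 2`.
#' @param t_per_condition Measurements per subject in each condition, `>= 1`.
#'   Each subject contributes `2 * t_per_condition` observations. Set
#'   `t_is_total = TRUE` to read the value as the total per-subject
#'   measurement count instead (must then be even).
#' @param replicates Number of simulation replicates, `>= 1`.
#' @param seed Root RNG seed (integer).
#' @param params A [population_parameters()] object.
#' @param t_is_total Interpret `t_per_condition` as the per-subject total
#'   split evenly across the two conditions.
#' @param id Optional scenario label; defaults to `"n<The n>_t<t>"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_subjects, t_per_condition, replicates = 1000,
                          seed = 1, params = population_parameters(),
                          t_is_total = FALSE, id = NULL) {
  stopifnot(inherits(params, "population_parameters"))
  if (t_is_total) {
    if (t_per_condition %% 2 != 0) stop("total measurement count must be even")
    t_per_condition <- t_per_condition / 2
  }
  if (n_subjects < 2) stop("need n_subjects >= 2")
  if (t_per_condition < 1) stop("need t_per_condition >= 1")
  if (replicates < 1) stop("need replicates >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 t_per_condition = as.integer(t_per_condition),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), params = params,
                 id = id %||% sprintf("n%d_t%d", n_subjects, t_per_condition)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario %s: %d subjects x 2x%d measurements, %d replicates, seed %d\n",
              x$id, x$n_subjects, x$t_per_condition, x$replicates, x$seed))
  print(x$params)
  invisible(x)
}

#' Simulate one replicate dataset from a scenario
#'
#' For each subject, draws the true intercept deviation
#' \eqn{\mu_i \sim N(0, \tau^2)} and treatment effect
#' \eqn{\beta_i \sim N(\beta_0, \omega^2)}, then emits `t` control and `t`
#' treatment observations in a uniformly random per-subject order (every
#' subject has equal counts in both conditions; the ordering differs randomly
#' between subjects) with residual noise \eqn{N(0, \sigma^2)}.
#'
#' The RNG stream is fully determined by `(scenario$seed, replicate_index)`:
#' the same pair always yields a bit-identical dataset.
#'
#' @param scenario A [scenario_spec()].
#' @param replicate_index Replicate counter, `>= 1`.
#' @return A list with `dataset` (a [trial_dataset()] with conditions
#'   `"control"` and `"treatment"`) and `truth` (a data.frame of per-subject
#'   true `mu_i` deviations and absolute `beta_i` effects).
#' @export
simulate_dataset <- function(scenario, replicate_index = 1) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- scenario$params
  n <- scenario$n_subjects
  t <- scenario$t_per_condition
  set.seed(derive_seed(scenario$seed, replicate_index))

  mu_i <- stats::rnorm(n, 0, sqrt(p$tau2))
  beta_i <- stats::rnorm(n, p$beta0, sqrt(p$omega2))
  subj_ids <- sprintf("s%0*d", max(2L, nchar(n)), seq_len(n))

  base <- rep(c("control", "treatment"), each = t)
  cond <- unlist(lapply(seq_len(n), function(i) sample(base)))
  idx <- rep(seq_len(n), each = 2 * t)
  trt <- as.numeric(cond == "treatment")
  y <- p$mu0 + mu_i[idx] + trt * beta_i[idx] +
    stats::rnorm(n * 2 * t, 0, sqrt(p$sigma2))

  dataset <- trial_dataset(
    data.frame(subject = subj_ids[idx], time = rep(seq_len(2 * t), n),
               condition = cond, outcome = y, stringsAsFactors = FALSE),
    conditions = c("control", "treatment"), reference = "control")
  truth <- data.frame(subject = subj_ids, mu_i = mu_i, beta_i = beta_i,
                      stringsAsFactors = FALSE)
  list(dataset = dataset, truth = truth)
}

#' The nine-scenario benchmark grid
#'
#' Cartesian product of `n_subjects` in \{20, 30, 40\} and `t_per_condition`
#' in \{10, 20, 30\}, each carrying the default [population_parameters()]
#' and 1000 replicates (overridable for scaled-down runs).
#'
#' @param seed Root seed; each scenario receives a distinct derived seed.
#' @param replicates Replicates per scenario (default 1000).
#' @param params Generating parameters shared by all scenarios.
#' @return A named list of 9 [scenario_spec()] objects.
#' @export
scenario_grid <- function(seed = 1, replicates = 1000,
                          params = population_parameters()) {
  cells <- expand.grid(t = c(10L, 20L, 30L), n = c(20L, 30L, 40L))
  grid <- lapply(seq_len(nrow(cells)), function(i) {
    scenario_spec(cells$n[i], cells$t[i], replicates = replicates,
                  seed = derive_seed(seed, 100000 + i), params = params)
  })
  names(grid) <- vapply(grid, function(s) s$id, character(1))
  grid
}
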