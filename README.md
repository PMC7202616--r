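# nof1lme

Simulation and mixed-model analysis of series of N-of-1 trials.

An N-of-1 trial is a crossover experiment run within a single subject,
alternating treatment and control periods over time. A *series* of such
trials — one per subject — supports both population-level inference and
genuinely individual treatment-effect estimates, which makes the design
attractive for personalized nutrition and lifestyle research where
responses are known to be heterogeneous. The statistical question is how
to combine the trials. This package implements and compares the three
standard strategies:

* **IPD** — two-step individual-participant-data meta-analysis: an
  ordinary least-squares fit per subject, then a (unit-)weighted mean of
  the subject-level estimates;
* **F-LME** — a frequentist linear mixed-effects model fitted by maximum
  likelihood, with empirical-Bayes (BLUP) per-subject predictions;
* **B-LME** — the same model fitted by a blocked Gibbs sampler, which
  additionally accepts informative priors, including priors *truncated*
  at an upper bound (e.g. "the average subject does not gain weight").

## The model

For subject *i* = 1, …, *N* at measurement *j* = 1, …, *J<sub>i</sub>*,

> Y<sub>ij</sub> = μ₀ + μ<sub>i</sub> + X<sub>ij</sub> β<sub>i</sub> + ε<sub>ij</sub>

with ε<sub>ij</sub> ~ N(0, σ²), subject intercept deviations
μ<sub>i</sub> ~ N(0, τ²) and subject treatment effects
β<sub>i</sub> ~ N(β₀, ω²), all mutually independent. X<sub>ij</sub> is the
0/1 condition indicator (one indicator per non-reference condition in
multi-condition designs, each with its own β and ω²). IPD estimates each
subject separately and aggregates; the mixed models estimate everything
jointly, shrinking individual effects toward the population mean.
Estimator accuracy is compared by the root-mean-square error
RMSE = √(1/q Σ (β̂<sub>i</sub> − β<sub>i</sub>)²) of the per-subject
effect predictions against the simulated truth, one RMSE per replicate.

## Worked example

Simulate one replicate of a 20-subject series (10 measurements per
condition per subject) from the default benchmark parameters
(μ₀ = 0, τ² = 1, β₀ = −2, treatment-effect SD ω = 0.5, σ² = 1), and fit
two of the estimators:

```r
library(nof1lme)
scenario <- scenario_spec(n_subjects = 20, t_per_condition = 10, seed = 42)
sim <- simulate_dataset(scenario, replicate_index = 1)

fit_ipd(sim$dataset)
#> IPD fit: 20 subjects
#>   mu0   = -0.1176   tau = 1.0844
#>   beta0[treatment] = -1.8024   omega[treatment] = 0.7134
#>   sigma = 0.9605

fit_lme_ml(sim$dataset)
#> F-LME fit: 20 subjects
#>   mu0   = -0.1176   tau = 1.0583
#>   beta0[treatment] = -1.8024   omega[treatment] = 0.5838
#>   sigma = 0.9584
```

Both estimators agree on the population effect (−1.80; the truth is −2),
but the IPD heterogeneity estimate ω̂ = 0.71 sits well above the
generating value 0.5 — the sampling error of each subject's OLS effect
inflates the observed dispersion — while the mixed model's ω̂ = 0.58 is
much closer. Repeating this comparison over 50 replicates of the same
scenario makes the pattern systematic:

```r
cmp <- run_scenario(scenario, methods = c("IPD", "F-LME"), replicates = 50)
summary(cmp)[, c("method", "mean_rmse_beta", "mean_omega_hat", "mean_beta0")]
#>   method mean_rmse_beta mean_omega_hat mean_beta0
#> 1  F-LME      0.3519476      0.4561821  -1.998069
#> 2    IPD      0.4465223      0.6598930  -1.998069
```

The mixed model predicts the individual effects more accurately (mean
RMSE 0.35 vs 0.45) and centers its heterogeneity estimate near the true
0.5, while IPD is biased upward (0.66). `run_grid(scenario_grid(...))`
runs the full 3 × 3 benchmark (20/30/40 subjects × 10/20/30 measurements
per condition).

### Priors on a multi-condition self-measurement study

`generate_empirical_fixture()` creates a synthetic 12-subject daily
body-weight study with three consecutive 3-week conditions, per-subject
missingness (up to 41 of 63 days) and two subjects with swapped
condition order. `analyze_empirical()` fits the Bayesian model under a
weak prior on both population condition effects (Normal(−1, 5²) kg) and
under the same prior truncated at 0:

```r
fx <- generate_empirical_fixture(seed = 1)
rep <- analyze_empirical(fx, chains = 2, warmup = 400, draws = 600, seed = 2)
rep$population_summary
#>       prior         parameter      mean        sd      q2.5      q97.5
#>        weak beta0[condition2] -1.411972 0.2760870 -1.955804 -0.8847056
#>        weak beta0[condition3] -1.290974 0.2716409 -1.839518 -0.7678651
#>    negative beta0[condition2] -1.402623 0.2570788 -1.930447 -0.9014822
#>    negative beta0[condition3] -1.294170 0.2790768 -1.860675 -0.7508739
```

Here the data carry a clearly negative effect, so the truncated
("negative") prior barely moves the estimates; under every truncated fit
the population-effect draws never exceed 0, while individual effects
remain unrestricted.

## Command line

A thin wrapper around the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(find.package("nof1lme"))')/cli/nof1.R" \
  simulate --config scenario.yaml --out out_dir
```

Subcommands: `simulate`, `benchmark`, `fit`, `empirical`. Options come
from a YAML config with flag overrides; every stochastic run requires a
seed and records its effective configuration in `run_metadata.txt`.
Exit codes: 0 success, 1 runtime failure, 2 usage error.

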