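---
title: "Models and methods behind nof1lme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nof1lme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model the package implements, the
estimators and their numerical details, the design of the synthetic-data
generators, and the choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The hierarchical model

A series of N-of-1 trials measures each of $N$ subjects repeatedly under a
reference (control) condition and one or more treatment conditions. For
subject $i$ at measurement $j$,

$$Y_{ij} = \mu_0 + \mu_i + \sum_k X_{ijk}\,\beta_{ik} + \varepsilon_{ij},$$

with $\varepsilon_{ij} \sim N(0, \sigma^2)$, subject intercept deviations
$\mu_i \sim N(0, \tau^2)$ and subject effects
$\beta_{ik} \sim N(\beta_{0k}, \omega_k^2)$, all mutually independent.
$X_{ijk}$ is the 0/1 indicator of non-reference condition $k$; reference
rows are all zeros, so indicators depend only on condition labels, never on
calendar position — subjects who received the conditions in a different
order are handled identically.

The model deliberately assumes:

* **no carry-over** — each condition's effect is fully washed out before
  the next period contributes;
* **no time trend** — the effect of a condition is the same whenever it
  occurs;
* **independent random effects** — no intercept–slope correlation
  parameter ($\mathrm{diag}(\tau^2, \omega_1^2, \dots)$ covariance).

The first two are known to be violated by real self-measurement data
(body weight drifts, and weight lost in one period persists into the
next); they are kept because they define the common ground on which the
three estimators are compared. The third keeps the model identical across
the IPD, likelihood and Bayesian routes.

Missing outcomes are retained in the `trial_dataset` container but
excluded from every likelihood and regression (complete-case per
observation). No imputation is offered: the estimators themselves handle
unbalanced subjects, and imputation would change what is being compared.

## The three estimators

### Two-step IPD meta-analysis

`fit_subject_ols()` fits each subject by OLS on the condition indicators —
with dummy coding this is the condition-means model, so the subject effect
is a difference of condition means and the residual variance uses
denominator (observations − parameters). `aggregate_ipd()` then takes
(unit-)weighted means of the subject-level estimates. Between-subject SDs
are the weighted *sample* SDs of the raw per-subject estimates: they are
not parameters of this estimator, and because each subject's OLS effect
carries sampling error of order $\sigma^2/t$, the observed dispersion is
systematically wider than the true heterogeneity. This is the source of
the upward bias in $\hat\omega$ that the benchmark quantifies; it shrinks
as measurements per subject grow. Inverse-variance weights can be supplied
explicitly, but unit weights are the default because the benchmark design
is balanced. Subjects lacking a condition contribute to the intercept
aggregation only, and are counted in the diagnostics rather than silently
dropped.

### Frequentist mixed model

`fit_lme_ml()` maximizes the marginal likelihood in which, per subject,
outcomes are jointly Normal with covariance
$\sigma^2 I + \tau^2 J + \sum_k \omega_k^2 x_k x_k^\top$. The
optimization is delegated to `lme4::lmer()` with one random-intercept term
and one independent random-slope term per condition — exactly this
marginal model — rather than a hand-written optimizer: `lme4`'s profiled
deviance and PLS machinery are more robust near the variance-component
boundary than a generic quasi-Newton on log-variances, and boundary
estimates ($\hat\omega^2 = 0$) are legitimate ML solutions here, not
failures. The test suite keeps an independent check: a brute-force
maximization of the same marginal likelihood (coarse log-variance grid
with closed-form GLS coefficients at each node, then a Nelder–Mead
polish) must agree with the attained log-likelihood to $10^{-4}$ on a toy
dataset. ML is the default to keep the estimand aligned across methods;
REML is available (`reml = TRUE`) with the usual caveat that its variance
estimates differ at small $N$.

`predict_subject_effects()` computes empirical-Bayes (BLUP) predictions at
any supplied parameter values: for subject design $Z_i = [1, x_{i1},
\dots]$ and prior covariance $D = \mathrm{diag}(\tau^2, \omega_k^2)$, the
deviation posterior mean is $(Z_i^\top Z_i/\sigma^2 +
D^{-1})^{-1} Z_i^\top r_i / \sigma^2$. Components whose variance falls
below a floor of $10^{-10}$ are pinned to the population value (complete
shrinkage) instead of entering a near-singular solve. One property worth
stating precisely: the *joint* intercept+slope predictor shrinks the
dispersion of the subject effects around $\hat\beta_0$, but an individual
subject's prediction can move slightly *away* from $\hat\beta_0$ relative
to its raw contrast, because intercept information leaks into the slope.
The strict per-subject inequality holds only in the diffuse-intercept
limit, where the predictor reduces to a scalar shrinkage of the contrast;
the tests assert both forms.

### Bayesian mixed model

`fit_lme_bayes()` is a blocked Gibbs sampler written for this model.
Full conditionals:

1. population coefficients — Normal; a population effect with an upper
   truncation bound is drawn from its truncated-Normal conditional by
   inverse-CDF sampling *in log probability space*
   (`qnorm(log(u) + pnorm(bound, log.p = TRUE), log.p = TRUE)`), which is
   exact, loop-free and stable even when nearly all conditional mass lies
   beyond the bound;
2. per-subject effect vectors $(a_i, b_{i1}, \dots)$ — jointly Normal via
   a Cholesky solve of the $(K{+}1)\times(K{+}1)$ posterior precision;
3. variance components — inverse-gamma (conjugate).

The sampler uses a **hierarchically centered** parameterization: subject
intercepts are sampled on the absolute scale $a_i \sim N(\mu_0, \tau^2)$,
so $\mu_0$ appears only as a hyper-mean, mirroring how the condition
effects are treated. With per-subject data as informative as it is in
these designs, the non-centered alternative couples $\mu_0$ tightly to
the likelihood and mixes an order of magnitude worse; centering removes
that bottleneck. Within each iteration randomness is consumed in a fixed
order (population coefficients, subjects in dataset order, variances), so
runs are bit-reproducible given the seed, and relabeling subjects changes
the stream — population summaries are then invariant up to Monte-Carlo
error, not bit-exactly.

Priors (`prior_spec()`): Normal on each population effect with optional
upper truncation; vague Normal on the intercept; inverse-gamma(0.001,
0.001) on all variance components. The variance prior is a documented
sensitivity point — it is weakly informative and conjugate, and nothing
in the empirical workflow pins it down, so it is surfaced in the
configuration rather than hidden. "Non-informative" is operationalized as
Normal(0, $1000^2$) on coefficients, diffuse enough that the posterior is
numerically governed by the likelihood. A truncated population prior
never truncates the per-subject effects: the bound restricts what the
*average* subject does, not what any individual does.

Defaults are 4 chains × (1000 warmup + 1000 retained) draws with
dispersed starts and a mandatory, explicit seed. Convergence is
summarized by split-$\hat R$ and an effective sample size from Geyer's
initial monotone sequence; $\hat R > 1.05$ on any parameter produces a
warning and a diagnostics flag, not an error, so that scaled-down
exploratory runs still return their output.

**Frequentist–Bayes agreement.** With the non-informative prior the
posterior is likelihood-dominated and the location parameters
($\mu_0$, $\beta_0$) reproduce the ML estimates to within Monte-Carlo
error. For variance components the *posterior mean* carries a known
$O(1/N)$ upward offset relative to the ML point estimate (the marginal
posterior of a variance is right-skewed; its mean exceeds its mode). The
package therefore frames the equivalence checks on the SD scale that
`nof1_fit` reports ($\hat\tau$, $\hat\omega$, $\hat\sigma$), where the
offset is roughly halved; this is a statement about comparing two point
summaries of the same information, not about either method being wrong.

## The simulator and the benchmark

`scenario_spec()` fixes a scenario: $n$ subjects, $t$ measurements per
condition per subject (each subject contributes $2t$ observations), the
generating parameters, replicate count and root seed. $t$ is interpreted
per condition because the benchmark design gives every subject an equal
number of measurements under treatment and control; a `t_is_total` switch
supports the alternative per-subject-total reading. Each subject's
condition sequence is an independent uniformly random permutation of the
multiset $\{t \times \text{control}, t \times \text{treatment}\}$ — the
minimal-assumption way to make the order "randomly differ between
subjects" without imposing block structure.

Default generating parameters are $\mu_0 = 0$, $\tau^2 = 1$,
$\beta_0 = -2$, $\omega^2 = 0.25$, $\sigma^2 = 1$: the heterogeneity-to-
noise ratios are 1:1 for intercepts and 0.5:1 for treatment effects on
the SD scale. The treatment-effect heterogeneity is deliberately
parameterized so its **SD is 0.5** — the quantity the benchmark tracks
and the value its recovery checks target — rather than its variance.

RNG protocol: one root seed; the substream for replicate $r$ is derived
arithmetically from `(seed, r)`, so any replicate is reproducible in
isolation and a scaled-down run over replicates $1..k$ is a prefix of the
full run. Derived seeds stay below $2^{31}$.

`run_scenario()` feeds byte-identical datasets to every requested method
(paired design), computes one RMSE per replicate over that replicate's
$n$ per-subject effect predictions — so the benchmark distribution is a
distribution *across replicates*, not across subjects — and excludes a
replicate from *all* methods if any method fails on it, keeping
comparisons paired. The scenario grid defaults to 1000 replicates;
scaled-down runs set `replicates`. The Bayesian model participates at
reduced replicates by default (its per-fit cost is two to three orders of
magnitude above the other methods); full 1000-replicate parity is a
long-running mode, not the default. The checks shipped with the package
use 200 replicates for recovery and ordering properties and 20 paired
replicates for the frequentist–Bayes agreement — sizes at which the
Monte-Carlo error of the checked means is comfortably inside the asserted
tolerances.

## The empirical-style fixture

`generate_empirical_fixture()` emulates the *structure* of a 12-subject
daily body-weight self-measurement study: 63 possible daily measurements
in three consecutive 21-day condition blocks (usual lifestyle; reduced
high-caloric snack intake; increased physical activity), per-subject
missing-day counts up to 41 of 63 realized exactly, and two subjects who
swapped the order of conditions 2 and 3. `map_day_to_condition()` maps
days 1–21 / 22–42 / 43–63 to conditions, honoring swaps; weeks are
7-observation windows, so the schedule is exactly $9 \times 7$ days.

Where the fixture's quantitative settings were open, they were chosen
once as realistic magnitudes for daily weight data and not revisited:
baseline weights $N(75, 10^2)$ kg; mean condition effects of −1 kg
(snacks) and −1.5 kg (activity) with between-subject SDs of 1 and 1.2 kg,
large enough that some subjects gain weight; day-to-day noise SD 0.6 kg.
Missing days are deleted at random subject-wise, constrained so every
condition keeps at least two observed days per subject.

What the fixture does **not** emulate — and hence what passing tests do
not show about real data: gradual within-period weight drift, carry-over
between periods, order effects, and any dependence of missingness on the
outcome. Effects switch on instantaneously and noise is i.i.d., exactly
matching the model assumptions. The fixture validates the *machinery*
(mapping, missingness bookkeeping, prior contracts); it cannot validate
the model against the violations real data exhibit.

`analyze_empirical()` runs the two-prior workflow: a weak prior
Normal(−1 kg, 5² kg²) on both population condition effects, and the same
prior truncated at 0 ("negative" prior — the average subject is assumed
not to gain weight). The same prior is used for both conditions,
expressing no a-priori difference between the interventions, and the
truncation applies to the population means only. Outputs are CSV tables
(population summaries by prior, per-subject period trajectories,
per-subject condition-3 effects under both priors) plus a metadata file
sufficient to reproduce the run.

## Numerical choices, degenerate inputs, limitations

* CSV outcomes are written with 17 significant digits so doubles
  round-trip bit-exactly; missing outcomes are empty cells.
* Variance floor $10^{-10}$ in the EB predictor; `lmer` boundary
  (singular) fits are accepted as legitimate estimates with the
  convergence flag carrying any optimizer complaints.
* Noiseless degenerate data (zero residual spread) is allowed in the
  simulator (`sigma2 = 0` generates exact means) and handled by the ML
  route (variances at the boundary, exact coefficients); the Gibbs
  sampler assumes stochastic data — with zero residual spread its
  variance conditionals collapse toward the prior floor and chains can
  become numerically fragile.
* Non-identifiable designs (fewer than 2 subjects observed in a
  non-reference condition) are rejected with an error before fitting.
* The IPD aggregation is the simple weighted mean; random-effects
  meta-analytic variance estimators (DerSimonian–Laird and relatives) are
  out of scope, as are autocorrelated errors, time trends, covariates,
  imputation, and sample-size rules.
* MCMC is plain Gibbs: no HMC/NUTS, no model-comparison criteria. For the
  model sizes targeted here (tens of subjects, thousands of observations)
  the conjugate blocks mix well; strongly unbalanced or near-degenerate
  data may need longer chains, which the $\hat R$/ESS diagnostics will
  indicate.
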