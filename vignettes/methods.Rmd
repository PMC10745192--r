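---
title: "Methods: three linked demographic estimators and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three linked demographic estimators and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestdemog)
```

`nestdemog` estimates three demographic parameters of plot-breeding
songbirds — nest density, daily nest survival, adult density — and tests
whether adult pair density tracks nest density. This vignette documents
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Nest density: line-transect distance sampling

Nests are found by walking parallel transects and recording the
perpendicular distance `x` of each nest from its line. Detection falls
off with distance according to `g(x)` with `g(0) = 1`; the conditional
likelihood of the observed distances is
`L = prod_i g(x_i) / integral_0^w g(u) du`, maximized over the key
function's parameters. Three keys are supported (half-normal, hazard-rate
with shape `b >= 1`, uniform), optionally multiplied by cosine,
simple-polynomial, or Hermite-polynomial adjustment series (rescaled so
`g(0) = 1`), or with covariates acting on `log(sigma)`. Adjustments and
covariates are never combined in one model, the conventional restriction
for covariate distance sampling. Candidates are ranked by AICc with `n`
equal to the number of detections.

Density per stratum is `D = n / (2 w L Pa)`, converted to nests per 25 ha
(the plot size). `Pa` is the average detection probability within the
truncation distance `w`; under covariate models it is the
Horvitz–Thompson average `n / sum(1/p_i)`. The variance combines the
encounter-rate variance across transects (the stratified
sample-variance estimator over transect rows, with transect effort
`length x rounds` as the weight) with the delta-method variance of `Pa`
from the inverse Hessian. Confidence intervals are log-normal with
Satterthwaite degrees of freedom combining the two components. Degenerate
cases are handled explicitly: a single-transect stratum falls back to a
Poisson encounter-rate variance with a warning, and strata with fewer
than two detections are dropped (a detection function needs at least two
data points, so the pipeline applies the same two-nest rule when
producing plot-level estimates).

Design choices made where the design was genuinely open:

* **Truncation.** Default `w` is the largest observed distance,
  configurable. Transect observers search a narrow corridor (the
  generator's default scale puts the mean detection distance near 5.4 m),
  so there is no long tail that truncation would need to trim.
* **Survey rounds.** Rounds within a season are pooled: detections are
  combined and effort is summed (`L = length x rounds`). The generator
  treats rounds as independent snapshots of a nest population at its
  season-constant density (staggered nesting means a different cohort is
  active at each round), which makes the pooled estimator unbiased for
  that snapshot density and avoids re-detection bookkeeping.
* **Adjustment orders.** Cosine 2 and 2–3, polynomial 4 and 4+6, Hermite
  4 and 4+6 — standard practice.
* **Optimizer.** `nlminb` on log-transformed parameters
  (`log sigma`, `log(b - 1)`), relative tolerance 1e-12, three starting
  scales (0.5x, 1x, 2x the root-mean-square distance); the best converged
  start wins. A grid check flags adjusted detection functions that are
  non-monotone or exceed one. Invalid parameter regions (non-positive
  `g` or integral) return a large finite penalty rather than `NaN`.

## Nest survival: the logistic-exposure model

Visit histories are decomposed into exposure intervals: `t` days between
consecutive checks, outcome `y = 1` if the nest was still active (or
fledged) at the end, `y = 0` if it had failed. An interval survives with
probability `theta^t`, with `logit(theta) = x'beta + u_plot` and
`u_plot ~ N(0, sigma^2)`. The marginal likelihood integrates `u` by
Gauss–Hermite quadrature (10 nodes by default), evaluated as a single
vectorized `n x nodes` array with a log-sum-exp reduction — accurate to
well below estimation error for the moderate plot SDs seen in these data
(the `t = 1` case reduces exactly to logistic regression, which the test
suite verifies against `glm` and `lme4::glmer`). Seasonal survival is
`theta^period` with species-specific periods (19 days Brewer's, 15 days
vesper by default).

Open-design choices:

* **Exposure of failed intervals.** Full interval length by default, with
  a `midpoint` option (the classic Mayfield halving); field protocols
  rarely record the exact failure day.
* **Stage at interval start** labels the whole interval; intervals
  spanning hatch are not split. With ~3-day visit intervals at most one
  interval per nest spans hatch, and splitting would require an assumed
  within-interval failure time.
* **AICc sample size** is the number of intervals, the convention used
  by nest-survival software.
* **Separation and rank deficiency.** Coefficients beyond ±15 on the
  logit scale trigger a warning; a rank-deficient design matrix is an
  error naming the columns.
* The apparent-success and failure-cause summaries are deliberately
  descriptive (counts and fractions); censored histories (no terminal
  fate) are excluded by default and countable on request.

## Adult abundance: the dependent double-observer model

Two observers walk together; the secondary records only birds the
primary missed. With latent abundance `N ~ Poisson(lambda)`, primary
detection `p1` and secondary detection `p2`, marginalizing `N` exactly
gives independent Poisson counts `x1 ~ Poisson(lambda p1)` and
`x2 ~ Poisson(lambda (1 - p1) p2)`. The sampler therefore never needs
data augmentation; the test suite proves the identity against a
brute-force sum over the latent count. Abundance is modelled as
`log lambda = alpha_sp + beta SGI + gamma_yr + eps_plot`,
`eps ~ N(0, sigma^2)`; detection as
`logit p = delta_obs + eta_sp + zeta_yr` with reference coding for
species and year offsets and one intercept per observer. Priors are
Normal with variance 1000 on every linear-predictor coefficient
(interpreting the conventional vague-normal prior as a variance) and
Uniform(0, 100) on `sigma`. Repeat visits are conditionally independent
replicates of a shared plot-year `lambda` (a closed season).

Sampling is Metropolis-within-Gibbs: scalar random-walk updates for the
fixed effects, a vectorized element-wise update for the plot effects, and
a random-walk update for `sigma` within its support. Two mixture kernels
improve mixing of the hierarchy: an independence proposal for `sigma`
drawn from its Uniform(0, 100) prior, and a prior-refresh proposal for
the plot effects (`eps' ~ N(0, sigma)`, accepted on the likelihood ratio
alone since the prior cancels). Proposal scales adapt toward a 0.3
acceptance rate during burn-in only and are frozen afterward, preserving
detailed balance; the adaptation factor is `exp(0.4 (rate - 0.3))` every
50 iterations, with scales clamped to `[1e-3, 50]`. Chains start from
overdispersed values around a method-of-moments initialization
(`p0 = 1 - sum(x2)/sum(x1)`, floored at 0.01). Defaults follow the
standard protocol: 3 chains, 10,000 iterations, 1,000 burn-in.
Convergence is summarized by split-Rhat (each chain halved) with the
conventional 1.1 flag threshold and an effective sample size from
combined-chain autocorrelations (initial-positive-sequence truncation,
lags capped at 2,000, autocovariances via `stats::acf`). A constant
parameter reports `NA` for Rhat. A prior-only sampling mode (likelihood
zeroed) exists purely so the tests can verify that the sampler recovers
the Uniform(0, 100) prior of `sigma` — a distributional check of the
whole kernel.

Pair density is `lambda / 2` under an assumed 1:1 sex ratio, summarized
by posterior mean, median and central 95% credible interval per
plot-year-species.

## Density dependence

Plot-level nest density point estimates and posterior-mean pair densities
are inner-joined (default keys plot and species, averaging over years;
duplicate pre-aggregation keys are an error, unmatched records are
logged — typically plots excluded by the two-nest rule). The association
is tested with a Pearson correlation and a two-sided t-based p-value on
`n - 2` degrees of freedom, and summarized by pair:nest ratios overall
and by enrollment stratum. Estimator uncertainty is deliberately not
propagated into the correlation — the comparison mirrors the standard
practice of correlating point estimates; an errors-in-variables treatment
is out of scope. Records with zero nest density have an undefined ratio
and are excluded with a log entry.

## What the synthetic-data generator emulates

`sim_config()` defaults describe the study conditions: 80 plots of
500 x 500 m (25 ha), half enrolled in the conservation program, three
seasons, five 500-m north-south transects per plot at 100-m spacing,
three survey rounds per season about 2.5 weeks apart, nest checks every
3 days, and two observers who swap primary/secondary roles between
visits. Two sparrow-like species differ in nest density (5.0 and 6.2
nests per 25 ha), stage-specific daily survival (0.88/0.92 and
0.79/0.83, bracketing seasonal means of roughly 0.90 and 0.81), nesting
period (19 and 15 days, hatch at `round(0.55 x period)`), and adult
density (18 and 12.5 birds per 25 ha). Nest detection is half-normal
with a 7.6-m scale inside 25-m strips, chosen so the mean detection
distance (~6 m) and the average detection probability (~0.38) match the
field protocol's narrow search corridor; adult per-observer detection is
0.48. Nests missed by the transect protocol are found opportunistically
with probability 0.25 (roughly equalizing transect and opportunistic
sample sizes); opportunistic nests carry no distance and are excluded
from density estimation but included in survival. Failure causes are
drawn as predation 0.78, abandonment 0.15, other 0.07. A log-normal
plot-quality multiplier (CV 0.5 by default, mean one) scales both nest
and adult density on a plot, inducing the between-plot covariation that
a density-dependence comparison needs; plot covariates (shrub cover
Beta(4, 16); GPP, LAI, precipitation and temperatures Normal) are drawn
identically across enrollment groups and — deliberately — independently
of density and survival, so covariate effects are null under the
default truth. Each generator stage draws from its own RNG stream derived
from the master seed, so adding one generator never perturbs another's
draws; the exact nest death day and the latent adult counts are kept in
the truth objects for oracle tests.

The generator does **not** emulate: renesting or multiple broods (nests
are independent; the real protocol could not verify renesting either),
territoriality or any spatial interaction, discovery-age bias (nests are
monitored from initiation, so simulated apparent success equals true
seasonal survival — field apparent success is biased high instead),
within-season density trends, observer heterogeneity beyond the
configured per-observer detection probabilities, or any dependence of
demographic rates on the simulated covariates. Passing recovery tests
therefore demonstrates that the estimators invert the sampling processes
they model — not that those processes capture every feature of field
data.

## Calibration scale

The recovery studies run at what a reviewer can reproduce on one CPU in
minutes, sized so Monte-Carlo error is small relative to the tolerances:
500 replicate strata of 20 plots for distance-sampling bias and coverage
(true density 6 nests per 25 ha, half-normal scale 8 m); 5,000 exposure
intervals across 50 plots for logistic-exposure coefficient recovery
(plot SD 0.4); 80 plots, mean 12 birds, detection 0.5, 3 visits and
3 chains x 10,000 iterations for the abundance model (credible-interval
coverage and Rhat); and a 500-plot end-to-end run with adult pairs at
exactly twice the nest density (plot-quality CV 1.0) for the
density-dependence comparison, expecting the recovered ratio near 2 and
correlation above 0.9.

## Known limitations

* Plot-level nest-density estimates reuse the pooled detection function;
  plots with fewer than two detections drop out, which slightly
  truncates the low end of the density distribution in the
  density-dependence join.
* The mean of per-plot pair:nest ratios is biased upward by noise in the
  denominator (Jensen's inequality); the ratio of mean densities is the
  more stable summary and both are reported.
* Non-adaptive Gauss–Hermite quadrature loses accuracy for plot SDs well
  above one on the logit scale; raise `nagq` in that regime.
* The MCMC sampler is plain R and sized for hundreds of plots; thousands
  of plots would warrant a compiled sampler.
* Seasonal survival assumes the fitted daily rate applies uniformly
  across the nesting period; stage-specific seasonal survival can be
  composed manually from stage-specific predictions.
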