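# nestdemog

Linked demographic estimators for songbirds breeding on fixed survey
plots, written for studies of shrub-steppe species (e.g. Brewer's sparrow
and vesper sparrow on 25-ha sagebrush plots, half of them enrolled in a
grazing-management conservation program). Monitoring programs usually
count adults and take that as a proxy for breeding activity; this package
estimates the three quantities that together tell a more complete story —
nest density, daily nest survival, and adult density — and tests whether
adult pair density actually tracks nest density.

## The estimators

**Nest density — line-transect distance sampling.** Perpendicular
distances `x` from transect lines to found nests are modelled with a
detection function `g(x)` (`g(0) = 1`), maximizing the conditional
likelihood with `f(x) = g(x) / ∫₀ʷ g(u) du` over a candidate set of key
functions (half-normal `exp(−x²/2σ²)`, hazard-rate `1 − exp(−(x/σ)^−b)`,
uniform) with cosine, simple-polynomial or Hermite-polynomial adjustment
series, or covariates on `log σ`. Candidates are ranked by AICc, and
density is estimated per stratum as

```
D̂ = n / (2 w L P̂a)        (converted to nests per 25 ha)
```

with encounter-rate variance across transects, delta-method variance of
`P̂a`, and log-normal confidence intervals with Satterthwaite degrees of
freedom. Strata need at least two detections (the "≥ 2 nests" rule).

**Nest survival — logistic exposure.** Visit histories become exposure
intervals; an interval of `t` days survives with probability `θᵗ` where
`logit(θ) = x'β + u_plot`, with stage (egg/nestling), year and covariate
effects and a plot random intercept integrated out by Gauss–Hermite
quadrature. Model suites are ranked by AICc; seasonal nest survival is
`θ̂^period` (19 days for Brewer's sparrow, 15 for vesper sparrow).

**Adult abundance — dependent double-observer (MDAM).** A primary
observer calls out birds; a secondary records only what the primary
missed. With latent plot abundance `N ~ Poisson(λ)`, the latent count is
marginalized exactly by Poisson thinning — `x₁ ~ Poisson(λp₁)`,
`x₂ ~ Poisson(λ(1−p₁)p₂)` — under a hierarchical model
`log λ = α_sp + β·SGI + γ_yr + ε_plot`,
`logit p = δ_obs + η_sp + ζ_yr`, with Normal(0, 1000) priors on
coefficients and a Uniform(0, 100) prior on the random-effect SD, fitted
by adaptive Metropolis-within-Gibbs MCMC (3 chains × 10,000 iterations,
1,000 burn-in by default) with split-Rhat and effective-sample-size
diagnostics.

**Density dependence.** Plot-level nest density and adult pair density
(λ/2 under a 1:1 sex ratio) are joined and compared with a Pearson
correlation test and pair:nest ratio summaries.

A synthetic-data generator (`simulate_demography()`) reproduces the whole
survey design — 80 plots of 25 ha, 3 seasons, 3–4 rounds, parallel
nest transects at 100-m spacing, ~3-day nest checks, rotating observer
pairs — with a truth table, so every estimator is testable by parameter
recovery.

## Worked example

```r
library(nestdemog)
cfg <- sim_config(n_plots = 40, years = 2016, seed = 11)
sim <- simulate_demography(cfg)

det  <- subset(sim$detections, species == "brewers_sparrow" & !opportunistic)
fits <- fit_detection_suite(det, w = 25, adjust_orders = list(cosine = list(2L)))
(tab <- rank_models(fits))
#> Model selection table (AICc), top model: hazard+cosine(2)
#>               model k  n loglik  AICc   dAICc    weight
#>    hazard+cosine(2) 3 98 -266.7 539.7  0.0000 4.221e-01
#>  halfnorm+cosine(2) 2 98 -268.0 540.1  0.4284 3.407e-01
#>            halfnorm 1 98 -269.4 540.8  1.1531 2.372e-01
#>             uniform 0 98 -315.4 630.9 91.2153 6.581e-21

eff <- merge(sim$effort, unique(sim$plots[c("plot_id", "year", "enrolled")]))
estimate_density(fits[[attr(tab, "top")]], merge(det, sim$plots), eff,
                 by = "enrolled")
#>   enrolled  n    L_m        Pa        D       se        cv      lcl      ucl
#> 1  non-SGI 48 150000 0.3137343 5.099857 1.425528 0.2795232 2.955307 8.800622
#> 2      SGI 50 150000 0.3137343 5.312351 1.468342 0.2764015 3.096732 9.113179
```

The generating truth is 5 nests per 25 ha in both enrollment groups; both
stratum estimates cover it. Survival from the same run:

```r
iv  <- build_exposure_intervals(subset(sim$visits, species == "brewers_sparrow"))
fit_dsr(iv, y ~ stage, random_plot = TRUE)
#> Logistic-exposure nest survival model: y ~ stage
#>   n = 651 intervals  logLik = -394.337  AICc = 794.711
#>                estimate         se
#> (Intercept)   1.9647494 0.08072171
#> stagenestling 0.3589483 0.23811479
#>   plot random-effect SD = 2.815e-05
```

`plogis(1.965) ≈ 0.88` recovers the egg-stage daily survival used by the
generator (0.88), with the nestling stage higher (truth 0.92), and the
plot heterogeneity correctly estimated near zero. The full pipeline —
simulate, fit all three estimators, compare densities — is one call:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "results")
```

or, from a shell, via the thin CLI at `inst/cli/nestdemog.R`
(`simulate`, `validate`, `fit-density`, `fit-survival`, `fit-abundance`,
`compare`, `run-all`).

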