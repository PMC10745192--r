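Package: nestdemog
Title: Songbird Demographic Estimators for Nest Density, Nest Survival and
    Adult Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators for three linked demographic parameters of
    shrub-steppe songbirds surveyed on fixed plots: nest density from
    line-transect distance sampling with maximum-likelihood detection
    functions and AICc model selection; daily nest survival from the
    logistic-exposure model with stage, year and covariate effects and a
    plot-level random effect; and adult abundance from a hierarchical
    multispecies dependent double-observer model fitted by Markov chain
    Monte Carlo. Includes a synthetic-data generator with a known truth
    table so every estimator is testable by parameter recovery, and a
    density-dependence comparison between adult pair density and nest
    density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
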