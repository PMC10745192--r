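test_that("marginal thinned likelihood matches hand-computed rates", {
  # x1 = 3, x2 = 1, lambda = 8, p1 = p2 = 0.5:
  # x1 ~ Pois(4), x2 ~ Pois(2)
  expect_equal(ddo_loglik(3, 1, 8, 0.5, 0.5),
               dpois(3, 4, log = TRUE) + dpois(1, 2, log = TRUE),
               tolerance = 1e-12)
  # empty-plot limit: lambda -> 0+ with zero counts
  expect_equal(ddo_loglik(0, 0, 1e-12, 0.5, 0.5), 0, tolerance = 1e-10)
  expect_error(ddo_loglik(-1, 0, 5, 0.5, 0.5), "non-negative")
})

test_that("marginalization equals brute-force latent-N augmentation", {
  set.seed(42)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 40)
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    x1 <- rpois(1, lam * p1); x2 <- rpois(1, lam * (1 - p1) * p2)
    expect_equal(ddo_loglik(x1, x2, lam, p1, p2),
                 nestdemog:::ddo_loglik_augmented(x1, x2, lam, p1, p2),
                 tolerance = 1e-10)
  }
})

test_that("moment detection estimator follows E(x2)/E(x1) = 1 - p", {
  expect_equal(moment_detection(data.frame(x1 = 80, x2 = 20)), 0.75)
  expect_equal(moment_detection(data.frame(x1 = c(30, 20), x2 = c(0, 0))), 1)
  expect_warning(p <- moment_detection(data.frame(x1 = 10, x2 = 10)),
                 "floored")
  expect_equal(p, 0.01)
})

test_that("increasing p1 decreases the abundance that explains fixed counts", {
  x1 <- 12; x2 <- 4
  lam_hat <- vapply(c(0.3, 0.5, 0.7), function(p1)
    stats::optimize(function(l) -ddo_loglik(x1, x2, l, p1, 0.5),
                    c(0.1, 200))$minimum, numeric(1))
  expect_true(all(diff(lam_hat) < 0))
})

test_that("the sampler is reproducible under a fixed seed", {
  cfg <- one_species_config(adult_density = 12, n_plots = 8, rounds = 2L,
                            seed = 5, observers = c(a = 0.5, b = 0.5))
  ddo <- simulate_ddo_counts(generate_plots(cfg), cfg)
  f1 <- fit_mdam(ddo, chains = 2, iterations = 200, burn_in = 100,
                 seed = 9)
  f2 <- fit_mdam(ddo, chains = 2, iterations = 200, burn_in = 100,
                 seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mdam(ddo, chains = 2, iterations = 200, burn_in = 100,
                 seed = 10)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("split-Rhat separates converged from divergent chains", {
  set.seed(8)
  good <- list(matrix(rnorm(4000), ncol = 2,
                      dimnames = list(NULL, c("a", "b"))),
               matrix(rnorm(4000), ncol = 2,
                      dimnames = list(NULL, c("a", "b"))))
  dg <- mdam_diagnostics(good)
  expect_true(all(dg$rhat > 0.99 & dg$rhat < 1.01))
  expect_false(any(dg$flag))

  shifted <- good
  shifted[[2]][, "a"] <- shifted[[2]][, "a"] + 5
  dg2 <- mdam_diagnostics(shifted)
  expect_gt(dg2$rhat[dg2$parameter == "a"], 1.5)
  expect_true(dg2$flag[dg2$parameter == "a"])

  const <- lapply(good, function(m) { m[, "b"] <- 1; m })
  dg3 <- mdam_diagnostics(const)
  expect_true(is.na(dg3$rhat[dg3$parameter == "b"]))
})

test_that("detection and abundance are recovered in a short calibration run", {
  cfg <- one_species_config(adult_density = 12, n_plots = 25, rounds = 3L,
                            seed = 31, plot_cv = 0,
                            observers = c(a = 0.5, b = 0.5))
  ddo <- simulate_ddo_counts(generate_plots(cfg), cfg)
  fit <- fit_mdam(ddo, chains = 2, iterations = 2500, burn_in = 500,
                  seed = 4)
  ds <- detection_summary(fit)
  expect_true(all(ds$lcl <= 0.5 & 0.5 <= ds$ucl))
  pd <- pair_density(fit)
  expect_true(all(pd$lcl <= pd$median & pd$median <= pd$ucl))
  # posterior mean abundance near truth on average over plots
  expect_lt(abs(mean(pd$lambda) - 12) / 12, 0.15)
  # pair density is lambda / 2
  expect_equal(pd$pairs, pd$lambda / 2, tolerance = 1e-12)
})

test_that("prior-only sampling recovers the Uniform(0, 100) sigma prior", {
  cfg <- one_species_config(adult_density = 10, n_plots = 2, rounds = 1L,
                            seed = 2, observers = c(a = 0.5, b = 0.5))
  ddo <- simulate_ddo_counts(generate_plots(cfg), cfg)
  fit <- fit_mdam(ddo, chains = 2, iterations = 6000, burn_in = 1000,
                  seed = 12, prior_only = TRUE)
  sig <- do.call(rbind, fit$draws)[, "sigma_plot"]
  expect_gt(length(sig), 9999)
  ks <- suppressWarnings(stats::ks.test(sig, "punif", 0, 100))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("posterior draws respect their support constraints", {
  cfg <- one_species_config(adult_density = 8, n_plots = 6, rounds = 2L,
                            seed = 3, observers = c(a = 0.5, b = 0.6))
  ddo <- simulate_ddo_counts(generate_plots(cfg), cfg)
  fit <- fit_mdam(ddo, chains = 2, iterations = 400, burn_in = 200,
                  seed = 6)
  d <- do.call(rbind, fit$draws)
  expect_true(all(d[, "sigma_plot"] >= 0 & d[, "sigma_plot"] <= 100))
  pd <- pair_density(fit)
  expect_true(all(pd$lambda > 0))
  ds <- detection_summary(fit)
  expect_true(all(ds$p > 0 & ds$p < 1))
})
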