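test_that("enrollment counts follow the configured fraction exactly", {
  cfg <- sim_config(n_plots = 80, prop_enrolled = 0.5, seed = 3)
  plots <- generate_plots(cfg)
  one_year <- plots[plots$year == plots$year[1], ]
  expect_equal(sum(one_year$enrolled == "SGI"), 40)
  expect_equal(sum(one_year$enrolled == "non-SGI"), 40)

  cfg0 <- sim_config(n_plots = 2, prop_enrolled = 0, seed = 3)
  expect_equal(sum(generate_plots(cfg0)$enrolled == "SGI"), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_plots = 1), "n_plots")
  expect_error(sim_config(prop_enrolled = 1.2), "prop_enrolled")
  expect_error(sim_config(scale = -1), "scale")
  sp_bad <- default_species()
  sp_bad$dsr_egg[1] <- 0
  expect_error(sim_config(species = sp_bad), "survival")
  expect_error(sim_config(n_transects = 7), "transect")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 11)
  s1 <- simulate_demography(cfg)
  s2 <- simulate_demography(cfg)
  for (tab in c("plots", "detections", "effort", "visits", "nests",
                "ddo_counts", "truth"))
    expect_identical(s1[[tab]], s2[[tab]])
  s3 <- simulate_demography(tiny_config(seed = 12))
  expect_false(identical(s1$detections, s3$detections))
})

test_that("truth table has exactly one row per plot-year-species", {
  cfg <- tiny_config()
  sim <- simulate_demography(cfg)
  key <- with(sim$truth, paste(plot_id, year, species))
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(sim$truth),
               cfg$n_plots * length(cfg$years) * nrow(cfg$species))
  # every downstream unit references a truth row
  det_key <- with(sim$detections, paste(plot_id, year, species))
  expect_true(all(det_key %in% key))
  ddo_key <- with(sim$ddo_counts, paste(plot_id, year, species))
  expect_true(all(ddo_key %in% key))
})

test_that("perfect detection over a full-coverage strip finds every nest", {
  cfg <- one_species_config(nest_density = 20, seed = 5, half_width = 50,
                            key = "uniform", p_opportunistic = 0)
  plots <- generate_plots(cfg)
  out <- simulate_nest_survey(plots, cfg)
  expect_gt(nrow(out$latent), 0)
  expect_true(all(out$latent$detected))
  expect_equal(nrow(out$detections), nrow(out$latent))
})

test_that("zero nest density yields no latent nests or detections", {
  cfg <- one_species_config(nest_density = 0, seed = 5)
  out <- simulate_nest_survey(generate_plots(cfg), cfg)
  expect_equal(nrow(out$latent), 0)
  expect_equal(nrow(out$detections), 0)
})

test_that("in-strip detection fraction matches the integral of g(x)", {
  # half-normal sigma = 6, w = 25: P(detect | in strip) = int g / w
  sigma <- 6; w <- 25
  cfg <- one_species_config(nest_density = 300, n_plots = 40, seed = 8,
                            scale = sigma, half_width = w,
                            p_opportunistic = 0)
  out <- simulate_nest_survey(generate_plots(cfg), cfg)
  strip <- out$latent[out$latent$in_strip, ]
  expect_gt(nrow(strip), 5000)
  p_obs <- mean(strip$detected)
  p_true <- stats::integrate(function(x) exp(-x^2 / (2 * sigma^2)),
                             0, w)$value / w
  mc_se <- sqrt(p_true * (1 - p_true) / nrow(strip))
  expect_lt(abs(p_obs - p_true), 3 * mc_se)
})

test_that("nest fates follow the configured daily survival", {
  # DSR = 1: every nest fledges
  cfg1 <- one_species_config(nest_density = 30, dsr = 1, seed = 2,
                             p_opportunistic = 1)
  sim1 <- simulate_demography(cfg1)
  expect_true(all(sim1$nests$fate == "fledged"))

  # DSR = 0.9 over 19 days: fledging fraction ~ 0.9^19
  cfg2 <- one_species_config(nest_density = 90, dsr = 0.9, period = 19L,
                             n_plots = 80L, rounds = 3L, seed = 9,
                             p_opportunistic = 1)
  sim2 <- simulate_demography(cfg2)
  n <- nrow(sim2$nests)
  expect_gt(n, 15000)
  p_true <- 0.9^19
  frac <- mean(sim2$nests$fate == "fledged")
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("visit schedules respect the interval and period arithmetic", {
  cfg <- one_species_config(nest_density = 20, dsr = 0.97, period = 15L,
                            seed = 4)
  expect_equal(cfg$visit_interval, 3L)
  sim <- simulate_demography(cfg)
  nvis <- table(sim$visits$nest_id)
  fledged <- sim$nests$nest_id[sim$nests$fate == "fledged"]
  expect_true(all(nvis[fledged] >= 5))
  # failure observed at the first visit after the true death day
  failed <- sim$nests[sim$nests$fate == "failed", ]
  lastv <- vapply(failed$nest_id, function(id) {
    v <- sim$visits[sim$visits$nest_id == id, ]
    max(v$day) - min(v$day)
  }, numeric(1))
  expect_true(all(lastv >= failed$death_day))
  expect_true(all(lastv - failed$death_day < cfg$visit_interval))
})

test_that("double-observer tallies obey the thinning structure", {
  # p1 = 1: the secondary observer never sees anything new
  cfg1 <- one_species_config(adult_density = 15, seed = 6,
                             observers = c(a = 1, b = 0.5))
  ddo1 <- simulate_ddo_counts(generate_plots(cfg1), cfg1)
  expect_true(all(ddo1$x2[ddo1$observer_primary == "a"] == 0))

  # zero density: all tallies zero
  cfg0 <- one_species_config(adult_density = 0, seed = 6)
  ddo0 <- simulate_ddo_counts(generate_plots(cfg0), cfg0)
  expect_true(all(ddo0$x1 == 0) && all(ddo0$x2 == 0))
})

test_that("thinning expectations match lambda = 10, p1 = p2 = 0.5", {
  # ~51,000 plot-visit cells
  cfg <- one_species_config(adult_density = 10, n_plots = 17000L,
                            rounds = 3L, seed = 13,
                            observers = c(a = 0.5, b = 0.5))
  ddo <- simulate_ddo_counts(generate_plots(cfg), cfg)
  n <- nrow(ddo)
  expect_gte(n, 50000)
  # x1 ~ Poisson(5), x2 ~ Poisson(2.5)
  expect_lt(abs(mean(ddo$x1) - 5), 3 * sqrt(5 / n))
  expect_lt(abs(mean(ddo$x2) - 2.5), 3 * sqrt(2.5 / n))
  # marginal variances also Poisson
  expect_lt(abs(var(ddo$x1) / 5 - 1), 0.05)
  expect_lt(abs(var(ddo$x2) / 2.5 - 1), 0.05)
})
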