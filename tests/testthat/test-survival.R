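test_that("exposure intervals are built from consecutive visits", {
  v <- data.frame(nest_id = "N1", plot_id = "P1", species = "sp",
                  year = 2016L, day = c(0, 3, 6),
                  stage = c("egg", "egg", "egg"),
                  status = c("active", "active", "failed"))
  iv <- build_exposure_intervals(v)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$t, c(3, 3))
  expect_equal(iv$y, c(1L, 0L))
  expect_equal(iv$stage, c("egg", "egg"))

  # success terminal: one interval ending fledged
  v2 <- data.frame(nest_id = "N2", plot_id = "P1", species = "sp",
                   year = 2016L, day = c(0, 4), stage = "egg",
                   status = c("active", "fledged"))
  iv2 <- build_exposure_intervals(v2)
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$t, 4)
  expect_equal(iv2$y, 1L)

  # midpoint convention halves failed-interval exposure only
  ivm <- build_exposure_intervals(v, exposure = "midpoint")
  expect_equal(ivm$t, c(3, 1.5))
})

test_that("degenerate histories are excluded or rejected", {
  v <- data.frame(nest_id = c("N1", "N2", "N2"), plot_id = "P1",
                  species = "sp", year = 2016L, day = c(0, 0, 3),
                  stage = "egg", status = c("active", "active", "failed"))
  expect_warning(iv <- build_exposure_intervals(v), "single-visit")
  expect_equal(unique(iv$nest_id), "N2")

  bad <- data.frame(nest_id = "N3", plot_id = "P1", species = "sp",
                    year = 2016L, day = c(3, 0), stage = "egg",
                    status = c("active", "failed"))
  expect_error(build_exposure_intervals(bad), "N3")
})

test_that("interval log-likelihood matches its closed forms", {
  expect_equal(logexp_loglik(1, 3, 0.9), log(0.729), tolerance = 1e-12)
  expect_equal(logexp_loglik(0, 2, 0.5), log(0.75), tolerance = 1e-12)
  expect_identical(logexp_loglik(1, 7, 1), 0)
  # boundary guarded, not -Inf
  expect_true(is.finite(logexp_loglik(0, 2, 1)))
})

test_that("intercept-only fit on unit exposures is the binomial MLE", {
  iv <- data.frame(plot_id = "P1", t = rep(1, 10), y = c(rep(1L, 9), 0L),
                   stage = "egg")
  f <- fit_dsr(iv, y ~ 1, random_plot = FALSE)
  expect_equal(stats::plogis(unname(coef(f)[1])), 0.9, tolerance = 1e-6)
})

test_that("with t = 1 the model reduces to ordinary logistic regression", {
  set.seed(12)
  n <- 400
  z <- rnorm(n)
  theta <- stats::plogis(1 + 0.7 * z)
  iv <- data.frame(plot_id = "P1", t = rep(1, n),
                   y = as.integer(runif(n) < theta), z = z)
  f <- fit_dsr(iv, y ~ z, random_plot = FALSE)
  g <- stats::glm(y ~ z, family = binomial(), data = iv)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-8)
})

test_that("mixed-exposure MLE matches a one-dimensional grid-search oracle", {
  set.seed(23)
  n <- 300
  t_i <- sample(1:4, n, replace = TRUE)
  theta_true <- 0.88
  y <- as.integer(runif(n) < theta_true^t_i)
  iv <- data.frame(plot_id = "P1", t = t_i, y = y)
  f <- fit_dsr(iv, y ~ 1, random_plot = FALSE)
  grid <- seq(0.70, 0.99, by = 1e-5)
  ll <- vapply(grid, function(th) logexp_loglik(y, t_i, rep(th, n)),
               numeric(1))
  oracle <- grid[which.max(ll)]
  expect_equal(stats::plogis(unname(coef(f)[1])), oracle, tolerance = 1e-4)
})

test_that("stage and plot-heterogeneity parameters are recovered", {
  iv <- simulate_intervals(4000, beta0 = 1.5, beta_stage = 0.8,
                           sigma_plot = 0.4, n_plots = 40, seed = 61)
  f <- fit_dsr(iv, y ~ stage, random_plot = TRUE)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(coef(f)[["(Intercept)"]] - 1.5), 3 * se[1])
  expect_lt(abs(coef(f)[["stagenestling"]] - 0.8), 3 * se[2])
  expect_gt(f$sigma_plot, 0.05)
  expect_lt(f$sigma_plot, 1.2)
})

test_that("random-effect fit agrees with an independent mixed-model fit", {
  # at t = 1 the marginal likelihood is a binomial GLMM; lme4 with
  # adaptive quadrature is the independent reference
  iv <- simulate_intervals(3000, beta0 = 1.2, beta_stage = 0.6,
                           sigma_plot = 0.5, n_plots = 30, t_range = 1,
                           seed = 55)
  f <- fit_dsr(iv, y ~ stage, random_plot = TRUE, nagq = 15)
  g <- lme4::glmer(y ~ stage + (1 | plot_id), data = iv,
                   family = stats::binomial(), nAGQ = 15L)
  expect_equal(unname(coef(f)), unname(lme4::fixef(g)), tolerance = 1e-3)
  sig_ref <- sqrt(unname(lme4::VarCorr(g)$plot_id[1, 1]))
  expect_equal(f$sigma_plot, sig_ref, tolerance = 1e-2)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
})

test_that("zero plot heterogeneity is estimated near zero", {
  iv <- simulate_intervals(6000, beta0 = 1.8, sigma_plot = 0,
                           n_plots = 40, seed = 77)
  f <- fit_dsr(iv, y ~ 1, random_plot = TRUE)
  expect_lt(f$sigma_plot, 0.05)
})

test_that("seasonal survival is the period power of the daily rate", {
  expect_equal(seasonal_survival(0.81, 15), 0.81^15, tolerance = 1e-12)
  expect_equal(seasonal_survival(1, 19), 1)
  expect_equal(seasonal_survival(0.90, 19), 0.1350852, tolerance = 1e-6)
  # monotone in dsr, antitone in period
  d <- seq(0.5, 0.99, by = 0.01)
  expect_true(all(diff(seasonal_survival(d, 15)) > 0))
  expect_true(all(diff(seasonal_survival(0.9, 10:25)) < 0))
})

test_that("apparent success counts fledged nests over known fates", {
  tab <- make_fate_table(66, 46)
  res <- apparent_success(tab)
  expect_equal(res$fledged, 66)
  expect_equal(res$total, 112)
  expect_equal(res$fraction, 66 / 112)
  expect_equal(apparent_success(make_fate_table(0, 5))$fraction, 0)
  # censored histories excluded by default, countable on request
  tab$fate[1] <- "active"
  expect_equal(apparent_success(tab)$total, 111)
  expect_equal(apparent_success(tab, censored = "failed")$total, 112)
})

test_that("failure causes are tabulated over failed nests only", {
  tab <- make_fate_table(10, 4, causes = c("predation", "predation",
                                           "abandonment", NA))
  fc <- failure_causes(tab)
  expect_equal(sum(fc$fraction), 1)
  expect_equal(fc$count[fc$cause == "predation"], 2L)
  expect_equal(fc$count[fc$cause == "unknown"], 1L)
  one <- failure_causes(make_fate_table(3, 2, causes = rep("predation", 2)))
  expect_equal(one$fraction, 1)
})

test_that("DSR predictions always lie in (0, 1)", {
  iv <- simulate_intervals(800, beta0 = 2, beta_stage = -0.5,
                           sigma_plot = 0.3, seed = 19)
  f <- fit_dsr(iv, y ~ stage, random_plot = TRUE)
  pr <- predict(f, iv)
  expect_true(all(pr > 0 & pr < 1))
  expect_true(all(seasonal_survival(pr, 19) >= 0 &
                  seasonal_survival(pr, 19) <= 1))
})
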