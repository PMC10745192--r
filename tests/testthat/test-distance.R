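test_that("truncation filters distances and flags degenerate input", {
  out <- truncate_distances(c(1, 5, 30), w = 25)
  expect_equal(as.numeric(out), c(1, 5))
  expect_equal(attr(out, "w"), 25)
  x <- c(2, 9, 14)
  expect_length(truncate_distances(x, w = max(x)), 3L)
  expect_error(truncate_distances(c(30, 40), w = 25), "all detections")
})

test_that("uniform key with no adjustment has its closed-form likelihood", {
  set.seed(1)
  x <- runif(5, 0, 10)
  m <- fit_detection_function(x, key = "uniform", w = 10)
  expect_equal(m$loglik, -5 * log(10), tolerance = 1e-12)
  expect_equal(m$Pa, 1)
  expect_equal(m$k, 0L)
})

test_that("numeric half-normal MLE matches the closed form sqrt(sum(x^2)/n)", {
  m <- fit_detection_function(c(1, 2, 3), key = "halfnorm", w = 150)
  expect_equal(m$sigma, sqrt(14 / 3), tolerance = 1e-6)
  set.seed(7)
  x <- abs(rnorm(200, 0, 5))
  m2 <- fit_detection_function(x, key = "halfnorm", w = 60 * 5)
  expect_equal(m2$sigma, sqrt(mean(x^2)), tolerance = 1e-6)
})

test_that("hazard-rate integral matches an adaptive-quadrature oracle", {
  mine <- nestdemog:::integrate_g("hazard", sigma = 5, shape = 2,
                                  adjustment = "none", orders = integer(0),
                                  acoef = numeric(0), w = 25)
  oracle <- pracma::quadgk(function(x)
    ifelse(x > 0, 1 - exp(-(x / 5)^(-2)), 1), 0, 25, tol = 1e-12)
  expect_lt(abs(mine - oracle) / oracle, 1e-6)
})

test_that("fitted detection functions satisfy g(0)=1 and integrate to one", {
  set.seed(21)
  x <- abs(rnorm(150, 0, 7)); x <- x[x <= 25]
  specs <- list(
    list(key = "halfnorm"),
    list(key = "hazard"),
    list(key = "halfnorm", adjustment = "cosine", orders = 2L),
    list(key = "uniform", adjustment = "cosine", orders = 2L),
    list(key = "halfnorm", adjustment = "hermite", orders = 4L),
    list(key = "halfnorm", adjustment = "poly", orders = 4L))
  for (sp in specs) {
    m <- do.call(fit_detection_function,
                 c(list(detections = x, w = 25), sp))
    expect_equal(predict(m, 0), 1, tolerance = 1e-10)
    expect_gt(m$Pa, 0)
    expect_lte(m$Pa, 1 + 1e-9)
    # f(x) = g(x)/mu integrates to 1 over [0, w]
    mu <- nestdemog:::integrate_g(m$key, m$sigma, m$shape, m$adjustment,
                                  m$orders, m$acoef, m$w)
    f_int <- stats::integrate(function(z) predict(m, z) / mu, 0, m$w,
                              rel.tol = 1e-12)$value
    expect_lt(abs(f_int - 1), 1e-8)
  }
})

test_that("estimates are scale-equivariant", {
  set.seed(9)
  x <- abs(rnorm(120, 0, 6)); x <- x[x <= 20]
  c_fac <- 3.7
  m1 <- fit_detection_function(x, key = "halfnorm", w = 20)
  m2 <- fit_detection_function(x * c_fac, key = "halfnorm", w = 20 * c_fac)
  expect_equal(m2$sigma, m1$sigma * c_fac, tolerance = 1e-4)
  expect_equal(m2$Pa, m1$Pa, tolerance = 1e-6)
  # log-likelihood shifts by -n log(c), preserving model ranking
  expect_equal(m2$loglik, m1$loglik - length(x) * log(c_fac),
               tolerance = 1e-6)
  h1 <- fit_detection_function(x, key = "hazard", w = 20)
  h2 <- fit_detection_function(x * c_fac, key = "hazard", w = 20 * c_fac)
  expect_equal(h2$loglik, h1$loglik - length(x) * log(c_fac),
               tolerance = 1e-3)
  expect_identical(m1$loglik > h1$loglik, m2$loglik > h2$loglik)
})

test_that("covariates on log-sigma are recovered and cannot mix with adjustments", {
  set.seed(31)
  n <- 400
  z <- rnorm(n)
  sig <- exp(log(6) + 0.4 * z)
  x <- abs(rnorm(n, 0, sig))
  keep <- x <= 30
  df <- data.frame(distance_m = x[keep], z = z[keep])
  m <- fit_detection_function(df, key = "halfnorm", formula = ~z, w = 30)
  expect_equal(unname(m$beta[1]), log(6), tolerance = 0.15)
  expect_equal(unname(m$beta[2]), 0.4, tolerance = 0.15)
  expect_error(
    fit_detection_function(df, key = "halfnorm", formula = ~z,
                           adjustment = "cosine", orders = 2L, w = 30),
    "cannot be combined")
})

test_that("AICc selects the generating key in a large-sample simulation", {
  set.seed(55)
  x <- abs(rnorm(600, 0, 6)); x <- x[x <= 25]
  fits <- fit_detection_suite(x, w = 25,
                              adjust_orders = list(cosine = list(2L)))
  tab <- rank_models(fits)
  expect_match(attr(tab, "top"), "^halfnorm")
})

test_that("density arithmetic: n/(2wL Pa) in nests per 25 ha", {
  set.seed(3)
  det <- data.frame(distance_m = runif(10, 0, 25), plot_id = "P001",
                    year = 2016L, transect_id = paste0("T", rep(1:2, 5)),
                    stratum = "s1")
  eff <- data.frame(plot_id = "P001", year = 2016L,
                    transect_id = c("T1", "T2"), length_m = 1250,
                    rounds = 1L, stratum = "s1")
  m <- fit_detection_function(det$distance_m, key = "uniform", w = 25)
  est <- estimate_density(m, det, eff, by = "stratum")
  # Pa = 1, n = 10, w = 25 m, L = 2500 m -> 20 nests per 25 ha
  expect_equal(est$Pa, 1)
  expect_equal(est$D, 20, tolerance = 1e-12)
  expect_true(est$lcl <= est$D && est$D <= est$ucl)
  # halving Pa doubles the density estimate
  m2 <- m; m2$Pa <- 0.5
  est2 <- estimate_density(m2, det, eff, by = "stratum")
  expect_equal(est2$D, 40, tolerance = 1e-12)
})

test_that("single-transect strata fall back to Poisson variance with a warning", {
  set.seed(4)
  det <- data.frame(distance_m = runif(6, 0, 25), plot_id = "P001",
                    year = 2016L, transect_id = "T1", stratum = "s1")
  eff <- data.frame(plot_id = "P001", year = 2016L, transect_id = "T1",
                    length_m = 2500, rounds = 1L, stratum = "s1")
  m <- fit_detection_function(det$distance_m, key = "uniform", w = 25)
  expect_warning(est <- estimate_density(m, det, eff, by = "stratum"),
                 "single transect")
  expect_equal(est$cv, sqrt(1 / 6), tolerance = 1e-12)
})

test_that("strata below the two-nest rule are dropped with a warning", {
  set.seed(5)
  det <- data.frame(distance_m = c(runif(5, 0, 25), 3),
                    plot_id = c(rep("P001", 5), "P002"),
                    year = 2016L,
                    transect_id = "T1")
  eff <- expand.grid(plot_id = c("P001", "P002"), year = 2016L,
                     transect_id = c("T1", "T2"),
                     stringsAsFactors = FALSE)
  eff$length_m <- 1000; eff$rounds <- 1L
  m <- fit_detection_function(det$distance_m, key = "uniform", w = 25)
  expect_warning(est <- estimate_density(m, det, eff, by = "plot_id"),
                 "dropped")
  expect_equal(nrow(est), 1L)
  expect_equal(est$plot_id, "P001")
})
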