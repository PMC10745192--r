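# Line-transect distance sampling: detection-function likelihoods, AICc
# model selection, and stratum/plot density estimation.

KEY_FUNS <- c("halfnorm", "hazard", "uniform")
ADJ_FUNS <- c("none", "cosine", "poly", "hermite")

# Key detection function k(x); k(0) = 1 for all three families.
key_fn <- function(x, key, sigma = NULL, shape = NULL) {
  switch(key,
    halfnorm = exp(-x^2 / (2 * sigma^2)),
    hazard = {
      g <- numeric(length(x))
      pos <- x > 0
      g[!pos] <- 1
      g[pos] <- 1 - exp(-exp(-shape * log(x[pos] / sigma)))
      g
    },
    uniform = rep(1, length(x)),
    stop("unknown key function: ", key)
  )
}

# Probabilists' Hermite polynomials used in adjustment series.
hermite_poly <- function(z, order) {
  switch(as.character(order),
    "4" = z^4 - 6 * z^2 + 3,
    "6" = z^6 - 15 * z^4 + 45 * z^2 - 15,
    {
      # general recurrence He_{n+1} = z He_n - n He_{n-1}
      h0 <- rep(1, length(z)); h1 <- z
      if (order == 0) return(h0)
      for (n in seq_len(order - 1)) {
        h2 <- z * h1 - n * h0
        h0 <- h1; h1 <- h2
      }
      h1
    })
}

# Adjustment-series terms evaluated at distance x; `ref` is the scaling
# distance (sigma for scaled keys, w for the uniform key).
adj_terms <- function(x, adjustment, orders, ref, w) {
  if (adjustment == "none" || length(orders) == 0L)
    return(matrix(0, nrow = length(x), ncol = 0))
  xs <- switch(adjustment,
    cosine = x / w,          # cosine series is scaled by truncation distance
    poly = x / w,
    hermite = x / ref)
  sapply(orders, function(j) {
    switch(adjustment,
      cosine = cos(j * pi * xs),
      poly = xs^j,
      hermite = hermite_poly(xs, j))
  }, simplify = "array") |> matrix(nrow = length(x))
}

# Full detection function g(x) with g(0) = 1 enforced by rescaling.
eval_g <- function(x, key, sigma, shape, adjustment, orders, acoef, w) {
  k <- key_fn(x, key, sigma, shape)
  if (adjustment == "none" || length(acoef) == 0L) return(k)
  ref <- if (key == "uniform") w else sigma
  series <- 1 + adj_terms(x, adjustment, orders, ref, w) %*% acoef
  series0 <- 1 + sum(adj_terms(0, adjustment, orders, ref, w) * acoef)
  as.numeric(k * series / series0)
}

# Integral of g over [0, w] (the effective strip half-width mu).
integrate_g <- function(key, sigma, shape, adjustment, orders, acoef, w) {
  if (key == "halfnorm" && adjustment == "none")
    return(sigma * sqrt(2 * pi) * (stats::pnorm(w / sigma) - 0.5))
  if (key == "uniform" && adjustment == "none") return(w)
  f <- function(x) eval_g(x, key, sigma, shape, adjustment, orders, acoef, w)
  out <- tryCatch(
    stats::integrate(f, 0, w, rel.tol = 1e-10, subdivisions = 500L)$value,
    error = function(e) pracma::integral(f, 0, w))
  out
}

unpack_par <- function(par, key, adjustment, n_orders, n_beta) {
  i <- 0L
  beta <- NULL; sigma <- NULL; shape <- NULL
  if (key != "uniform") {
    beta <- par[seq_len(n_beta)]
    i <- n_beta
  }
  if (key == "hazard") {
    shape <- 1 + exp(par[i + 1L])
    i <- i + 1L
  }
  acoef <- if (adjustment != "none") par[i + seq_len(n_orders)] else numeric(0)
  list(beta = beta, shape = shape, acoef = acoef)
}

#' Truncate perpendicular distances
#'
#' Removes detections beyond the truncation distance `w` and records `w`
#' for likelihood normalization.
#'
#' @param detections a data.frame with a `distance_m` column, or a numeric
#'   vector of perpendicular distances in meters.
#' @param w truncation distance (m), strictly positive.
#' @return the retained detections with attribute `w` set.
#' @export
truncate_distances <- function(detections, w) {
  stopifnot(is.numeric(w), length(w) == 1L, w > 0)
  d <- if (is.data.frame(detections)) detections$distance_m else detections
  keep <- !is.na(d) & d <= w
  if (!any(keep))
    stop("all detections removed by truncation at w = ", w)
  out <- if (is.data.frame(detections)) detections[keep, , drop = FALSE]
         else detections[keep]
  attr(out, "w") <- w
  out
}

#' Fit a line-transect detection function by maximum likelihood
#'
#' Maximizes the conditional likelihood \eqn{\prod_i f(x_i)} with
#' \eqn{f(x) = g(x) / \int_0^w g(u)\,du} over perpendicular distances
#' \eqn{x_i \in [0, w]}. Supported key functions: half-normal
#' \eqn{g(x) = \exp(-x^2/2\sigma^2)}, hazard-rate
#' \eqn{g(x) = 1 - \exp(-(x/\sigma)^{-b})} and uniform \eqn{g(x) = 1}.
#' Adjustment series (cosine, simple polynomial, Hermite polynomial)
#' multiply the key and the result is rescaled so that \eqn{g(0) = 1}.
#' Covariates act on \eqn{\log\sigma}; adjustments and covariates are never
#' combined in one model (the conventional MCDS restriction).
#'
#' @param detections numeric vector of distances (m) or a data.frame with a
#'   `distance_m` column (and covariate columns when `formula` is used).
#' @param key one of `"halfnorm"`, `"hazard"`, `"uniform"`.
#' @param adjustment one of `"none"`, `"cosine"`, `"poly"`, `"hermite"`.
#' @param orders integer vector of adjustment orders (e.g. `2:3` for cosine,
#'   `c(4, 6)` for polynomials).
#' @param formula covariate model for `log(sigma)`, e.g. `~ shrub_cover`;
#'   the default `~ 1` fits a common scale.
#' @param w truncation distance (m); defaults to the largest observed
#'   distance.
#' @return an object of class `detfun`: fitted parameters (`sigma`, `shape`,
#'   adjustment coefficients, covariate coefficients), `loglik`, `k`, `n`,
#'   `w`, average detection probability `Pa` (Horvitz-Thompson averaged
#'   under covariate models), per-detection probabilities `p_i`,
#'   variance-covariance matrix and a monotonicity flag.
#' @examples
#' x <- c(1, 2, 3)
#' m <- fit_detection_function(x, key = "halfnorm", w = 100)
#' m$sigma  # ~ sqrt(14/3), the closed-form untruncated MLE
#' @export
fit_detection_function <- function(detections,
                                   key = c("halfnorm", "hazard", "uniform"),
                                   adjustment = c("none", "cosine", "poly",
                                                  "hermite"),
                                   orders = NULL,
                                   formula = ~1,
                                   w = NULL) {
  key <- match.arg(key)
  adjustment <- match.arg(adjustment)
  df <- if (is.data.frame(detections)) detections
        else data.frame(distance_m = detections)
  x <- df$distance_m
  if (is.null(w)) w <- if (!is.null(attr(detections, "w"))) attr(detections, "w")
                       else max(x)
  if (any(x < 0 | x > w))
    stop("distances must lie in [0, w]; truncate first (w = ", w, ")")
  n <- length(x)
  if (n < 2L) stop("detection function requires >= 2 detections, got ", n)

  X <- stats::model.matrix(formula, df)
  n_beta <- ncol(X)
  has_cov <- n_beta > 1L
  if (has_cov && adjustment != "none")
    stop("adjustment terms and covariates cannot be combined in one model")
  if (has_cov && key == "uniform")
    stop("the uniform key has no scale parameter for covariates")
  if (adjustment != "none" && is.null(orders))
    orders <- switch(adjustment, cosine = 2L, poly = 4L, hermite = 4L)
  if (adjustment == "none") orders <- integer(0)
  n_orders <- length(orders)

  negll <- function(par) {
    up <- unpack_par(par, key, adjustment, n_orders, n_beta)
    if (key == "uniform") {
      sig_i <- rep(NA_real_, n); usig <- NA_real_
      gx <- eval_g(x, key, NA, NA, adjustment, orders, up$acoef, w)
      if (any(!is.finite(gx)) || any(gx <= 0)) return(1e8)
      mu <- integrate_g(key, NA, NA, adjustment, orders, up$acoef, w)
      if (!is.finite(mu) || mu <= 0) return(1e8)
      return(-(sum(log(gx)) - n * log(mu)))
    }
    lsig <- as.numeric(X %*% up$beta)
    if (any(!is.finite(lsig)) || any(abs(lsig) > 30)) return(1e8)
    sig_i <- exp(lsig)
    ll <- 0
    for (s in unique(sig_i)) {
      idx <- sig_i == s
      gx <- eval_g(x[idx], key, s, up$shape, adjustment, orders, up$acoef, w)
      if (any(!is.finite(gx)) || any(gx <= 0)) return(1e8)
      mu <- integrate_g(key, s, up$shape, adjustment, orders, up$acoef, w)
      if (!is.finite(mu) || mu <= 0) return(1e8)
      ll <- ll + sum(log(gx)) - sum(idx) * log(mu)
    }
    -ll
  }

  # parameter layout: [log-sigma betas][log(b-1) if hazard][adj coefs]
  sd0 <- max(sqrt(mean(x^2)), 1e-3)
  n_par <- (if (key != "uniform") n_beta else 0L) +
    (key == "hazard") + n_orders
  starts <- list()
  for (mult in c(1, 0.5, 2)) {
    p0 <- numeric(n_par)
    if (key != "uniform") p0[1L] <- log(sd0 * mult)
    starts[[length(starts) + 1L]] <- p0
  }
  if (n_par == 0L) {
    # uniform key without adjustments: no free parameters
    ll <- -n * log(w)
    fit <- list(par = numeric(0), objective = -ll, convergence = 0L)
  } else {
    fits <- lapply(starts, function(p0)
      tryCatch(stats::nlminb(p0, negll,
                             control = list(rel.tol = 1e-12, iter.max = 500)),
               error = function(e) list(objective = Inf, convergence = 1L)))
    fits <- Filter(function(f) is.finite(f$objective), fits)
    if (length(fits) == 0L)
      stop("detection-function fit failed to converge (key = ", key,
           ", adjustment = ", adjustment, ")")
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  }
  up <- unpack_par(fit$par, key, adjustment, n_orders, n_beta)
  sigma <- if (key != "uniform") exp(up$beta[1L]) else NA_real_

  # per-detection sigma and detection probability p_i = mu_i / w
  if (key == "uniform") {
    sig_i <- rep(NA_real_, n)
    mu_i <- rep(integrate_g(key, NA, NA, adjustment, orders, up$acoef, w), n)
  } else {
    sig_i <- as.numeric(exp(X %*% up$beta))
    mus <- vapply(unique(sig_i), function(s)
      integrate_g(key, s, up$shape, adjustment, orders, up$acoef, w),
      numeric(1))
    mu_i <- mus[match(sig_i, unique(sig_i))]
  }
  p_i <- mu_i / w
  Pa <- if (has_cov) n / sum(1 / p_i) else p_i[1L]

  # weak monotonicity / positivity check of the adjusted g on a grid
  grid <- seq(0, w, length.out = 200L)
  gg <- if (key == "uniform")
    eval_g(grid, key, NA, NA, adjustment, orders, up$acoef, w)
  else eval_g(grid, key, sigma, up$shape, adjustment, orders, up$acoef, w)
  monotone_ok <- all(gg >= -1e-9) && all(diff(gg) <= 1e-6) &&
    all(gg <= 1 + 1e-6)

  vcov <- matrix(NA_real_, n_par, n_par)
  if (n_par > 0L) {
    H <- tryCatch(stats::optimHess(fit$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) vcov <- V
    }
  }

  out <- list(key = key, adjustment = adjustment, orders = orders,
              formula = formula, par = fit$par, beta = up$beta,
              sigma = sigma, shape = up$shape, acoef = up$acoef,
              loglik = -fit$objective, k = n_par, n = n, w = w,
              Pa = Pa, p_i = p_i, sigma_i = sig_i, vcov = vcov,
              monotone_ok = monotone_ok,
              converged = identical(fit$convergence, 0L) || n_par == 0L,
              data = df)
  class(out) <- "detfun"
  out
}

#' @export
print.detfun <- function(x, ...) {
  adj <- if (x$adjustment == "none") "no adjustment"
         else paste0(x$adjustment, "(", paste(x$orders, collapse = ","), ")")
  cat("Detection function:", x$key, "key,", adj, "\n")
  cat("  n =", x$n, " w =", format(x$w), "m  logLik =",
      format(x$loglik, digits = 6), " k =", x$k, "\n")
  if (!is.na(x$sigma)) cat("  sigma =", format(x$sigma, digits = 5), "m\n")
  if (!is.null(x$shape)) cat("  shape b =", format(x$shape, digits = 5), "\n")
  cat("  average detection probability Pa =", format(x$Pa, digits = 4), "\n")
  if (!x$monotone_ok)
    cat("  NOTE: adjusted g(x) violates monotonicity/positivity\n")
  invisible(x)
}

#' @export
logLik.detfun <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Predict detection probability g(x) from a fitted detection function
#'
#' @param object a `detfun` fit.
#' @param distance distances (m) at which to evaluate g.
#' @param sigma optional scale override (for covariate models, the
#'   per-observation scale); defaults to the fitted baseline scale.
#' @param ... unused.
#' @return numeric vector of detection probabilities.
#' @export
predict.detfun <- function(object, distance, sigma = NULL, ...) {
  s <- if (is.null(sigma)) object$sigma else sigma
  eval_g(distance, object$key, s, object$shape, object$adjustment,
         object$orders, object$acoef, object$w)
}

#' Fit the default candidate set of detection functions
#'
#' Builds the conventional candidate suite: each key function alone, each
#' key crossed with cosine (orders 2, then 2:3), simple-polynomial (4, then
#' 4 and 6) and Hermite (4, then 4 and 6) adjustments, plus single-covariate
#' scale models for the half-normal and hazard-rate keys. Candidates that
#' fail to converge are dropped with a warning.
#'
#' @param detections as in [fit_detection_function()].
#' @param w truncation distance.
#' @param covariates character vector of covariate column names to try one
#'   at a time on log-sigma (default none).
#' @param keys,adjust_orders control the grid; defaults follow standard
#'   practice.
#' @return named list of `detfun` fits.
#' @export
fit_detection_suite <- function(detections, w = NULL,
                                covariates = character(0),
                                keys = c("halfnorm", "hazard", "uniform"),
                                adjust_orders = list(
                                  cosine = list(2L, 2:3),
                                  poly = list(4L, c(4L, 6L)),
                                  hermite = list(4L, c(4L, 6L)))) {
  fits <- list()
  tryfit <- function(name, ...) {
    f <- tryCatch(fit_detection_function(detections, w = w, ...),
                  error = function(e) {
                    demog_log("WARN", "candidate ", name, " dropped: ",
                              conditionMessage(e))
                    NULL
                  })
    if (!is.null(f) && f$converged) fits[[name]] <<- f
  }
  for (key in keys) {
    tryfit(paste0(key), key = key)
    for (adj in names(adjust_orders))
      for (ord in adjust_orders[[adj]])
        tryfit(paste0(key, "+", adj, "(", paste(ord, collapse = ","), ")"),
               key = key, adjustment = adj, orders = ord)
    if (key != "uniform")
      for (cv in covariates)
        tryfit(paste0(key, "+", cv), key = key,
               formula = stats::as.formula(paste("~", cv)))
  }
  if (length(fits) == 0L) stop("no detection-function candidate converged")
  fits
}

#' Estimate nest density by stratum from a fitted detection function
#'
#' Computes \eqn{\hat D = n / (2 w L \hat P_a)} per stratum, converted to
#' nests per 25 ha, where `n` is the number of retained detections, `L` the
#' total transect length walked (length times survey rounds, summed over
#' transects) and \eqn{\hat P_a} the average detection probability within
#' the truncation distance `w`. The density variance combines the
#' encounter-rate variance across transects (stratified sample-variance
#' estimator) with the delta-method variance of \eqn{\hat P_a}; confidence
#' intervals are log-normal based. Strata with a single transect fall back
#' to a Poisson encounter-rate variance with a warning; strata with fewer
#' than `min_n` detections are dropped with a warning (the \eqn{\ge 2}-nest
#' rule).
#'
#' @param model a `detfun` fit (fitted to the pooled detections).
#' @param detections data.frame with `distance_m`, the transect keys
#'   (`plot_id`, `transect_id`, and `year` when present) and the `by`
#'   columns.
#' @param effort data.frame with transect keys, `length_m` and `rounds`,
#'   plus the `by` columns.
#' @param by character vector of stratum columns (e.g. `c("year",
#'   "enrolled")` or `"plot_id"`).
#' @param min_n minimum detections per stratum (default 2).
#' @param conf confidence level (default 0.95).
#' @return a data.frame of class `density_est`: one row per stratum with
#'   `n`, `L_m`, `Pa`, `D` (nests per 25 ha), `se`, `cv`, `lcl`, `ucl`.
#' @export
estimate_density <- function(model, detections, effort,
                             by = c("year", "enrolled"),
                             min_n = 2L, conf = 0.95) {
  stopifnot(inherits(model, "detfun"))
  w <- model$w
  miss <- setdiff(by, names(detections))
  if (length(miss)) stop("detections lack stratum columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(by, names(effort))
  if (length(miss)) stop("effort lacks stratum columns: ",
                         paste(miss, collapse = ", "))
  over <- sum(detections$distance_m > w, na.rm = TRUE)
  if (over > 0) {
    demog_log("WARN", over, " detections beyond w = ", w, " dropped")
    detections <- detections[detections$distance_m <= w, , drop = FALSE]
  }

  tkeys <- intersect(c("plot_id", "year", "transect_id"),
                     intersect(names(detections), names(effort)))
  strat_id <- function(d) interaction(d[by], drop = FALSE, sep = "|")
  det_str <- strat_id(detections)
  eff_str <- strat_id(effort)

  has_cov <- length(model$beta) > 1L
  # delta-method variance of Pa via numeric gradient over fitted parameters
  pa_fun <- function(par, det_rows) {
    up <- unpack_par(par, model$key, model$adjustment,
                     length(model$orders),
                     if (model$key != "uniform") length(model$beta) else 0L)
    if (model$key == "uniform") {
      mu <- integrate_g("uniform", NA, NA, model$adjustment, model$orders,
                        up$acoef, w)
      return(mu / w)
    }
    if (!has_cov) {
      mu <- integrate_g(model$key, exp(up$beta[1L]), up$shape,
                        model$adjustment, model$orders, up$acoef, w)
      return(mu / w)
    }
    X <- stats::model.matrix(model$formula, det_rows)
    sig <- as.numeric(exp(X %*% up$beta))
    mus <- vapply(unique(sig), function(s)
      integrate_g(model$key, s, up$shape, model$adjustment, model$orders,
                  up$acoef, w), numeric(1))
    p <- mus[match(sig, unique(sig))] / w
    nrow(det_rows) / sum(1 / p)
  }

  res <- list()
  for (s in levels(droplevels(eff_str))) {
    det_s <- detections[det_str == s, , drop = FALSE]
    eff_s <- effort[eff_str == s, , drop = FALSE]
    n_s <- nrow(det_s)
    if (n_s < min_n) {
      demog_log("WARN", "stratum ", s, " dropped: ", n_s,
                " detections < min_n = ", min_n)
      next
    }
    l_k <- eff_s$length_m * eff_s$rounds
    L <- sum(l_k)
    if (L <= 0) stop("stratum ", s, " has non-positive effort")

    Pa_s <- if (has_cov) pa_fun(model$par, det_s) else model$Pa
    D_m2 <- n_s / (2 * w * L * Pa_s)
    D <- D_m2 * 250000  # 25 ha = 250,000 m^2

    # encounter-rate variance across transect rows
    K <- nrow(eff_s)
    if (K >= 2L) {
      ek <- interaction(eff_s[tkeys], drop = TRUE, sep = "|")
      dk <- interaction(det_s[tkeys], drop = FALSE, sep = "|")
      n_k <- as.numeric(table(factor(dk, levels = levels(ek))))
      r <- n_s / L
      var_er <- K / (L^2 * (K - 1)) * sum(l_k^2 * (n_k / l_k - r)^2)
      cv2_n <- var_er / r^2
    } else {
      demog_log("WARN", "stratum ", s,
                " has a single transect; Poisson encounter-rate variance used")
      cv2_n <- 1 / n_s
    }

    cv2_p <- 0
    if (model$k > 0L && all(is.finite(model$vcov))) {
      gr <- tryCatch(
        pracma::grad(function(p) pa_fun(p, det_s), model$par),
        error = function(e) NULL)
      if (!is.null(gr)) {
        v <- as.numeric(t(gr) %*% model$vcov %*% gr)
        if (is.finite(v) && v > 0) cv2_p <- v / Pa_s^2
      }
    }

    cv2 <- cv2_n + cv2_p
    se <- D * sqrt(cv2)
    # log-normal CI with Satterthwaite df combining the encounter-rate
    # (K - 1 df) and detection (n - k df) variance components
    df_n <- max(K - 1L, 1L)
    df_p <- max(n_s - model$k, 1L)
    df_sat <- if (cv2 > 0)
      cv2^2 / (cv2_n^2 / df_n + cv2_p^2 / df_p) else df_n
    tq <- stats::qt(1 - (1 - conf) / 2, df_sat)
    C <- exp(tq * sqrt(log(1 + cv2)))
    row <- det_s[1L, by, drop = FALSE]
    if (n_s == 0L) row <- eff_s[1L, by, drop = FALSE]
    row$n <- n_s; row$L_m <- L; row$Pa <- Pa_s
    row$D <- D; row$se <- se; row$cv <- sqrt(cv2)
    row$lcl <- D / C; row$ucl <- D * C
    res[[length(res) + 1L]] <- row
  }
  if (length(res) == 0L) stop("no stratum retained for density estimation")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "w") <- w
  attr(out, "conf") <- conf
  class(out) <- c("density_est", "data.frame")
  out
}
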