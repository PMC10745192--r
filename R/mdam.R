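# Hierarchical multispecies dependent double-observer abundance model:
# exact Poisson-thinning marginal likelihood, adaptive random-walk
# Metropolis-within-Gibbs sampler, convergence diagnostics and derived
# pair densities.

#' Dependent double-observer marginal log-likelihood
#'
#' With latent plot abundance N ~ Poisson(lambda), a primary observer
#' detecting each bird with probability p1 and a secondary observer
#' detecting missed birds with probability p2, marginalizing N exactly by
#' Poisson thinning gives independent counts
#' x1 ~ Poisson(lambda p1) and x2 ~ Poisson(lambda (1 - p1) p2).
#'
#' @param x1 primary-observer counts.
#' @param x2 secondary-only counts.
#' @param lambda expected abundance(s), > 0.
#' @param p1,p2 observer detection probabilities in (0, 1).
#' @return the summed log-likelihood over cells.
#' @export
ddo_loglik <- function(x1, x2, lambda, p1, p2) {
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  stopifnot(all(lambda > 0), all(p1 > 0 & p1 < 1), all(p2 > 0 & p2 < 1))
  sum(stats::dpois(x1, lambda * p1, log = TRUE) +
      stats::dpois(x2, lambda * (1 - p1) * p2, log = TRUE))
}

# Brute-force data-augmentation version, used as an independent oracle in
# tests: sum over latent N from x1 + x2 to N_max.
ddo_loglik_augmented <- function(x1, x2, lambda, p1, p2, N_max = 500L) {
  stopifnot(length(x1) == 1L, length(x2) == 1L)
  N <- seq.int(x1 + x2, N_max)
  terms <- stats::dpois(N, lambda, log = TRUE) +
    stats::dbinom(x1, N, p1, log = TRUE) +
    stats::dbinom(x2, N - x1, p2, log = TRUE)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Method-of-moments detection estimate from pooled counts
#'
#' Under a shared detection probability p, E(x2)/E(x1) = 1 - p, so
#' `p_hat = 1 - sum(x2)/sum(x1)`. Used to initialize the MCMC and as a
#' sanity cross-check only.
#'
#' @param counts data.frame with `x1` and `x2` columns (or x1 vector).
#' @param x2 secondary counts when `counts` is a vector.
#' @return the pooled detection estimate, floored at 0.01 with a warning
#'   when the naive estimate is non-positive.
#' @export
moment_detection <- function(counts, x2 = NULL) {
  if (is.data.frame(counts)) {
    x1 <- counts$x1; x2 <- counts$x2
  } else x1 <- counts
  s1 <- sum(x1); s2 <- sum(x2)
  if (s1 <= 0) stop("moment detection estimate needs sum(x1) > 0")
  p <- 1 - s2 / s1
  if (p <= 0) {
    demog_log("WARN", "sum(x2) >= sum(x1); detection estimate floored at 0.01")
    p <- 0.01
  }
  p
}

# index bookkeeping: map count rows to design levels
mdam_design <- function(counts) {
  for (col in c("plot_id", "year", "visit", "species", "observer_primary",
                "observer_secondary", "x1", "x2"))
    if (is.null(counts[[col]])) stop("counts lack column ", col)
  if (is.null(counts$enrolled)) counts$enrolled <- "non-SGI"
  species <- sort(unique(counts$species))
  years <- sort(unique(counts$year))
  plots <- sort(unique(counts$plot_id))
  observers <- sort(unique(c(counts$observer_primary,
                             counts$observer_secondary)))
  list(counts = counts, species = species, years = years, plots = plots,
       observers = observers,
       i_sp = match(counts$species, species),
       i_yr = match(counts$year, years),
       i_pl = match(counts$plot_id, plots),
       i_o1 = match(counts$observer_primary, observers),
       i_o2 = match(counts$observer_secondary, observers),
       sgi = as.numeric(counts$enrolled == "SGI"))
}

# cell-wise log-likelihood given the parameter list
mdam_cells <- function(par, d) {
  eta_l <- par$alpha[d$i_sp] + par$beta_sgi * d$sgi + par$eps[d$i_pl]
  if (length(par$gamma)) eta_l <- eta_l + c(0, par$gamma)[d$i_yr]
  lambda <- exp(eta_l)
  eta_p1 <- par$delta[d$i_o1]
  eta_p2 <- par$delta[d$i_o2]
  if (length(par$eta_sp)) {
    sp_off <- c(0, par$eta_sp)[d$i_sp]
    eta_p1 <- eta_p1 + sp_off; eta_p2 <- eta_p2 + sp_off
  }
  if (length(par$zeta)) {
    yr_off <- c(0, par$zeta)[d$i_yr]
    eta_p1 <- eta_p1 + yr_off; eta_p2 <- eta_p2 + yr_off
  }
  p1 <- stats::plogis(eta_p1)
  p2 <- stats::plogis(eta_p2)
  stats::dpois(d$counts$x1, lambda * p1, log = TRUE) +
    stats::dpois(d$counts$x2, lambda * (1 - p1) * p2, log = TRUE)
}

mdam_prior <- function(par, prior_sd) {
  fx <- c(par$alpha, par$beta_sgi, par$gamma, par$delta, par$eta_sp,
          par$zeta)
  sum(stats::dnorm(fx, 0, prior_sd, log = TRUE))
}

#' Fit the multispecies dependent double-observer abundance model
#'
#' Hierarchical model: plot-level expected abundance
#' \eqn{\log\lambda = \alpha_{sp} + \beta_{SGI}\,SGI + \gamma_{yr} +
#' \varepsilon_{plot}} with \eqn{\varepsilon \sim N(0, \sigma^2)}, and
#' detection \eqn{\mathrm{logit}\,p = \delta_{obs} + \eta_{sp} +
#' \zeta_{yr}}. Repeat visits are conditionally independent replicate
#' thinned observations of a shared plot-year abundance. The latent count
#' is marginalized exactly by Poisson thinning (see [ddo_loglik()]), so no
#' data augmentation is needed. Priors: Normal(0, variance 1000) on all
#' linear-predictor coefficients and Uniform(0, 100) on the plot
#' random-effect SD. Sampling is adaptive random-walk
#' Metropolis-within-Gibbs; proposal scales adapt toward a 0.3 acceptance
#' rate during burn-in only and are frozen afterward.
#'
#' @param counts data.frame of count rows (`plot_id`, `year`, `visit`,
#'   `species`, `observer_primary`, `observer_secondary`, `x1`, `x2`,
#'   optional `enrolled`).
#' @param chains number of chains (default 3).
#' @param iterations iterations per chain including burn-in (default
#'   10000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed RNG seed; one sub-stream per chain.
#' @param prior_sd prior SD on coefficients (default `sqrt(1000)`).
#' @param prior_only drop the count likelihood and sample from the joint
#'   prior (testing hook: the marginal of `sigma_plot` must recover its
#'   Uniform(0, 100) prior).
#' @return object of class `mdam_fit`: `draws` (list of matrices, one per
#'   chain, columns named `alpha[...]`, `beta_sgi`, `gamma[...]`,
#'   `delta[...]`, `eta_sp[...]`, `zeta[...]`, `eps[...]`,
#'   `sigma_plot`), the design, and acceptance rates.
#' @export
fit_mdam <- function(counts, chains = 3L, iterations = 10000L,
                     burn_in = 1000L, thin = 1L, seed = 1L,
                     prior_sd = sqrt(1000), prior_only = FALSE) {
  d <- mdam_design(counts)
  cell_ll <- if (prior_only)
    function(par, d) rep(0, nrow(d$counts)) else mdam_cells
  n_sp <- length(d$species); n_yr <- length(d$years)
  n_pl <- length(d$plots); n_ob <- length(d$observers)
  tot <- stats::aggregate(cbind(x1, x2) ~ species, data = d$counts, sum)
  zero_sp <- tot$species[tot$x1 + tot$x2 == 0]
  if (length(zero_sp))
    demog_log("WARN", "all-zero counts for species ",
              paste(zero_sp, collapse = ", "),
              "; posterior will be prior-dominated")

  p0 <- tryCatch(moment_detection(d$counts), error = function(e) 0.5)
  # crude per-visit total / p0 as abundance start
  mean_tot <- mean(d$counts$x1 + d$counts$x2)
  lam0 <- max(mean_tot / max(p0 + (1 - p0) * p0, 0.1), 0.5)

  par_template <- list(alpha = rep(log(lam0), n_sp), beta_sgi = 0,
                       gamma = rep(0, max(n_yr - 1L, 0L)),
                       delta = rep(stats::qlogis(min(max(p0, 0.05), 0.95)),
                                   n_ob),
                       eta_sp = rep(0, max(n_sp - 1L, 0L)),
                       zeta = rep(0, max(n_yr - 1L, 0L)),
                       eps = rep(0, n_pl), sigma = 0.5)
  blocks <- c("alpha", "beta_sgi", "gamma", "delta", "eta_sp", "zeta")
  run_chain <- function(chain_id) {
    set.seed(stage_seed(seed + 1000L * chain_id, "mcmc"))
    par <- par_template
    # overdisperse starts across chains
    par$alpha <- par$alpha + stats::rnorm(n_sp, 0, 0.3)
    par$delta <- par$delta + stats::rnorm(n_ob, 0, 0.3)
    par$sigma <- stats::runif(1, 0.2, 1)
    scal <- list(alpha = rep(0.1, n_sp), beta_sgi = 0.1,
                 gamma = rep(0.1, length(par$gamma)),
                 delta = rep(0.1, n_ob),
                 eta_sp = rep(0.1, length(par$eta_sp)),
                 zeta = rep(0.1, length(par$zeta)),
                 eps = rep(0.2, n_pl), sigma = 0.2)
    acc <- rapply(scal, function(x) x * 0, how = "replace")
    trials <- acc
    cells <- cell_ll(par, d)
    ll <- sum(cells)
    n_keep <- floor((iterations - burn_in) / thin)
    p_names <- c(paste0("alpha[", d$species, "]"), "beta_sgi",
                 if (length(par$gamma)) paste0("gamma[", d$years[-1], "]"),
                 paste0("delta[", d$observers, "]"),
                 if (length(par$eta_sp))
                   paste0("eta_sp[", d$species[-1], "]"),
                 if (length(par$zeta)) paste0("zeta[", d$years[-1], "]"),
                 paste0("eps[", d$plots, "]"), "sigma_plot")
    draws <- matrix(NA_real_, n_keep, length(p_names),
                    dimnames = list(NULL, p_names))
    keep_i <- 0L
    for (it in seq_len(iterations)) {
      adapting <- it <= burn_in
      # scalar fixed-effect updates
      for (b in blocks) {
        for (j in seq_along(par[[b]])) {
          prop <- par
          prop[[b]][j] <- par[[b]][j] + stats::rnorm(1, 0, scal[[b]][j])
          cells_p <- cell_ll(prop, d)
          ll_p <- sum(cells_p)
          lr <- ll_p - ll +
            stats::dnorm(prop[[b]][j], 0, prior_sd, log = TRUE) -
            stats::dnorm(par[[b]][j], 0, prior_sd, log = TRUE)
          trials[[b]][j] <- trials[[b]][j] + 1
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            par <- prop; ll <- ll_p; cells <- cells_p
            acc[[b]][j] <- acc[[b]][j] + 1
          }
        }
      }
      # vectorized plot random-effect update
      eps_prop <- par$eps + stats::rnorm(n_pl, 0, scal$eps)
      prop <- par; prop$eps <- eps_prop
      cells_p <- cell_ll(prop, d)
      by_pl <- rowsum(cbind(cells, cells_p), d$i_pl)
      lr_pl <- (by_pl[, 2L] - by_pl[, 1L]) +
        stats::dnorm(eps_prop, 0, par$sigma, log = TRUE) -
        stats::dnorm(par$eps, 0, par$sigma, log = TRUE)
      take <- is.finite(lr_pl) & log(stats::runif(n_pl)) < lr_pl
      trials$eps <- trials$eps + 1
      acc$eps <- acc$eps + as.numeric(take)
      if (any(take)) {
        par$eps[take] <- eps_prop[take]
        cells <- cell_ll(par, d)
        ll <- sum(cells)
      }
      # prior-refresh move for the plot effects: propose eps' ~ N(0, sigma)
      # independently per plot; the prior cancels, leaving the likelihood
      # ratio (mixes the hierarchy when the data are weak)
      eps_ref <- stats::rnorm(n_pl, 0, par$sigma)
      prop <- par; prop$eps <- eps_ref
      cells_p <- cell_ll(prop, d)
      by_pl <- rowsum(cbind(cells, cells_p), d$i_pl)
      take <- is.finite(by_pl[, 2L]) &
        log(stats::runif(n_pl)) < (by_pl[, 2L] - by_pl[, 1L])
      if (any(take)) {
        par$eps[take] <- eps_ref[take]
        cells <- cell_ll(par, d)
        ll <- sum(cells)
      }
      # random-effect SD: random-walk Metropolis under the Uniform(0, 100)
      # prior, plus an independence proposal from that prior
      sig_prop <- par$sigma + stats::rnorm(1, 0, scal$sigma)
      trials$sigma <- trials$sigma + 1
      if (sig_prop > 0 && sig_prop < 100) {
        lr <- sum(stats::dnorm(par$eps, 0, sig_prop, log = TRUE)) -
          sum(stats::dnorm(par$eps, 0, par$sigma, log = TRUE))
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          par$sigma <- sig_prop
          acc$sigma <- acc$sigma + 1
        }
      }
      sig_ind <- stats::runif(1, 0, 100)
      lr <- sum(stats::dnorm(par$eps, 0, sig_ind, log = TRUE)) -
        sum(stats::dnorm(par$eps, 0, par$sigma, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr)
        par$sigma <- sig_ind
      # proposal adaptation toward 0.3 acceptance, burn-in only
      if (adapting && it %% 50L == 0L) {
        for (b in names(scal)) {
          rate <- acc[[b]] / pmax(trials[[b]], 1)
          scal[[b]] <- scal[[b]] * exp(0.4 * (rate - 0.3))
          scal[[b]] <- pmin(pmax(scal[[b]], 1e-3), 50)
          acc[[b]] <- acc[[b]] * 0
          trials[[b]] <- trials[[b]] * 0
        }
      }
      if (!adapting && (it - burn_in) %% thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(par$alpha, par$beta_sgi, par$gamma, par$delta,
                             par$eta_sp, par$zeta, par$eps, par$sigma)
      }
    }
    list(draws = draws[seq_len(keep_i), , drop = FALSE],
         accept = rapply(acc, function(x) x, how = "replace"),
         trials = trials)
  }
  chain_out <- lapply(seq_len(chains), run_chain)
  out <- list(draws = lapply(chain_out, `[[`, "draws"),
              design = d, chains = chains, iterations = iterations,
              burn_in = burn_in, thin = thin, seed = seed,
              prior_sd = prior_sd)
  class(out) <- "mdam_fit"
  out
}

#' @export
print.mdam_fit <- function(x, ...) {
  d <- x$design
  cat("Dependent double-observer abundance model (marginalized)\n")
  cat("  cells:", nrow(d$counts), " plots:", length(d$plots),
      " species:", length(d$species), " years:", length(d$years), "\n")
  cat("  chains:", x$chains, " iterations:", x$iterations,
      " burn-in:", x$burn_in, "\n")
  dg <- mdam_diagnostics(x)
  bad <- dg$parameter[dg$flag]
  if (length(bad)) cat("  Rhat > 1.1 for:", paste(bad, collapse = ", "),
                       "\n")
  else cat("  all monitored Rhat <= 1.1\n")
  invisible(x)
}

split_chains <- function(draws_list) {
  out <- list()
  for (m in draws_list) {
    n <- nrow(m)
    h <- floor(n / 2)
    out[[length(out) + 1L]] <- m[seq_len(h), , drop = FALSE]
    out[[length(out) + 1L]] <- m[(n - h + 1L):n, , drop = FALSE]
  }
  out
}

rhat_ess_one <- function(chains) {
  # chains: list of numeric vectors of equal length
  n <- length(chains[[1L]]); m <- length(chains)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W <= .Machine$double.eps)
    return(c(rhat = NA_real_, ess = NA_real_))
  B <- n * stats::var(means)
  varp <- (n - 1) / n * W + B / n
  rhat <- sqrt(varp / W)
  # combined-chain autocorrelation ESS with an initial positive sequence:
  # rho_t = 1 - (W - mean lag-t autocovariance) / varp
  max_lag <- min(n - 2L, 2000L)
  acv <- rowMeans(vapply(chains, function(ch)
    as.numeric(stats::acf(ch, lag.max = max_lag, type = "covariance",
                          plot = FALSE, demean = TRUE)$acf),
    numeric(max_lag + 1L)))
  rho <- 1 - (W - acv[-1L]) / varp
  s <- 0; lag <- 1L
  while (lag + 1L <= max_lag) {
    pair <- rho[lag] + rho[lag + 1L]
    if (pair < 0) break
    s <- s + pair
    lag <- lag + 2L
  }
  ess <- m * n / (1 + 2 * s)
  c(rhat = rhat, ess = min(ess, m * n))
}

#' MCMC convergence diagnostics
#'
#' Split-Rhat (each chain halved, the potential scale reduction factor
#' computed across the halves) and a combined-autocorrelation effective
#' sample size per monitored parameter. Parameters with Rhat above the
#' threshold are flagged; constant parameters report NA.
#'
#' @param fit an `mdam_fit`, or a list of draw matrices with identical
#'   column names.
#' @param threshold Rhat flag threshold (default 1.1).
#' @return data.frame: `parameter`, `rhat`, `ess`, `flag`.
#' @export
mdam_diagnostics <- function(fit, threshold = 1.1) {
  draws <- if (inherits(fit, "mdam_fit")) fit$draws else fit
  stopifnot(is.list(draws), length(draws) >= 1L)
  if (length(draws) < 2L && nrow(draws[[1L]]) < 4L)
    stop("diagnostics need >= 2 chains or enough draws to split")
  halves <- split_chains(draws)
  pars <- colnames(draws[[1L]])
  res <- t(vapply(pars, function(p)
    rhat_ess_one(lapply(halves, function(m) m[, p])), numeric(2)))
  out <- data.frame(parameter = pars, rhat = res[, 1L], ess = res[, 2L],
                    stringsAsFactors = FALSE)
  out$flag <- !is.na(out$rhat) & out$rhat > threshold
  rownames(out) <- NULL
  out
}

#' Posterior pair densities per plot-year-species
#'
#' Reconstructs the abundance lambda (birds per 25-ha plot) for every
#' plot-year-species from the posterior draws, halves it under the assumed
#' 1:1 sex ratio (two birds of a species = one pair), and summarizes with
#' the posterior mean, median and a central credible interval.
#'
#' @param fit an `mdam_fit`.
#' @param level credible level (default 0.95).
#' @return data.frame of class `pair_density_est`: `plot_id`, `year`,
#'   `species`, `enrolled`, `pairs` (posterior mean), `median`, `lcl`,
#'   `ucl`, `lambda` (posterior mean abundance).
#' @export
pair_density <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mdam_fit"))
  d <- fit$design
  all_draws <- do.call(rbind, fit$draws)
  a <- (1 - level) / 2
  grid <- unique(d$counts[, c("plot_id", "year", "species", "enrolled")])
  sgi <- as.numeric(grid$enrolled == "SGI")
  out <- grid
  out$lambda <- out$pairs <- out$median <- out$lcl <- out$ucl <- NA_real_
  for (i in seq_len(nrow(grid))) {
    eta <- all_draws[, paste0("alpha[", grid$species[i], "]")] +
      all_draws[, "beta_sgi"] * sgi[i] +
      all_draws[, paste0("eps[", grid$plot_id[i], "]")]
    gcol <- paste0("gamma[", grid$year[i], "]")
    if (gcol %in% colnames(all_draws)) eta <- eta + all_draws[, gcol]
    lam <- exp(eta)
    pr <- lam / 2
    out$lambda[i] <- mean(lam)
    out$pairs[i] <- mean(pr)
    out$median[i] <- stats::median(pr)
    qs <- stats::quantile(pr, c(a, 1 - a), names = FALSE)
    out$lcl[i] <- qs[1L]; out$ucl[i] <- qs[2L]
  }
  rownames(out) <- NULL
  class(out) <- c("pair_density_est", "data.frame")
  out
}

#' Posterior summary of per-observer detection probabilities
#'
#' @param fit an `mdam_fit`.
#' @param level credible level (default 0.95).
#' @return data.frame with one row per observer-species-year combination
#'   present in the data: posterior mean detection and credible interval.
#' @export
detection_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mdam_fit"))
  d <- fit$design
  all_draws <- do.call(rbind, fit$draws)
  a <- (1 - level) / 2
  grid <- expand.grid(observer = d$observers, species = d$species,
                      year = d$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- grid
  out$p <- out$lcl <- out$ucl <- NA_real_
  for (i in seq_len(nrow(grid))) {
    eta <- all_draws[, paste0("delta[", grid$observer[i], "]")]
    scol <- paste0("eta_sp[", grid$species[i], "]")
    if (scol %in% colnames(all_draws)) eta <- eta + all_draws[, scol]
    ycol <- paste0("zeta[", grid$year[i], "]")
    if (ycol %in% colnames(all_draws)) eta <- eta + all_draws[, ycol]
    p <- stats::plogis(eta)
    out$p[i] <- mean(p)
    qs <- stats::quantile(p, c(a, 1 - a), names = FALSE)
    out$lcl[i] <- qs[1L]; out$ucl[i] <- qs[2L]
  }
  out
}
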