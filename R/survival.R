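# Logistic-exposure daily nest survival: exposure-interval construction,
# marginal maximum likelihood with a plot random effect (Gauss-Hermite
# quadrature), AICc model ranking and derived seasonal survival.

#' Decompose nest visit histories into exposure intervals
#'
#' Each pair of consecutive visits up to the terminal one becomes one
#' survival trial: `t` exposure days, outcome `y = 1` if the nest was still
#' active (or fledged) at the interval end and `y = 0` if it had failed,
#' with the stage taken at the interval start. Opportunistically found
#' nests are included. Single-visit histories are excluded with a warning.
#'
#' @param visits data.frame of nest checks with columns `nest_id`,
#'   `plot_id`, `species`, `year`, `day` (or `visit_date` as Date),
#'   `stage` (`"egg"`/`"nestling"`), `status`
#'   (`"active"`/`"fledged"`/`"failed"`).
#' @param exposure `"full"` (default) scores a failed interval's exposure
#'   as the whole interval length; `"midpoint"` halves it, the classic
#'   Mayfield convention.
#' @return data.frame of intervals: `nest_id`, `plot_id`, `species`,
#'   `year`, `t`, `stage`, `y`.
#' @export
build_exposure_intervals <- function(visits, exposure = c("full",
                                                          "midpoint")) {
  exposure <- match.arg(exposure)
  if (is.null(visits$day)) {
    if (is.null(visits$visit_date))
      stop("visits need a `day` or `visit_date` column")
    visits$day <- as.numeric(as.Date(visits$visit_date))
  }
  out <- list(); dropped <- 0L
  for (id in unique(visits$nest_id)) {
    h <- visits[visits$nest_id == id, , drop = FALSE]
    if (any(diff(h$day) <= 0))
      stop("non-monotone visit dates for nest ", id)
    term <- which(h$status %in% c("fledged", "failed"))
    if (length(term)) h <- h[seq_len(term[1L]), , drop = FALSE]
    if (nrow(h) < 2L) { dropped <- dropped + 1L; next }
    k <- nrow(h) - 1L
    t_i <- diff(h$day)
    y_i <- as.integer(h$status[-1L] != "failed")
    if (exposure == "midpoint") t_i[y_i == 0L] <- t_i[y_i == 0L] / 2
    out[[length(out) + 1L]] <- data.frame(
      nest_id = id, plot_id = h$plot_id[1L], species = h$species[1L],
      year = h$year[1L], t = t_i, stage = h$stage[-(k + 1L)], y = y_i,
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    demog_log("WARN", dropped, " single-visit histories excluded")
  if (length(out) == 0L) stop("no usable exposure intervals")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Logistic-exposure interval log-likelihood
#'
#' For an interval of `t` exposure days with daily survival `theta`, the
#' survival probability is `theta^t`; the log-likelihood contribution is
#' `t log(theta)` for a surviving interval and `log(1 - theta^t)` for a
#' failed one. Boundary values of `theta` that would give `-Inf` are
#' guarded with a large finite penalty.
#'
#' @param y 0/1 outcomes.
#' @param t exposure days (> 0).
#' @param theta daily survival rate(s) in (0, 1].
#' @return the summed log-likelihood.
#' @examples
#' logexp_loglik(1, 3, 0.9)  # log(0.729)
#' @export
logexp_loglik <- function(y, t, theta) {
  stopifnot(all(t > 0), all(theta > 0 & theta <= 1))
  ll <- ifelse(y == 1, t * log(theta), log1p(-exp(t * log(theta))))
  ll[!is.finite(ll)] <- -1e10
  sum(ll)
}

#' Fit a logistic-exposure daily nest survival model
#'
#' Maximizes the (marginal) likelihood of exposure intervals where
#' \eqn{\mathrm{logit}(\theta_i) = x_i'\beta + u_{plot}} and an interval
#' survives with probability \eqn{\theta_i^{t_i}}. The plot random effect
#' \eqn{u \sim N(0, \sigma^2)} is integrated out by Gauss-Hermite
#' quadrature.
#'
#' @param intervals data.frame from [build_exposure_intervals()], joined
#'   with any covariates named in `formula`; must contain `y`, `t` and
#'   `plot_id` when `random_plot = TRUE`.
#' @param formula model formula with `y` on the left, e.g.
#'   `y ~ stage + year`.
#' @param random_plot include the plot random intercept (default TRUE).
#' @param nagq number of Gauss-Hermite quadrature nodes (default 10).
#' @return object of class `dsr_model`: `coef`, `vcov`, `sigma_plot`,
#'   `loglik`, `k`, `n`, `AICc`.
#' @export
fit_dsr <- function(intervals, formula = y ~ 1, random_plot = TRUE,
                    nagq = 10L) {
  mf <- stats::model.frame(formula, intervals)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  t_i <- intervals$t
  stopifnot(length(y) == nrow(X), length(t_i) == length(y), all(t_i > 0))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix rank deficient; check columns: ",
         paste(colnames(X), collapse = ", "))
  }
  n <- length(y)
  p <- ncol(X)

  # crude Mayfield start for the intercept: 1 - failures / exposure days
  dsr0 <- max(min(1 - sum(y == 0) / sum(t_i), 0.99), 0.5)
  start <- c(stats::qlogis(dsr0), rep(0, p - 1L))

  ll_fixed <- function(beta, u = 0) {
    eta <- as.numeric(X %*% beta) + u
    theta <- stats::plogis(eta)
    lt <- t_i * log(theta)
    ifelse(y == 1, lt, log1p(-exp(lt)))
  }

  if (!random_plot) {
    negll <- function(par) {
      ll <- ll_fixed(par)
      ll[!is.finite(ll)] <- -1e10
      -sum(ll)
    }
    fit <- stats::nlminb(start, negll,
                         control = list(rel.tol = 1e-12, iter.max = 500))
    k <- p
    sigma_plot <- NA_real_
    par_full <- fit$par
  } else {
    if (is.null(intervals$plot_id))
      stop("random_plot = TRUE requires a plot_id column")
    plot_f <- factor(intervals$plot_id)
    gh <- pracma::gaussHermite(nagq)
    negll <- function(par) {
      beta <- par[seq_len(p)]
      sig <- exp(par[p + 1L])
      # n x nagq matrix of interval log-likelihoods at each node
      llk <- vapply(seq_len(nagq), function(k2)
        ll_fixed(beta, sqrt(2) * sig * gh$x[k2]), numeric(n))
      llk[!is.finite(llk)] <- -1e10
      per_plot <- rowsum(llk, plot_f)         # plots x nodes
      lw <- sweep(per_plot, 2L, log(gh$w), "+")
      m <- apply(lw, 1L, max)
      lmarg <- m + log(rowSums(exp(lw - m))) - 0.5 * log(pi)
      -sum(lmarg)
    }
    fit <- stats::nlminb(c(start, log(0.3)), negll,
                         control = list(rel.tol = 1e-12, iter.max = 500))
    k <- p + 1L
    sigma_plot <- exp(fit$par[p + 1L])
    par_full <- fit$par
  }

  coefs <- stats::setNames(par_full[seq_len(p)], colnames(X))
  if (any(abs(coefs) > 15))
    demog_log("WARN", "possible separation: |coefficient| > 15 in ",
              deparse(formula))
  H <- tryCatch(stats::optimHess(par_full, negll), error = function(e) NULL)
  vc <- matrix(NA_real_, length(par_full), length(par_full))
  if (!is.null(H)) {
    Vt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vt)) vc <- Vt
  }
  out <- list(coef = coefs, vcov = vc[seq_len(p), seq_len(p), drop = FALSE],
              sigma_plot = sigma_plot, loglik = -fit$objective,
              k = k, n = n, AICc = aicc(-fit$objective, k, n),
              formula = formula, random_plot = random_plot,
              converged = fit$convergence == 0L, nagq = nagq)
  class(out) <- "dsr_model"
  out
}

#' @export
print.dsr_model <- function(x, ...) {
  cat("Logistic-exposure nest survival model:", deparse(x$formula), "\n")
  cat("  n =", x$n, "intervals  logLik =", format(x$loglik, digits = 6),
      " AICc =", format(x$AICc, digits = 6), "\n")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coef, se = se))
  if (x$random_plot)
    cat("  plot random-effect SD =", format(x$sigma_plot, digits = 4), "\n")
  invisible(x)
}

#' @export
logLik.dsr_model <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
coef.dsr_model <- function(object, ...) object$coef

#' @export
vcov.dsr_model <- function(object, ...) object$vcov

#' Predicted daily survival rate
#'
#' @param object a `dsr_model`.
#' @param newdata data.frame of covariates (the plot random effect is set
#'   to its mean, zero).
#' @param ... unused.
#' @return vector of daily survival rates in (0, 1).
#' @export
predict.dsr_model <- function(object, newdata, ...) {
  rhs <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(rhs, newdata)
  as.numeric(stats::plogis(X %*% object$coef))
}

#' Seasonal nest survival from a daily rate
#'
#' The probability a nest survives the whole nesting period (egg laying to
#' fledging) is the daily survival rate raised to the period length.
#'
#' @param dsr daily survival rate(s) in `[0, 1]`.
#' @param period_days nesting period length in days (>= 1).
#' @return `dsr ^ period_days`.
#' @examples
#' seasonal_survival(0.81, 15)  # ~0.042
#' @export
seasonal_survival <- function(dsr, period_days) {
  stopifnot(all(dsr >= 0 & dsr <= 1), all(period_days >= 1))
  dsr^period_days
}

# terminal fate per nest from a visit table
terminal_fates <- function(visits) {
  ord <- order(visits$nest_id, visits$day)
  v <- visits[ord, , drop = FALSE]
  last <- !duplicated(v$nest_id, fromLast = TRUE)
  v[last, c("nest_id", "plot_id", "species", "year", "status", "cause"),
    drop = FALSE]
}

#' Apparent nest success
#'
#' The raw fraction of monitored nests whose terminal status is fledged,
#' uncorrected for discovery bias. Histories still active at the last
#' visit are censored and excluded by default.
#'
#' @param histories a visit table (as from [simulate_nest_histories()]) or
#'   a nest-level data.frame with a `fate`/`status` column.
#' @param censored how to treat censored histories: `"exclude"` (default),
#'   `"failed"` or `"fledged"`.
#' @return list with `fraction`, `fledged`, `total`.
#' @examples
#' # 66 of 112 fledged -> 0.589
#' @export
apparent_success <- function(histories, censored = c("exclude", "failed",
                                                     "fledged")) {
  censored <- match.arg(censored)
  fate <- nest_fates(histories)
  cens <- !fate %in% c("fledged", "failed")
  if (any(cens)) {
    if (censored == "exclude") fate <- fate[!cens]
    else fate[cens] <- censored
  }
  total <- length(fate)
  if (total == 0L) stop("no nests with terminal fate")
  fledged <- sum(fate == "fledged")
  list(fraction = fledged / total, fledged = fledged, total = total)
}

nest_fates <- function(histories) {
  if (!is.null(histories$fate)) return(histories$fate)
  if (!is.null(histories$status) && !is.null(histories$nest_id) &&
      anyDuplicated(histories$nest_id)) {
    if (is.null(histories$day))
      histories$day <- as.numeric(as.Date(histories$visit_date))
    return(terminal_fates(histories)$status)
  }
  if (!is.null(histories$status)) return(histories$status)
  stop("histories need a `fate` or `status` column")
}

#' Breakdown of nest failure causes
#'
#' Tabulates the cause of failure over failed nests only; fractions sum to
#' one. Failures without a cause label fall into an `"unknown"` bucket.
#'
#' @param histories as in [apparent_success()]; failed nests should carry a
#'   `cause` label (e.g. predation, abandonment).
#' @return data.frame with `cause`, `count`, `fraction`.
#' @export
failure_causes <- function(histories) {
  fate <- nest_fates(histories)
  cause <- if (!is.null(histories$cause)) histories$cause
           else rep(NA_character_, length(fate))
  if (!is.null(histories$nest_id) && anyDuplicated(histories$nest_id) &&
      is.null(histories$fate)) {
    if (is.null(histories$day))
      histories$day <- as.numeric(as.Date(histories$visit_date))
    tf <- terminal_fates(histories)
    fate <- tf$status; cause <- tf$cause
  }
  failed <- fate == "failed"
  if (!any(failed)) stop("no failed nests")
  cause <- cause[failed]
  cause[is.na(cause) | cause == ""] <- "unknown"
  tab <- table(cause)
  out <- data.frame(cause = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count), , drop = FALSE]
}
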