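#' Small-sample Akaike information criterion
#'
#' AICc penalizes the ordinary AIC for small samples:
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1}.}
#' As \eqn{n \to \infty} the correction vanishes and AICc converges to AIC.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (detections for distance sampling, exposure
#'   intervals for nest survival).
#' @return the AICc value, a single numeric.
#' @examples
#' aicc(-10, k = 2, n = 10)  # 25.7143
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.numeric(loglik), length(loglik) == 1L,
            is.numeric(k), k >= 0, is.numeric(n))
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Builds the conventional model-selection table: models sorted by AICc
#' (ascending), with ties broken by fewer parameters and then by model name,
#' plus delta-AICc and Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param models a named list of fitted models; each must respond to
#'   `logLik()` (with attributes `df` and `nobs`) or carry `loglik`, `k`,
#'   `n` fields.
#' @return a data.frame of class `demog_modtab` with columns `model`, `k`,
#'   `n`, `loglik`, `AICc`, `dAICc`, `weight`, ordered best-first, and an
#'   attribute `top` holding the best model's name.
#' @export
rank_models <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  info <- lapply(models, function(m) {
    if (!is.null(m$loglik) && !is.null(m$k) && !is.null(m$n)) {
      list(ll = m$loglik, k = m$k, n = m$n)
    } else {
      ll <- stats::logLik(m)
      list(ll = as.numeric(ll), k = attr(ll, "df"), n = attr(ll, "nobs"))
    }
  })
  converged <- vapply(info, function(x) is.finite(x$ll), logical(1))
  if (!any(converged)) stop("no converged candidate models to rank")
  info <- info[converged]
  tab <- data.frame(
    model = names(info),
    k = vapply(info, `[[`, numeric(1), "k"),
    n = vapply(info, `[[`, numeric(1), "n"),
    loglik = vapply(info, `[[`, numeric(1), "ll"),
    stringsAsFactors = FALSE
  )
  tab$AICc <- mapply(aicc, tab$loglik, tab$k, tab$n)
  ord <- order(tab$AICc, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  attr(tab, "top") <- tab$model[1L]
  class(tab) <- c("demog_modtab", "data.frame")
  tab
}

#' @export
print.demog_modtab <- function(x, digits = 4, ...) {
  cat("Model selection table (AICc), top model:", attr(x, "top"), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# Derive a per-stage RNG seed from the master seed so that adding one
# generator never perturbs another's draws.  Offsets are fixed per stage.
stage_seed <- function(seed, stage) {
  offsets <- c(plots = 11L, nests = 23L, histories = 37L, ddo = 51L,
               mcmc = 67L, acceptance = 83L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]] * 9973) %% 2147483647)
}

# Evaluate `expr` under a stage-local RNG state, restoring the caller's.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# One-line structured log message; level in {INFO, WARN, ERROR}.
demog_log <- function(level, ...) {
  level <- match.arg(level, c("INFO", "WARN", "ERROR"))
  msg <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (level == "WARN") warning(msg, call. = FALSE) else message(msg)
  invisible(msg)
}
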