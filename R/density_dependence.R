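# Density-dependence comparison: join plot-level nest density and adult
# pair density estimates and test their linear association.

#' Join nest density and adult pair density estimates
#'
#' Inner join on the shared keys (default plot and species, pooling years
#' by the mean when `year` is not a key). Unmatched records are logged
#' with a reason (e.g. a plot excluded from density estimation by the
#' two-nest rule). Duplicate keys after aggregation are an error.
#'
#' @param nest_est a `density_est` data.frame (must carry the key columns
#'   and `D`).
#' @param pair_est a `pair_density_est` data.frame (key columns and
#'   `pairs`).
#' @param by join keys, default `c("plot_id", "species")`; add `"year"` to
#'   pair by plot-year.
#' @return data.frame of paired records: keys, `nest_density`,
#'   `pair_density`, plus `enrolled` when available in either input.
#' @export
join_densities <- function(nest_est, pair_est,
                           by = c("plot_id", "species")) {
  for (col in by) {
    if (is.null(nest_est[[col]]))
      stop("nest estimates lack join column ", col)
    if (is.null(pair_est[[col]]))
      stop("pair estimates lack join column ", col)
  }
  agg <- function(df, value, out_name) {
    full_key <- c(by, if ("year" %in% names(df) && !"year" %in% by) "year")
    if (anyDuplicated(df[full_key]))
      stop("duplicate ", paste(full_key, collapse = "-"),
           " keys in density estimates")
    keep <- c(by, if ("enrolled" %in% names(df) &&
                      !"enrolled" %in% by) "enrolled")
    f <- stats::aggregate(df[[value]], df[keep], mean)
    names(f)[ncol(f)] <- out_name
    f
  }
  nd <- agg(as.data.frame(nest_est), "D", "nest_density")
  pd <- agg(as.data.frame(pair_est), "pairs", "pair_density")
  if (anyDuplicated(nd[by]) || anyDuplicated(pd[by]))
    stop("duplicate keys in density estimates after aggregation")
  joined <- merge(nd, pd, by = intersect(names(nd), names(pd)))
  if (nrow(joined) == 0L) stop("empty join between density estimates")
  only_n <- nrow(nd) - nrow(joined)
  only_p <- nrow(pd) - nrow(joined)
  if (only_n > 0)
    demog_log("INFO", only_n, " nest-density records without an abundance ",
              "match excluded (e.g. plots below the two-nest rule)")
  if (only_p > 0)
    demog_log("INFO", only_p, " abundance records without a nest-density ",
              "match excluded")
  rownames(joined) <- NULL
  joined
}

#' Pearson correlation test
#'
#' Computes \eqn{r = \sum (x_i - \bar x)(y_i - \bar y) /
#' \sqrt{\sum (x_i - \bar x)^2 \sum (y_i - \bar y)^2}} and the two-sided
#' p-value from \eqn{t = r\sqrt{n - 2}/\sqrt{1 - r^2}} on `n - 2` degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-degenerate.
#' @return list of class `pearson_cor`: `r`, `p`, `t`, `df`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Pearson test needs n >= 3 paired records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in an input vector")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(min(r, 1), -1)
  df <- n - 2L
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf; p <- 0
  } else {
    t_stat <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  out <- list(r = r, p = p, t = t_stat, df = df, n = n)
  class(out) <- "pearson_cor"
  out
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, t = %.3f on %d df, p = %.3f (n = %d)\n",
              x$r, x$t, x$df, x$p, x$n))
  invisible(x)
}

#' Pair-to-nest density ratio summary
#'
#' Distribution of adult pair density divided by nest density per species
#' (and per enrollment stratum when available). Records with zero nest
#' density have an undefined ratio and are excluded with a log entry.
#'
#' @param records paired records from [join_densities()].
#' @return data.frame: `species` (and `enrolled` stratum rows), `n`,
#'   `mean_ratio`, `min_ratio`, `max_ratio`.
#' @export
density_ratio <- function(records) {
  stopifnot(all(c("species", "nest_density", "pair_density") %in%
                names(records)))
  zero <- records$nest_density == 0
  if (any(zero)) {
    demog_log("WARN", sum(zero),
              " records with zero nest density excluded from ratios")
    records <- records[!zero, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records with positive nest density")
  records$ratio <- records$pair_density / records$nest_density
  summarize <- function(df, label) {
    data.frame(species = df$species[1L], stratum = label, n = nrow(df),
               mean_ratio = mean(df$ratio), min_ratio = min(df$ratio),
               max_ratio = max(df$ratio), stringsAsFactors = FALSE)
  }
  out <- list()
  for (sp in unique(records$species)) {
    rs <- records[records$species == sp, , drop = FALSE]
    out[[length(out) + 1L]] <- summarize(rs, "all")
    if ("enrolled" %in% names(rs))
      for (e in unique(rs$enrolled))
        out[[length(out) + 1L]] <-
          summarize(rs[rs$enrolled == e, , drop = FALSE], e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Density-dependence comparison per species
#'
#' Runs [pearson_test()] and [density_ratio()] per species over paired
#' plot-level records.
#'
#' @param records paired records from [join_densities()].
#' @return data.frame: `species`, `n`, `r`, `t`, `p`, `mean_ratio`.
#' @export
density_dependence <- function(records) {
  out <- list()
  for (sp in unique(records$species)) {
    rs <- records[records$species == sp, , drop = FALSE]
    ct <- pearson_test(rs$nest_density, rs$pair_density)
    rat <- density_ratio(rs)
    out[[length(out) + 1L]] <- data.frame(
      species = sp, n = ct$n, r = ct$r, t = ct$t, p = ct$p,
      mean_ratio = rat$mean_ratio[rat$stratum == "all"],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
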