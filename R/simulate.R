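# Synthetic survey generator: plots with covariates, line-transect nest
# detections, nest visit histories, and dependent double-observer counts,
# all tied to a truth table so each estimator can be tested by parameter
# recovery.

#' Build and validate a simulation configuration
#'
#' Defines the study conditions the generator emulates: a grid of 25-ha
#' (500 x 500 m) plots, half enrolled in a grazing-management conservation
#' program, surveyed over several breeding seasons with parallel
#' north-south nest transects, repeated nest visits and two-observer
#' dependent adult counts. Defaults describe two sparrow-like species with
#' distinct daily survival rates and nesting periods.
#'
#' @param n_plots number of 25-ha plots (default 80).
#' @param prop_enrolled fraction of plots enrolled in the conservation
#'   program (default 0.5).
#' @param years vector of year labels (default 2016:2018).
#' @param species a data.frame with one row per species and columns `name`,
#'   `nest_density` (true nests per 25 ha present at a survey round),
#'   `dsr_egg`, `dsr_nestling` (daily survival rates by stage),
#'   `period` (days, egg laying to fledging), `hatch_day` (last egg-stage
#'   day; default `round(0.55 * period)`), `adult_density` (birds per
#'   25 ha).
#' @param key,scale,shape nest detection function: key family
#'   (`"halfnorm"`, `"hazard"`, `"uniform"`), scale sigma in meters, and
#'   hazard shape b.
#' @param observers named numeric vector of per-observer adult detection
#'   probabilities (two observers who swap primary/secondary roles between
#'   visits).
#' @param n_transects,transect_length,half_width,transect_spacing survey
#'   geometry in meters; transects are parallel, north-south, and must fit
#'   inside the 500 x 500 m plot.
#' @param rounds survey rounds per season (default 3); `round_spacing` days
#'   between rounds (default 17, about 2.5 weeks).
#' @param visit_interval days between nest status checks (default 3).
#' @param p_opportunistic probability that a nest missed by the transect
#'   protocol is still found opportunistically (no distance recorded).
#' @param plot_cv coefficient of variation of a log-normal plot-quality
#'   multiplier shared by nest and adult densities (default 0.5); set 0 for
#'   homogeneous plots.
#' @param cause_probs probabilities of failure causes (predation,
#'   abandonment, other).
#' @param covariate_pars list of distribution parameters for plot
#'   covariates (shrub cover Beta; GPP, LAI, precipitation, temperatures
#'   Normal), identical across enrollment groups.
#' @param seed master seed; every generator derives its own RNG stream from
#'   it, so the seed fully determines all outputs.
#' @return a validated list of class `demog_config`.
#' @export
sim_config <- function(n_plots = 80L,
                       prop_enrolled = 0.5,
                       years = 2016:2018,
                       species = default_species(),
                       key = "halfnorm",
                       scale = 7.6,
                       shape = 2.5,
                       observers = c(obs1 = 0.48, obs2 = 0.48),
                       n_transects = 5L,
                       transect_length = 500,
                       half_width = 25,
                       transect_spacing = 100,
                       rounds = 3L,
                       round_spacing = 17L,
                       visit_interval = 3L,
                       p_opportunistic = 0.25,
                       plot_cv = 0.5,
                       cause_probs = c(predation = 0.78, abandonment = 0.15,
                                       other = 0.07),
                       covariate_pars = default_covariate_pars(),
                       seed = 1L) {
  if (!is.numeric(n_plots) || n_plots < 2)
    stop("configuration error: n_plots must be >= 2")
  if (!is.numeric(prop_enrolled) || prop_enrolled < 0 || prop_enrolled > 1)
    stop("configuration error: prop_enrolled must be in [0, 1]")
  stopifnot(is.data.frame(species), nrow(species) >= 1L)
  req <- c("name", "nest_density", "dsr_egg", "dsr_nestling", "period",
           "adult_density")
  miss <- setdiff(req, names(species))
  if (length(miss)) stop("configuration error: species table lacks ",
                         paste(miss, collapse = ", "))
  if (is.null(species$hatch_day))
    species$hatch_day <- round(0.55 * species$period)
  with(species, {
    if (any(nest_density < 0) || any(adult_density < 0))
      stop("configuration error: densities must be >= 0")
    if (any(dsr_egg <= 0 | dsr_egg > 1) || any(dsr_nestling <= 0 |
                                               dsr_nestling > 1))
      stop("configuration error: daily survival rates must be in (0, 1]")
    if (any(period < 1)) stop("configuration error: period must be >= 1 day")
  })
  if (!key %in% KEY_FUNS) stop("configuration error: unknown key ", key)
  if (key != "uniform" && scale <= 0)
    stop("configuration error: detection scale must be > 0")
  if (any(observers <= 0 | observers > 1))
    stop("configuration error: observer detection probabilities in (0, 1]")
  if (length(observers) < 2L)
    stop("configuration error: need >= 2 observers for dependent counts")
  tx <- transect_x(n_transects, transect_spacing)
  if (any(tx < 25) || any(tx > 475) || transect_length > 500)
    stop("configuration error: transect layout does not fit a 500 x 500 m ",
         "plot with a 25 m edge buffer")
  if (half_width <= 0 || half_width > 250)
    stop("configuration error: strip half-width must be in (0, 250] m")
  if (abs(sum(cause_probs) - 1) > 1e-8)
    stop("configuration error: cause_probs must sum to 1")
  cfg <- list(n_plots = as.integer(n_plots), prop_enrolled = prop_enrolled,
              years = years, species = species, key = key, scale = scale,
              shape = shape, observers = observers,
              n_transects = as.integer(n_transects),
              transect_length = transect_length, half_width = half_width,
              transect_spacing = transect_spacing,
              rounds = as.integer(rounds),
              round_spacing = as.integer(round_spacing),
              visit_interval = as.integer(visit_interval),
              p_opportunistic = p_opportunistic, plot_cv = plot_cv,
              cause_probs = cause_probs, covariate_pars = covariate_pars,
              seed = as.integer(seed))
  class(cfg) <- "demog_config"
  cfg
}

#' @rdname sim_config
#' @export
default_species <- function() {
  data.frame(
    name = c("brewers_sparrow", "vesper_sparrow"),
    nest_density = c(5.0, 6.2),      # nests per 25 ha at a survey round
    dsr_egg = c(0.88, 0.79),
    dsr_nestling = c(0.92, 0.83),
    period = c(19L, 15L),
    adult_density = c(18, 12.5),     # birds per 25 ha
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_covariate_pars <- function() {
  list(shrub = c(shape1 = 4, shape2 = 16),   # Beta; mean cover ~0.20
       gpp = c(mean = 1.2, sd = 0.3),
       lai = c(mean = 0.4, sd = 0.1),
       precip = c(mean = 36, sd = 8),        # cm, annual
       temp_max = c(mean = 26, sd = 3),      # deg C
       temp_min = c(mean = 4, sd = 2))
}

transect_x <- function(n_transects, spacing) {
  # parallel north-south lines every `spacing` m, centered in the plot
  offset <- (500 - (n_transects - 1) * spacing) / 2
  offset + (seq_len(n_transects) - 1) * spacing
}

#' Generate plot records with covariates and enrollment flags
#'
#' Creates one record per plot-year. Exactly
#' `round(n_plots * prop_enrolled)` plots are flagged enrolled; covariates
#' are drawn from the configured distributions identically across
#' enrollment groups. A latent log-normal plot-quality multiplier (shared
#' by nest and adult densities, stable across years) is attached as the
#' `quality` attribute and surfaces in the truth table.
#'
#' @param config a `demog_config`.
#' @return data.frame of plot-years: `plot_id`, `year`, `enrolled`
#'   (`"SGI"`/`"non-SGI"`), `shrub_cover`, `gpp_mean`, `lai_mean`,
#'   `precip_mean`, `temp_max`, `temp_min`.
#' @export
generate_plots <- function(config) {
  stopifnot(inherits(config, "demog_config"))
  with_stage_seed(config$seed, "plots", {
    np <- config$n_plots
    n_enr <- round(np * config$prop_enrolled)
    ids <- sprintf("P%03d", seq_len(np))
    enrolled <- rep("non-SGI", np)
    enrolled[sample.int(np, n_enr)] <- "SGI"
    cv <- config$plot_cv
    quality <- if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      exp(stats::rnorm(np, -sdl^2 / 2, sdl))  # mean-1 log-normal
    } else rep(1, np)
    cp <- config$covariate_pars
    rows <- expand.grid(plot_id = ids, year = config$years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(rows)
    rows$enrolled <- enrolled[match(rows$plot_id, ids)]
    rows$shrub_cover <- stats::rbeta(n, cp$shrub[1], cp$shrub[2])
    rows$gpp_mean <- stats::rnorm(n, cp$gpp[1], cp$gpp[2])
    rows$lai_mean <- stats::rnorm(n, cp$lai[1], cp$lai[2])
    rows$precip_mean <- stats::rnorm(n, cp$precip[1], cp$precip[2])
    rows$temp_max <- stats::rnorm(n, cp$temp_max[1], cp$temp_max[2])
    rows$temp_min <- stats::rnorm(n, cp$temp_min[1], cp$temp_min[2])
    rows <- rows[order(rows$year, rows$plot_id), , drop = FALSE]
    rownames(rows) <- NULL
    attr(rows, "quality") <- stats::setNames(quality, ids)
    rows
  })
}

#' Simulate line-transect nest detections
#'
#' Each survey round places a fresh latent nest field uniformly over every
#' plot at the plot's true density (rounds are independent snapshots,
#' mirroring staggered nest initiation). A nest within the strip half-width
#' of its nearest transect is detected with probability g(x) from the
#' configured key function at its exact perpendicular distance. Nests
#' missed by the protocol may still be found opportunistically (flagged,
#' distance withheld).
#'
#' @param plots output of [generate_plots()].
#' @param config a `demog_config`.
#' @return list with `detections` (transect finds with distances plus
#'   opportunistic finds), `latent` (every simulated nest with its true
#'   distance and detection outcome) and `effort` (per plot-year-transect
#'   lengths and rounds).
#' @export
simulate_nest_survey <- function(plots, config) {
  stopifnot(inherits(config, "demog_config"))
  quality <- attr(plots, "quality")
  if (is.null(quality))
    quality <- stats::setNames(rep(1, length(unique(plots$plot_id))),
                               unique(plots$plot_id))
  tx <- transect_x(config$n_transects, config$transect_spacing)
  w <- config$half_width
  with_stage_seed(config$seed, "nests", {
    # one cell per plot-year x species x round, latent counts Poisson
    cells <- merge(plots[c("plot_id", "year")],
                   expand.grid(species = config$species$name,
                               round = seq_len(config$rounds),
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE))
    cells <- cells[order(match(cells$plot_id, plots$plot_id), cells$year,
                         match(cells$species, config$species$name),
                         cells$round), , drop = FALSE]
    dens <- config$species$nest_density[match(cells$species,
                                              config$species$name)]
    lam <- dens * quality[match(cells$plot_id, names(quality))]
    n_cell <- stats::rpois(nrow(cells), lam)
    idx <- rep(seq_len(nrow(cells)), n_cell)
    n_tot <- length(idx)
    if (n_tot > 0L) {
      px <- stats::runif(n_tot, 0, 500)
      py <- stats::runif(n_tot, 0, 500)
      nearest <- pmin(pmax(round((px - tx[1L]) /
                                   config$transect_spacing) + 1L, 1L),
                      length(tx))
      dist <- abs(px - tx[nearest])
      in_strip <- dist <= w &
        py >= (250 - config$transect_length / 2) &
        py <= (250 + config$transect_length / 2)
      g <- key_fn(dist, config$key, config$scale, config$shape)
      det <- in_strip & (stats::runif(n_tot) < g)
      opp <- !det & (stats::runif(n_tot) < config$p_opportunistic)
      latent <- data.frame(
        plot_id = cells$plot_id[idx], year = cells$year[idx],
        species = cells$species[idx], round = cells$round[idx],
        transect_id = paste0("T", nearest), x = px, y = py,
        distance_m = dist, in_strip = in_strip, detected = det,
        opportunistic = opp, stringsAsFactors = FALSE)
    } else latent <-
      data.frame(plot_id = character(0), year = integer(0),
                 species = character(0), round = integer(0),
                 transect_id = character(0), x = numeric(0), y = numeric(0),
                 distance_m = numeric(0), in_strip = logical(0),
                 detected = logical(0), opportunistic = logical(0))
    found <- latent[latent$detected | latent$opportunistic, , drop = FALSE]
    detections <- found[, c("plot_id", "year", "species", "round",
                            "transect_id", "distance_m", "opportunistic")]
    if (nrow(detections)) {
      detections$nest_id <- sprintf("N%05d", seq_len(nrow(detections)))
      detections$distance_m[detections$opportunistic] <- NA_real_
      detections$transect_id[detections$opportunistic] <- NA_character_
    } else detections$nest_id <- character(0)
    rownames(detections) <- NULL
    effort <- expand.grid(plot_id = unique(plots$plot_id),
                          year = unique(plots$year),
                          transect_id = paste0("T",
                                               seq_len(config$n_transects)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    effort$length_m <- config$transect_length
    effort$rounds <- config$rounds
    effort <- effort[order(effort$year, effort$plot_id, effort$transect_id), ]
    rownames(effort) <- NULL
    list(detections = detections, latent = latent, effort = effort)
  })
}

#' Simulate nest visit histories
#'
#' Each discovered nest survives each day independently at its
#' stage-specific daily survival rate; the stage switches from egg to
#' nestling after the configured hatch day. Visits are scheduled at the
#' configured interval from discovery (at initiation); a nest alive through
#' the full nesting period fledges, otherwise failure is recorded at the
#' first visit after death (field-style censoring of the exact death day,
#' which is kept in the nest-level truth).
#'
#' @param detections the `detections` element of [simulate_nest_survey()]
#'   (or any data.frame with `nest_id`, `plot_id`, `year`, `species`,
#'   `round`).
#' @param config a `demog_config`.
#' @return list with `visits` (one row per nest check: `nest_id`,
#'   `plot_id`, `species`, `year`, `visit_date`, `day`, `stage`, `status`,
#'   `cause`) and `nests` (nest-level truth: fate, exact death day).
#' @export
simulate_nest_histories <- function(detections, config) {
  stopifnot(inherits(config, "demog_config"))
  sp_tab <- config$species
  with_stage_seed(config$seed, "histories", {
    n <- nrow(detections)
    if (n == 0L) return(list(visits = NULL, nests = NULL))
    si <- match(detections$species, sp_tab$name)
    period <- sp_tab$period[si]
    hatch <- sp_tab$hatch_day[si]
    iv <- config$visit_interval
    # daily survival trials: day d of nest i survives with its stage's DSR
    maxp <- max(period)
    u <- matrix(stats::runif(n * maxp), nrow = maxp)
    in_egg <- row(u) <= matrix(hatch, maxp, n, byrow = TRUE)
    dsr_mat <- matrix(sp_tab$dsr_nestling[si], maxp, n, byrow = TRUE)
    dsr_mat[in_egg] <- matrix(sp_tab$dsr_egg[si], maxp, n,
                              byrow = TRUE)[in_egg]
    dead <- u >= dsr_mat & (row(u) <= matrix(period, maxp, n, byrow = TRUE))
    death_day <- rep(NA_integer_, n)
    wd <- which(dead, arr.ind = TRUE)
    if (nrow(wd)) {
      first <- tapply(wd[, 1L], wd[, 2L], min)
      death_day[as.integer(names(first))] <- as.integer(first)
    }
    fate <- ifelse(is.na(death_day), "fledged", "failed")
    cause <- rep(NA_character_, n)
    nf <- sum(fate == "failed")
    if (nf > 0L)
      cause[fate == "failed"] <- sample(names(config$cause_probs), nf,
                                        replace = TRUE,
                                        prob = config$cause_probs)
    end_day <- ifelse(is.na(death_day), period, death_day)
    nv <- ceiling(end_day / iv) + 1L     # visits incl. day 0
    vdays <- sequence(nv, from = 0L, by = iv)
    ni <- rep(seq_len(n), nv)            # nest index per visit row
    last <- cumsum(nv)
    # terminal visit: first scheduled visit >= death day, clamped so a
    # fledged nest's final check lands on the fledge day
    vdays[last] <- pmin(vdays[last], pmax(period, vdays[last - 1L] + 1L))
    status <- rep("active", length(vdays))
    status[last] <- fate
    stage <- ifelse(vdays <= hatch[ni], "egg", "nestling")
    season_day <- (detections$round - 1L) * config$round_spacing
    date0 <- as.Date(paste0(detections$year, "-05-08"))
    visits <- data.frame(
      nest_id = detections$nest_id[ni], plot_id = detections$plot_id[ni],
      species = detections$species[ni], year = detections$year[ni],
      visit_date = date0[ni] + season_day[ni] + vdays,
      day = season_day[ni] + vdays, stage = stage, status = status,
      cause = ifelse(status == "failed", cause[ni], NA_character_),
      stringsAsFactors = FALSE)
    nests <- data.frame(
      nest_id = detections$nest_id, plot_id = detections$plot_id,
      species = detections$species, year = detections$year,
      fate = fate, death_day = death_day, cause = cause,
      opportunistic = detections$opportunistic, stringsAsFactors = FALSE)
    list(visits = visits, nests = nests)
  })
}

#' Simulate dependent double-observer adult counts
#'
#' Per plot-visit-species, a latent adult count N ~ Poisson(lambda) is
#' thinned by the two observers: the primary tallies x1 ~ Binomial(N, p1)
#' and the secondary tallies only what the primary missed,
#' x2 ~ Binomial(N - x1, p2). Observers swap roles between visits. The
#' latent N is withheld to the truth table.
#'
#' @param plots output of [generate_plots()].
#' @param config a `demog_config`.
#' @return data.frame: `plot_id`, `year`, `visit`, `species`,
#'   `observer_primary`, `observer_secondary`, `x1`, `x2`, `enrolled`.
#' @export
simulate_ddo_counts <- function(plots, config) {
  stopifnot(inherits(config, "demog_config"))
  quality <- attr(plots, "quality")
  if (is.null(quality))
    quality <- stats::setNames(rep(1, length(unique(plots$plot_id))),
                               unique(plots$plot_id))
  obs <- names(config$observers)
  with_stage_seed(config$seed, "ddo", {
    grid <- expand.grid(visit = seq_len(config$rounds),
                        sp = seq_len(nrow(config$species)),
                        row = seq_len(nrow(plots)),
                        KEEP.OUT.ATTRS = FALSE)
    n <- nrow(grid)
    lambda <- config$species$adult_density[grid$sp] *
      quality[match(plots$plot_id[grid$row], names(quality))]
    o1 <- obs[(grid$visit - 1L) %% 2L + 1L]
    o2 <- obs[grid$visit %% 2L + 1L]
    N <- stats::rpois(n, lambda)
    x1 <- stats::rbinom(n, N, config$observers[o1])
    x2 <- stats::rbinom(n, N - x1, config$observers[o2])
    out <- data.frame(
      plot_id = plots$plot_id[grid$row], year = plots$year[grid$row],
      visit = grid$visit, species = config$species$name[grid$sp],
      observer_primary = o1, observer_secondary = o2,
      x1 = x1, x2 = x2, enrolled = plots$enrolled[grid$row],
      stringsAsFactors = FALSE)
    attr(out, "N_true") <- N
    rownames(out) <- NULL
    out
  })
}

#' Generate a full synthetic survey bundle with its truth table
#'
#' Runs all four generators under RNG streams derived from the master seed
#' and assembles the truth table (one row per plot-year-species with the
#' true nest density, adult density, stage-specific daily survival rates
#' and the shared plot-quality multiplier).
#'
#' @param config a `demog_config`.
#' @return list of class `demog_sim`: `plots`, `detections`, `latent`,
#'   `effort`, `visits`, `nests`, `ddo_counts`, `truth`, `config`.
#' @export
simulate_demography <- function(config) {
  stopifnot(inherits(config, "demog_config"))
  plots <- generate_plots(config)
  survey <- simulate_nest_survey(plots, config)
  hist <- simulate_nest_histories(survey$detections, config)
  ddo <- simulate_ddo_counts(plots, config)
  quality <- attr(plots, "quality")
  truth <- expand.grid(plot_id = unique(plots$plot_id),
                       year = unique(plots$year),
                       species = config$species$name,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  si <- match(truth$species, config$species$name)
  truth$quality <- quality[match(truth$plot_id, names(quality))]
  truth$nest_density <- config$species$nest_density[si] * truth$quality
  truth$adult_density <- config$species$adult_density[si] * truth$quality
  truth$dsr_egg <- config$species$dsr_egg[si]
  truth$dsr_nestling <- config$species$dsr_nestling[si]
  truth <- truth[order(truth$year, truth$plot_id, truth$species), ]
  rownames(truth) <- NULL
  attr(truth, "detection") <- list(key = config$key, scale = config$scale,
                                   shape = config$shape,
                                   observers = config$observers)
  out <- list(plots = plots, detections = survey$detections,
              latent = survey$latent, effort = survey$effort,
              visits = hist$visits, nests = hist$nests,
              ddo_counts = ddo, truth = truth, config = config)
  class(out) <- "demog_sim"
  out
}

#' @export
print.demog_sim <- function(x, ...) {
  cat("Synthetic demographic survey:",
      x$config$n_plots, "plots x", length(x$config$years), "years,",
      nrow(x$config$species), "species\n")
  cat("  nest detections:", nrow(x$detections),
      "(", sum(x$detections$opportunistic), "opportunistic )\n")
  cat("  nest visit records:",
      if (is.null(x$visits)) 0L else nrow(x$visits), "\n")
  cat("  double-observer count rows:", nrow(x$ddo_counts), "\n")
  invisible(x)
}
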