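# Umbrella pipeline: simulate (optional) -> fit-density -> fit-survival ->
# fit-abundance -> compare, with all artifacts written as CSV.

#' Default pipeline configuration
#'
#' @param seed master seed for simulation and MCMC.
#' @param simulate arguments forwarded to [sim_config()]; set `NULL` and
#'   supply `input` paths to run on existing CSVs.
#' @param input named list of CSV paths (`plots`, `nest_detections`,
#'   `effort`, `nest_visits`, `ddo_counts`) when not simulating.
#' @param truncation distance-sampling truncation (m); `NULL` uses the
#'   largest observed distance.
#' @param density_by stratum columns for the headline density estimates.
#' @param suite_keys,suite_adjustments candidate detection-function grid.
#' @param survival_formulas named list of candidate DSR formulas.
#' @param periods named vector of nesting-period lengths (days) per
#'   species, used for seasonal survival.
#' @param mcmc list with `chains`, `iterations`, `burn_in`, `thin`.
#' @return a config list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(),
                            input = NULL,
                            truncation = NULL,
                            density_by = c("year", "enrolled"),
                            suite_keys = c("halfnorm", "hazard", "uniform"),
                            suite_adjustments = list(cosine = list(2L),
                                                     poly = list(4L),
                                                     hermite = list(4L)),
                            survival_formulas = list(
                              null = y ~ 1,
                              stage = y ~ stage,
                              year = y ~ factor(year),
                              stage_year = y ~ stage + factor(year),
                              density = y ~ nest_density,
                              enroll = y ~ enrolled,
                              shrub = y ~ shrub_cover,
                              weather = y ~ temp_max + precip_mean),
                            periods = c(brewers_sparrow = 19,
                                        vesper_sparrow = 15),
                            mcmc = list(chains = 3L, iterations = 10000L,
                                        burn_in = 1000L, thin = 1L)) {
  list(seed = as.integer(seed), simulate = simulate, input = input,
       truncation = truncation, density_by = density_by,
       suite_keys = suite_keys, suite_adjustments = suite_adjustments,
       survival_formulas = survival_formulas, periods = periods,
       mcmc = mcmc)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

load_input <- function(input, name, stage) {
  path <- input[[name]]
  if (is.null(path) || !file.exists(path))
    stop("pipeline stage `", stage, "` failed: required input file `",
         name, "` not found", if (!is.null(path)) paste0(" at ", path),
         call. = FALSE)
  read_demog_csv(path)
}

#' Run the full demographic pipeline
#'
#' Executes simulate (optional), nest-density estimation with detection
#' function selection, logistic-exposure nest survival with AICc model
#' ranking, dependent double-observer abundance by MCMC, and the
#' density-dependence comparison. Every stage writes its CSV artifacts to
#' `out_dir` and a plain-text report summarizes model tables, estimates
#' and diagnostics. The run is fully determined by the config and its
#' seed; a stage failure halts with the stage name, leaving earlier
#' artifacts in place.
#'
#' @param config from [pipeline_config()].
#' @param out_dir output directory.
#' @return invisible list with all intermediate objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- character(0)
  note <- function(...) report <<- c(report, paste0(...))

  # --- data stage ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", {
      sc <- do.call(sim_config, c(config$simulate,
                                  list(seed = config$seed)))
      simulate_demography(sc)
    })
    write_survey_bundle(sim, out_dir)
    plots <- sim$plots; detections <- sim$detections
    effort <- sim$effort; visits <- sim$visits
    ddo_counts <- sim$ddo_counts
    note("simulated dataset: ", nrow(plots), " plot-years, ",
         nrow(detections), " nest detections, ",
         nrow(ddo_counts), " count rows")
  } else {
    sim <- NULL
    plots <- run_stage("load", load_input(config$input, "plots", "load"))
    detections <- load_input(config$input, "nest_detections", "fit-density")
    effort <- load_input(config$input, "effort", "fit-density")
    visits <- load_input(config$input, "nest_visits", "fit-survival")
    ddo_counts <- load_input(config$input, "ddo_counts", "fit-abundance")
  }
  rep_v <- validate_dataset(list(plots = plots,
                                 nest_detections = detections,
                                 effort = effort, nest_visits = visits,
                                 ddo_counts = ddo_counts))
  if (nrow(rep_v) > 0L)
    demog_log("WARN", nrow(rep_v), " validation issue(s); see report")
  note("validation violations: ", nrow(rep_v))

  # --- fit-density --------------------------------------------------
  dens <- run_stage("fit-density", {
    res <- list()
    for (sp in unique(detections$species)) {
      det_sp <- detections[detections$species == sp &
                             !detections$opportunistic, , drop = FALSE]
      if (nrow(det_sp) < 2L) {
        demog_log("WARN", "species ", sp, " has < 2 transect detections")
        next
      }
      w <- if (is.null(config$truncation)) max(det_sp$distance_m)
           else config$truncation
      det_sp <- truncate_distances(det_sp, w)
      det_sp <- merge(det_sp, plots, by = c("plot_id", "year"))
      suite <- fit_detection_suite(det_sp, w = w,
                                   keys = config$suite_keys,
                                   adjust_orders = config$suite_adjustments)
      tab <- rank_models(suite)
      top <- suite[[attr(tab, "top")]]
      eff_sp <- merge(effort, unique(plots[c("plot_id", "year",
                                             "enrolled")]),
                      by = c("plot_id", "year"))
      strata <- estimate_density(top, det_sp, eff_sp,
                                 by = config$density_by)
      plot_est <- tryCatch(
        estimate_density(top, det_sp, eff_sp, by = c("plot_id")),
        error = function(e) NULL)
      res[[sp]] <- list(suite = suite, table = tab, top = top,
                        strata = strata, plot_est = plot_est)
    }
    if (length(res) == 0L) stop("no species with enough detections")
    res
  })
  mt <- do.call(rbind, lapply(names(dens), function(sp)
    cbind(species = sp, as.data.frame(dens[[sp]]$table))))
  write_demog_csv(mt, file.path(out_dir, "detection_model_table.csv"))
  de <- do.call(rbind, lapply(names(dens), function(sp)
    cbind(species = sp, as.data.frame(dens[[sp]]$strata))))
  write_demog_csv(de, file.path(out_dir, "density_estimates.csv"))
  pe <- do.call(rbind, lapply(names(dens), function(sp) {
    x <- dens[[sp]]$plot_est
    if (is.null(x)) NULL else cbind(species = sp, as.data.frame(x))
  }))
  if (!is.null(pe))
    write_demog_csv(pe, file.path(out_dir, "plot_density_estimates.csv"))
  note("top detection models: ",
       paste(vapply(names(dens), function(sp)
         paste0(sp, "=", attr(dens[[sp]]$table, "top")), character(1)),
         collapse = "; "))

  # --- fit-survival -------------------------------------------------
  surv <- run_stage("fit-survival", {
    intervals <- build_exposure_intervals(visits)
    intervals <- merge(intervals, plots, by = c("plot_id", "year"),
                       all.x = TRUE)
    if (!is.null(pe)) {
      nd <- pe[, c("species", "plot_id", "D")]
      names(nd)[3] <- "nest_density"
      intervals <- merge(intervals, nd, by = c("species", "plot_id"),
                         all.x = TRUE)
    } else intervals$nest_density <- NA_real_
    res <- list()
    for (sp in unique(intervals$species)) {
      iv <- intervals[intervals$species == sp, , drop = FALSE]
      forms <- config$survival_formulas
      vars <- unique(unlist(lapply(forms, all.vars)))
      vars <- setdiff(intersect(vars, names(iv)), "y")
      cc <- stats::complete.cases(iv[vars])
      if (sum(!cc) > 0)
        demog_log("INFO", sum(!cc), " intervals dropped for missing ",
                  "covariates (", sp, ")")
      iv <- iv[cc, , drop = FALSE]
      keep <- vapply(forms, function(f)
        all(all.vars(f) %in% c("y", names(iv))), logical(1))
      fits <- lapply(forms[keep], function(f)
        tryCatch(fit_dsr(iv, f, random_plot = TRUE),
                 error = function(e) NULL))
      fits <- Filter(Negate(is.null), fits)
      if (length(fits) == 0L) stop("no survival model converged for ", sp)
      tab <- rank_models(fits)
      top <- fits[[attr(tab, "top")]]
      dsr_hat <- mean(predict(top, iv))
      period <- config$periods[[sp]]
      if (is.null(period)) period <- 19
      res[[sp]] <- list(table = tab, top = top, intervals = iv,
                        dsr = dsr_hat,
                        seasonal = seasonal_survival(dsr_hat, period))
    }
    res
  })
  st <- do.call(rbind, lapply(names(surv), function(sp)
    cbind(species = sp, as.data.frame(surv[[sp]]$table))))
  write_demog_csv(st, file.path(out_dir, "dsr_model_table.csv"))
  sp_pred <- do.call(rbind, lapply(names(surv), function(sp)
    data.frame(species = sp, dsr = surv[[sp]]$dsr,
               seasonal_survival = surv[[sp]]$seasonal,
               top_model = attr(surv[[sp]]$table, "top"))))
  write_demog_csv(sp_pred, file.path(out_dir, "dsr_predictions.csv"))
  note("daily survival: ",
       paste(sprintf("%s DSR=%.3f seasonal=%.3f", sp_pred$species,
                     sp_pred$dsr, sp_pred$seasonal), collapse = "; "))

  # --- fit-abundance ------------------------------------------------
  mdam <- run_stage("fit-abundance", {
    mc <- config$mcmc
    fit_mdam(ddo_counts, chains = mc$chains, iterations = mc$iterations,
             burn_in = mc$burn_in,
             thin = if (is.null(mc$thin)) 1L else mc$thin,
             seed = config$seed)
  })
  pairs_est <- pair_density(mdam)
  diag_tab <- mdam_diagnostics(mdam)
  write_demog_csv(as.data.frame(pairs_est),
                  file.path(out_dir, "abundance_estimates.csv"))
  write_demog_csv(diag_tab, file.path(out_dir, "mcmc_diagnostics.csv"))
  note("abundance: ", sum(diag_tab$flag), " parameter(s) with Rhat > 1.1")

  # --- compare ------------------------------------------------------
  dd <- run_stage("compare", {
    if (is.null(pe)) stop("no plot-level nest density estimates to compare")
    nd <- pe
    names(nd)[names(nd) == "D"] <- "D"
    joined <- join_densities(nd, pairs_est, by = c("plot_id", "species"))
    list(joined = joined, result = density_dependence(joined),
         ratios = density_ratio(joined))
  })
  write_demog_csv(dd$result, file.path(out_dir, "density_dependence.csv"))
  note("density dependence: ",
       paste(sprintf("%s r=%.3f p=%.3f n=%d", dd$result$species,
                     dd$result$r, dd$result$p, dd$result$n),
             collapse = "; "))

  writeLines(c("nestdemog pipeline report",
               paste0("seed: ", config$seed), report),
             file.path(out_dir, "report.txt"))
  invisible(list(sim = sim, density = dens, survival = surv, mdam = mdam,
                 pairs = pairs_est, diagnostics = diag_tab,
                 density_dependence = dd, report = report))
}
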