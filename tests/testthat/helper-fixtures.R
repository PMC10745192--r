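# Shared fixtures, built in code at load time.

# small single-year world used by several estimator tests
tiny_config <- function(seed = 42L, ...) {
  sim_config(n_plots = 12L, years = 2016L, seed = seed, plot_cv = 0.3, ...)
}

# one-species world with controllable density/detection, for oracles
one_species_config <- function(nest_density = 6, adult_density = 24,
                               dsr = 0.9, period = 19L, n_plots = 20L,
                               seed = 1L, plot_cv = 0, rounds = 1L, ...) {
  sim_config(
    n_plots = n_plots, years = 2016L, plot_cv = plot_cv, rounds = rounds,
    species = data.frame(name = "sp", nest_density = nest_density,
                         dsr_egg = dsr, dsr_nestling = dsr,
                         period = period, adult_density = adult_density),
    seed = seed, ...)
}

# nest-level fate table with the given fledged/failed/cause composition
make_fate_table <- function(n_fledged, n_failed, causes = NULL) {
  n <- n_fledged + n_failed
  fate <- c(rep("fledged", n_fledged), rep("failed", n_failed))
  cause <- rep(NA_character_, n)
  if (!is.null(causes))
    cause[fate == "failed"] <- causes
  data.frame(nest_id = sprintf("N%04d", seq_len(n)),
             plot_id = "P001", species = "sp", year = 2016L,
             fate = fate, cause = cause, stringsAsFactors = FALSE)
}

# exposure intervals simulated directly from the logistic-exposure model
simulate_intervals <- function(n, beta0, beta_stage = 0, sigma_plot = 0,
                               n_plots = 25L, t_range = 1:4, seed = 1L) {
  set.seed(seed)
  plot <- sample.int(n_plots, n, replace = TRUE)
  u <- stats::rnorm(n_plots, 0, sigma_plot)
  stage <- sample(c(0, 1), n, replace = TRUE)
  t_i <- sample(t_range, n, replace = TRUE)
  theta <- stats::plogis(beta0 + beta_stage * stage + u[plot])
  y <- as.integer(stats::runif(n) < theta^t_i)
  data.frame(plot_id = sprintf("P%03d", plot), t = t_i,
             stage = ifelse(stage == 1, "nestling", "egg"), y = y,
             stage_num = stage)
}
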