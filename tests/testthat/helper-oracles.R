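# Brute-force oracles and small builders shared across tests. These stay
# deliberately naive (day-by-day loops) and independent of the package's
# rle/vector implementations.

# Day-by-day count of values inside a bin ([lower, upper] for the lowest bin,
# (lower, upper] otherwise). NA days never count.
oracle_total_days <- function(values, lower, upper, closed_lower) {
  n <- 0L
  for (v in values) {
    if (is.na(v)) next
    inside <- if (closed_lower) v >= lower && v <= upper else v > lower && v <= upper
    if (inside) n <- n + 1L
  }
  n
}

# Longest run of consecutive in-bin days; an NA breaks the run.
oracle_max_consecutive <- function(values, lower, upper, closed_lower) {
  best <- 0L
  run <- 0L
  for (v in values) {
    inside <- !is.na(v) &&
      (if (closed_lower) v >= lower && v <= upper else v > lower && v <= upper)
    run <- if (inside) run + 1L else 0L
    if (run > best) best <- run
  }
  best
}

# A one-station daily series over given dates.
make_series <- function(values, start = "2018-05-01", station = "S1", basin = "Terrebonne") {
  dates <- as.Date(start) + seq_along(values) - 1L
  data.frame(station_id = station, basin_id = basin, date = dates,
             salinity = values, stringsAsFactors = FALSE)
}

# A constant-salinity generator config: one basin, one station, one year.
constant_config <- function(level, year = 2018, seed = 1L, events = list(),
                            event_noise_sd = 0) {
  salinity_gen_config(basins = "Terrebonne", stations_per_basin = 1,
                      years = year, baseline_mean = level,
                      seasonal_amplitude = 0, ar1_coefficient = 0,
                      noise_sd = 0, event_noise_sd = event_noise_sd,
                      events = events, seed = seed)
}

# Minimal hand-built fit object with point-mass (or supplied) draws, for
# exercising prediction/sweep logic with known posteriors.
fake_fit <- function(intercept = 100, gamma = -1, n_draws = 200,
                     basin = "Barataria", covariate = "c.d_su0.1",
                     lambda = NULL, sigma2 = 1, jitter = 0) {
  draws <- cbind(stats::rnorm(n_draws, intercept, jitter),
                 stats::rnorm(n_draws, gamma, jitter),
                 rep(sigma2, n_draws), rep(intercept, n_draws))
  colnames(draws) <- c(paste0("alpha.", basin), paste0("gamma.", covariate),
                       "sigma2", "alpha0")
  if (!is.null(lambda)) {
    lm <- sapply(lambda, function(l) rep(l, n_draws))
    colnames(lm) <- paste0("lambda.", names(lambda))
    draws <- cbind(draws, lm)
  }
  levels <- if (is.null(lambda)) "basin" else "basin-year"
  structure(list(spec = model_spec(levels, covariate), draws = draws,
                 y = numeric(0)), class = "oyster_fit")
}

# Reduced chain geometry for simulation studies in tests.
test_mcmc <- function(n_chains = 2, n_iter = 1500, burn_in = 500, thin = 1) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in, thin = thin)
}
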