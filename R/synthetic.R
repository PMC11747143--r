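#' Basin registry for coastal Louisiana
#'
#' The six estuarine basins used in the analysis, split east/west. Sabine and
#' Outside Waters are excluded by design. Basin-level mean salinities follow
#' the published monitoring ranges for 2016-2020.
#'
#' @return Data frame with `basin_id`, `region`, `baseline_mean` (psu).
#' @export
basin_registry <- function() {
  data.frame(
    basin_id = c("Pontchartrain", "Barataria", "Terrebonne",
                 "Calcasieu", "Vermilion-Teche", "Atchafalaya"),
    region = c("east", "east", "east", "west", "west", "west"),
    baseline_mean = c(9.7, 9.1, 11.7, 12.9, 6.2, 9.4),
    stringsAsFactors = FALSE
  )
}

#' Map a basin to its region
#' @param basin_id Basin name, as in [basin_registry()].
#' @return `"east"` or `"west"`.
#' @export
region_split <- function(basin_id) {
  reg <- basin_registry()
  i <- match(basin_id, reg$basin_id)
  if (any(is.na(i))) {
    stop("unknown basin (not in the study registry): ",
         paste(basin_id[is.na(i)], collapse = ", "))
  }
  reg$region[i]
}

#' Describe an injected low-salinity event
#'
#' Events overwrite the baseline salinity process with `target_level` (plus
#' small observation noise) for `duration_days` consecutive days, emulating a
#' freshwater pulse. Used to plant known exposure runs.
#'
#' @param basin Basin id the event applies to.
#' @param stations Station ids, or `"all"` for every station in the basin.
#' @param start_date Event start (`Date` or ISO-8601 string).
#' @param duration_days Length in days (>= 1).
#' @param target_level Salinity during the event (psu, >= 0).
#' @return An object of class `low_salinity_event`.
#' @export
low_salinity_event <- function(basin, stations = "all", start_date, duration_days,
                               target_level) {
  stopifnot(duration_days >= 1, target_level >= 0)
  structure(list(basin = basin, stations = stations,
                 start_date = as.Date(start_date),
                 duration_days = as.integer(duration_days),
                 target_level = target_level),
            class = "low_salinity_event")
}

#' Configuration for the daily salinity generator
#'
#' The generated process is a seasonal sinusoid (minimum in mid-June, when
#' river flood pulses depress estuarine salinity) plus AR(1) Gaussian noise,
#' clamped at zero, with optional injected low-salinity events.
#'
#' @param basins Basin ids; defaults to the full study registry.
#' @param stations_per_basin Stations per basin.
#' @param years Calendar years to generate (daily, Jan 1 - Dec 31).
#' @param baseline_mean Named per-basin mean salinity (psu); defaults to the
#'   registry values.
#' @param seasonal_amplitude Amplitude of the seasonal cycle (psu).
#' @param ar1_coefficient AR(1) coefficient, |phi| < 1.
#' @param noise_sd Innovation SD of the AR(1) noise (psu, >= 0).
#' @param event_noise_sd SD of the observation noise added on event days.
#' @param events List of [low_salinity_event()] objects.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `salinity_gen_config`.
#' @export
salinity_gen_config <- function(basins = basin_registry()$basin_id,
                                stations_per_basin = 6,
                                years = 2016:2020,
                                baseline_mean = NULL,
                                seasonal_amplitude = 3,
                                ar1_coefficient = 0.8,
                                noise_sd = 1.8,
                                event_noise_sd = 0.05,
                                events = list(),
                                seed = 1L) {
  if (is.null(baseline_mean)) {
    reg <- basin_registry()
    baseline_mean <- stats::setNames(reg$baseline_mean, reg$basin_id)[basins]
    if (any(is.na(baseline_mean))) {
      stop("baseline_mean must be supplied for basins outside the registry")
    }
  }
  if (length(baseline_mean) == 1) {
    baseline_mean <- stats::setNames(rep(baseline_mean, length(basins)), basins)
  }
  stopifnot(length(baseline_mean) == length(basins),
            abs(ar1_coefficient) < 1, noise_sd >= 0, event_noise_sd >= 0,
            length(years) >= 1)
  names(baseline_mean) <- basins
  structure(list(basins = basins, stations_per_basin = as.integer(stations_per_basin),
                 years = as.integer(years), baseline_mean = baseline_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
                 event_noise_sd = event_noise_sd, events = events,
                 seed = as.integer(seed)),
            class = "salinity_gen_config")
}

# station ids are "<basin>-S<k>"
.station_ids <- function(config, basin) {
  sprintf("%s-S%d", basin, seq_len(config$stations_per_basin))
}

#' Generate daily salinity series
#'
#' One series per station covering every day of the configured years:
#' baseline + seasonal sinusoid (minimum June 15) + AR(1) noise, clamped at 0.
#' Event days are overwritten with the event's target level plus small noise.
#' Overlapping events on the same station-day are rejected.
#'
#' @param config A [salinity_gen_config()].
#' @return Long data frame: `station_id`, `basin_id`, `date`, `salinity`.
#' @export
generate_salinity <- function(config) {
  stopifnot(inherits(config, "salinity_gen_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- -config$seasonal_amplitude * cos(2 * pi * (doy - 166) / 365)
  nd <- length(dates)
  out <- vector("list", length(config$basins) * config$stations_per_basin)
  idx <- 0L
  for (basin in config$basins) {
    base <- config$baseline_mean[[basin]]
    for (st in .station_ids(config, basin)) {
      # AR(1) started from its stationary distribution
      eps <- stats::rnorm(nd, 0, config$noise_sd)
      x <- numeric(nd)
      sd0 <- if (config$noise_sd > 0) config$noise_sd / sqrt(1 - config$ar1_coefficient^2) else 0
      x[1] <- stats::rnorm(1, 0, sd0)
      for (t in seq_len(nd)[-1]) x[t] <- config$ar1_coefficient * x[t - 1] + eps[t]
      sal <- pmax(0, base + seasonal + x)
      out[[idx <- idx + 1L]] <- data.frame(
        station_id = st, basin_id = basin, date = dates, salinity = sal,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- .apply_events(out, config)
  rownames(out) <- NULL
  out
}

.apply_events <- function(salinity, config) {
  if (!length(config$events)) return(salinity)
  touched <- character(0)  # "station|date" keys already overwritten
  for (ev in config$events) {
    stopifnot(inherits(ev, "low_salinity_event"))
    stations <- if (identical(ev$stations, "all")) .station_ids(config, ev$basin) else ev$stations
    ev_dates <- ev$start_date + 0:(ev$duration_days - 1L)
    keys <- as.vector(outer(stations, as.character(ev_dates), paste, sep = "|"))
    clash <- intersect(keys, touched)
    if (length(clash)) {
      stop("overlapping low-salinity events on station-dates: ",
           paste(utils::head(clash, 3), collapse = ", "))
    }
    touched <- c(touched, keys)
    sel <- salinity$station_id %in% stations & salinity$date %in% ev_dates
    salinity$salinity[sel] <- pmax(0, ev$target_level +
      stats::rnorm(sum(sel), 0, config$event_noise_sd))
  }
  salinity
}

#' Ground-truth parameters for the abundance model
#'
#' The generating model is the hierarchical normal model: abundance
#' A ~ Normal(beta_station + lambda_year + sum(gamma * S), sigma^2) with
#' station intercepts beta ~ Normal(alpha_basin, sigma_station^2). Negative
#' draws are retained (the likelihood is an unbounded normal).
#'
#' @param alpha Named vector of basin intercepts.
#' @param sigma_station SD of station intercepts around their basin mean.
#' @param lambda Named vector of year effects (names are years).
#' @param gamma Named vector of covariate slopes; names must be exposure
#'   column names (see [exposure_column_names()]).
#' @param sigma Residual SD at the reef scale.
#' @return An object of class `model_truth`.
#' @export
model_truth <- function(alpha, sigma_station = 0, lambda = NULL, gamma = numeric(0),
                        sigma = 1) {
  stopifnot(sigma >= 0, sigma_station >= 0)
  if (length(gamma) && is.null(names(gamma))) stop("gamma must be named by covariate column")
  structure(list(alpha = alpha, sigma_station = sigma_station,
                 lambda = lambda, gamma = gamma, sigma = sigma),
            class = "model_truth")
}

#' Draw abundance from the generating model
#'
#' One abundance value per station-year row of the exposure table, emitted as
#' dredge-style records (one record per sampling month in the season, all
#' carrying the station-year draw) so the collation stage can be exercised.
#'
#' @param truth A [model_truth()].
#' @param exposure Exposure table from [build_exposure_table()].
#' @param season `"fall"` (records dated Sep 15 / Oct 15) or `"winter"`
#'   (Nov 15 / Dec 15).
#' @param stage `"spat"` or `"adult"` label for the records.
#' @param seed Integer seed.
#' @param records If `FALSE`, return one row per station-year (`abundance`
#'   column) instead of monthly records.
#' @return Data frame of records (`station_id`, `basin_id`, `date`, `stage`,
#'   `count`) or the per-station-year table.
#' @export
generate_abundance <- function(truth, exposure, season = "fall", stage = "adult",
                               seed = 1L, records = TRUE) {
  stopifnot(inherits(truth, "model_truth"))
  miss <- setdiff(names(truth$gamma), names(exposure))
  if (length(miss)) stop("exposure table lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  set.seed(seed)
  stations <- unique(exposure[, c("station_id", "basin_id")])
  ai <- truth$alpha[stations$basin_id]
  if (any(is.na(ai))) stop("truth$alpha lacks basin(s): ",
                           paste(unique(stations$basin_id[is.na(ai)]), collapse = ", "))
  beta <- stats::rnorm(nrow(stations), ai, truth$sigma_station)
  names(beta) <- stations$station_id
  lam <- rep(0, nrow(exposure))
  if (!is.null(truth$lambda)) {
    lam <- truth$lambda[as.character(exposure$year)]
    if (any(is.na(lam))) stop("truth$lambda lacks year(s)")
  }
  lin <- beta[exposure$station_id] + lam
  if (length(truth$gamma)) {
    lin <- lin + as.matrix(exposure[, names(truth$gamma), drop = FALSE]) %*% truth$gamma
  }
  a <- stats::rnorm(nrow(exposure), as.numeric(lin), truth$sigma)
  tab <- data.frame(station_id = exposure$station_id, basin_id = exposure$basin_id,
                    year = exposure$year, season = season, stage = stage,
                    abundance = a, stringsAsFactors = FALSE)
  if (!records) return(tab)
  months <- if (season == "fall") c("09-15", "10-15") else c("11-15", "12-15")
  recs <- do.call(rbind, lapply(months, function(m) {
    data.frame(station_id = tab$station_id, basin_id = tab$basin_id,
               date = as.Date(sprintf("%d-%s", tab$year, m)),
               stage = stage, count = tab$abundance, stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}

#' Canned synthetic scenarios
#'
#' Small, fully-specified datasets with stored truth, for regression tests
#' and worked examples:
#' \describe{
#'   \item{`"null"`}{East basins, all slopes zero: abundance unrelated to
#'     salinity exposure.}
#'   \item{`"negative-slope-east"`}{Slope -0.6 on continuous summer days
#'     below 1 psu (`c.d_su0.1`), residual SD 5.}
#'   \item{`"rf-step"`}{Step response: abundance drops by 30 once continuous
#'     summer days below 1 exceed 40.}
#' }
#' Event durations are spread uniformly over 0-90 days so the low-salinity
#' covariates span the summer window.
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @param stations_per_basin Stations per basin (default 6).
#' @return List with `salinity`, `exposure`, `abundance` (per station-year),
#'   `records` (dredge-style), and `truth`.
#' @export
make_fixture <- function(scenario = c("null", "negative-slope-east", "rf-step"),
                         seed = 1L, stations_per_basin = 6) {
  scenario <- match.arg(scenario)
  basins <- c("Pontchartrain", "Barataria", "Terrebonne")
  years <- 2016:2020
  # spread of event durations -> spread of low-salinity exposure covariates
  max_dur <- 90L
  set.seed(seed)
  events <- list()
  cfg0 <- salinity_gen_config(basins = basins, stations_per_basin = stations_per_basin,
                              years = years, seed = seed)
  for (basin in basins) {
    for (st in .station_ids(cfg0, basin)) {
      for (y in years) {
        dur <- sample.int(max_dur + 1L, 1L) - 1L  # uniform 0..max_dur
        if (dur > 0) {
          start <- as.Date(sprintf("%d-05-01", y)) + sample.int(123 - dur, 1L) - 1L
          events[[length(events) + 1L]] <-
            low_salinity_event(basin, st, start, dur, target_level = 0.5)
        }
      }
    }
  }
  cfg <- salinity_gen_config(basins = basins, stations_per_basin = stations_per_basin,
                             years = years, events = events, seed = seed + 1L)
  salinity <- generate_salinity(cfg)
  exposure <- build_exposure_table(salinity, years = years)
  alpha <- c(Pontchartrain = 42, Barataria = 48, Terrebonne = 45)
  lambda <- stats::setNames(c(-2, 1, 0, 2, -1), years)
  if (scenario == "rf-step") {
    set.seed(seed + 2L)
    x <- exposure$c.d_su0.1
    a <- 50 - 30 * (x > 40) + stats::rnorm(nrow(exposure), 0, 2)
    truth <- list(kind = "step", covariate = "c.d_su0.1", step_at = 40,
                  base = 50, drop = 30, sigma = 2)
    abundance <- data.frame(station_id = exposure$station_id,
                            basin_id = exposure$basin_id, year = exposure$year,
                            season = "fall", stage = "spat", abundance = a,
                            stringsAsFactors = FALSE)
    months <- c("09-15", "10-15")
    records <- do.call(rbind, lapply(months, function(m) {
      data.frame(station_id = abundance$station_id, basin_id = abundance$basin_id,
                 date = as.Date(sprintf("%d-%s", abundance$year, m)),
                 stage = "spat", count = abundance$abundance, stringsAsFactors = FALSE)
    }))
    return(list(salinity = salinity, exposure = exposure, abundance = abundance,
                records = records, truth = truth))
  }
  gamma <- if (scenario == "negative-slope-east") c(c.d_su0.1 = -0.6) else
    stats::setNames(rep(0, 10), exposure_column_names("summer"))
  truth <- model_truth(alpha = alpha, sigma_station = 2, lambda = lambda,
                       gamma = gamma, sigma = 5)
  abundance <- generate_abundance(truth, exposure, season = "fall", stage = "spat",
                                  seed = seed + 2L, records = FALSE)
  records <- generate_abundance(truth, exposure, season = "fall", stage = "spat",
                                seed = seed + 2L, records = TRUE)
  list(salinity = salinity, exposure = exposure, abundance = abundance,
       records = records, truth = truth)
}
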