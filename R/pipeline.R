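# Table IO: plain CSV with schema validation and ISO-8601 dates. Dates are
# accepted only as YYYY-MM-DD; anything else is reported with its line number.

.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
}

.parse_iso_dates <- function(x, what) {
  bad <- which(!grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x)))
  if (length(bad)) {
    stop(what, ": non-ISO-8601 date(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected YYYY-MM-DD, got e.g. '", x[bad[1]], "')")
  }
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop(what, ": unparseable date at row(s) ",
         paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  }
  d
}

#' Read and write the pipeline's tables
#'
#' Round-trip stable CSV IO for the salinity, dredge/abundance and exposure
#' tables, with named-column errors and strict ISO-8601 date parsing.
#'
#' @param path File path.
#' @param x Table to write.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_salinity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("station_id", "basin_id", "date", "salinity"), "salinity CSV")
  df$date <- .parse_iso_dates(df$date, "salinity CSV")
  if (any(df$salinity < 0, na.rm = TRUE)) stop("salinity CSV: negative salinity")
  df
}

#' @rdname table_io
#' @export
write_salinity_csv <- function(x, path) {
  x$date <- format(as.Date(x$date), "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dredge_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("station_id", "basin_id", "date", "count"), "dredge CSV")
  if (!any(c("stage", "shell_height_class_mm") %in% names(df))) {
    stop("dredge CSV is missing required column(s): stage or shell_height_class_mm")
  }
  df$date <- .parse_iso_dates(df$date, "dredge CSV")
  if (any(df$count < 0)) {
    # real dredge counts are non-negative; synthetic records drawn from the
    # unbounded-normal abundance model may dip below zero
    warning("dredge CSV: ", sum(df$count < 0), " negative count(s), e.g. row ",
            which(df$count < 0)[1])
  }
  df
}

#' @rdname table_io
#' @export
write_dredge_csv <- function(x, path) {
  x$date <- format(as.Date(x$date), "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, c("station_id", "basin_id", "year"), "exposure CSV")
  df
}

#' @rdname table_io
#' @export
write_exposure_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Persist posterior draws with a metadata sidecar
#'
#' Draws go to CSV (one column per parameter, one row per retained
#' iteration); chain geometry, seed and model spec go to a plain-text
#' key-value sidecar at `<path>.meta`.
#'
#' @param fit An `oyster_fit`.
#' @param path CSV path.
#' @export
write_draws_csv <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  meta <- c(
    paste0("levels: ", fit$spec$levels),
    paste0("covariates: ", paste(fit$spec$covariates, collapse = ",")),
    paste0("quadratic: ", fit$spec$quadratic),
    paste0("n_chains: ", fit$mcmc$n_chains),
    paste0("n_iter: ", fit$mcmc$n_iter),
    paste0("burn_in: ", fit$mcmc$burn_in),
    paste0("thin: ", fit$mcmc$thin),
    paste0("seed: ", fit$seed),
    paste0("dic: ", fit$dic),
    paste0("ppl: ", fit$ppl),
    paste0("converged: ", fit$converged))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

# Deterministic fan-out of the master seed to a named stage: a small
# polynomial hash of the stage name folded into the seed, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' @param scenario Synthetic scenario name for [make_fixture()], or `NULL`
#'   when `salinity_path`/`dredge_path` are given.
#' @param salinity_path,dredge_path CSV inputs (alternative to a scenario).
#' @param seasons,stages Cells to analyze.
#' @param candidate_levels Hierarchy structures to compare before the finals.
#' @param mcmc,priors,rf Stage settings.
#' @param sweep_window Day range for the threshold sweep.
#' @param seed Master seed, fanned out per stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "negative-slope-east",
                            salinity_path = NULL, dredge_path = NULL,
                            seasons = "fall", stages = "spat",
                            candidate_levels = c("station-basin-year", "station-basin"),
                            mcmc = mcmc_settings(n_chains = 2, n_iter = 3000,
                                                 burn_in = 1000, thin = 2),
                            priors = prior_spec(),
                            rf = rf_settings(),
                            sweep_window = 123,
                            seed = 1L) {
  if (is.null(scenario) && (is.null(salinity_path) || is.null(dredge_path))) {
    stop("either a synthetic scenario or both input paths are required")
  }
  structure(list(scenario = scenario, salinity_path = salinity_path,
                 dredge_path = dredge_path, seasons = seasons, stages = stages,
                 candidate_levels = candidate_levels, mcmc = mcmc,
                 priors = priors, rf = rf, sweep_window = sweep_window,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Direction of the smoothed partial-dependence curve at its changepoint:
# +1 when the response rises past the changepoint (safe-bin reading, use the
# subtract-from-window rule), -1 when it falls (decline within the low bin
# itself, use the rule's direct mode).
.changepoint_direction <- function(curve, day) {
  y <- curve$yhat
  n <- length(y)
  sm <- vapply(seq_len(n), function(i) mean(y[max(1, i - 1):min(n, i + 1)]), numeric(1))
  i <- match(day, curve$day)
  sign(sm[min(n, i + 1)] - sm[max(1, i - 1)])
}

#' Run the two-branch threshold pipeline end to end
#'
#' Simulate (or read) -> exposure covariates -> seasonal collation -> per
#' cell: Bayesian hierarchy comparison, single-covariate finals with the
#' co-best DIC rule, critical-abundance sweeps per basin for
#' negative-classified finals; and in parallel the random-forest branch:
#' retention by OOB r-squared, importance ranking, interpretation-variable
#' selection, partial dependence, changepoint detection and the
#' subtract-from-window rule. Every decision is logged.
#'
#' @param config A [pipeline_config()].
#' @return An `oyster_report`: `thresholds` (both methods), `model_summary`,
#'   `comparisons`, `rf_summary`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  if (!is.null(config$scenario)) {
    fx <- make_fixture(config$scenario, seed = stage_seed(config$seed, "simulate"))
    salinity <- fx$salinity
    records <- fx$records
    say("simulate: scenario '", config$scenario, "', ",
        length(unique(salinity$station_id)), " stations")
  } else {
    salinity <- read_salinity_csv(config$salinity_path)
    records <- read_dredge_csv(config$dredge_path)
    say("inputs: read ", nrow(salinity), " salinity rows, ",
        nrow(records), " dredge records")
  }
  exposure <- build_exposure_table(salinity)
  say("exposure: ", nrow(exposure), " station-years, ",
      ncol(exposure) - 3, " covariate columns")
  covariate_cols <- setdiff(names(exposure), c("station_id", "basin_id", "year"))

  thresholds <- list()
  summaries <- list()
  comparisons <- list()
  rf_rows <- list()

  for (season in config$seasons) {
    abund_all <- collate_season(records, season)
    for (stage in config$stages) {
      abund_stage <- abund_all[abund_all$stage == stage, , drop = FALSE]
      if (nrow(abund_stage) == 0) {
        say("cell ", season, "/", stage, ": no abundance rows, skipped")
        next
      }
      regions <- unique(region_split(abund_stage$basin_id))
      for (region in regions) {
        basins <- basin_registry()$basin_id[basin_registry()$region == region]
        ab <- abund_stage[abund_stage$basin_id %in% basins, , drop = FALSE]
        if (nrow(ab) == 0) next
        cell <- paste(region, season, stage, sep = "/")
        cell_seed <- stage_seed(config$seed, paste0("fit-", cell))

        # ---- Bayesian branch ----
        total_cols <- grep("^s_d_", covariate_cols, value = TRUE)
        scale_fits <- lapply(config$candidate_levels, function(lv) {
          gibbs_fit(ab, exposure, model_spec(lv, total_cols),
                    config$priors, config$mcmc, seed = cell_seed)
        })
        cmp <- compare_models(scale_fits)
        comparisons[[paste0(cell, ":scales")]] <- cmp
        best_levels <- cmp$levels[1]
        say(cell, ": hierarchy comparison by ", cmp$metric[1], " -> ", best_levels,
            " (co-best: ", paste(cmp$model[cmp$co_best], collapse = "; "), ")")

        finals <- lapply(covariate_cols, function(cv) {
          gibbs_fit(ab, exposure, model_spec(best_levels, cv),
                    config$priors, config$mcmc, seed = cell_seed)
        })
        names(finals) <- covariate_cols
        fcmp <- compare_models(finals, labels = covariate_cols)
        comparisons[[paste0(cell, ":finals")]] <- fcmp
        co_best <- fcmp$model[fcmp$co_best]
        say(cell, ": co-best single-covariate models: ",
            paste(co_best, collapse = ", "))

        for (cv in co_best) {
          fit <- finals[[cv]]
          cls <- classify_effect(fit, cv)
          p <- parse_exposure_column(cv)
          summaries[[paste0(cell, ":", cv)]] <- data.frame(
            region = region, season = season, stage = stage,
            levels = best_levels, covariate = cv,
            salinity = .covariate_salinity_label(cv, direct = TRUE),
            count = if (p$kind == "total") "T" else "M",
            median_sign = ifelse(stats::median(fit$draws[, paste0("gamma.", cv)]) < 0, "-", "+"),
            probability = switch(cls, "negative-95" = , "positive-95" = "95",
                                 "negative-50" = , "positive-50" = "50", "-"),
            converged = fit$converged,
            dic = fit$dic, stringsAsFactors = FALSE)
          if (!fit$converged) say(cell, ": WARNING non-converged fit for ", cv)
          if (cls %in% c("negative-95", "negative-50")) {
            for (basin in intersect(basins, unique(ab$basin_id))) {
              crit <- critical_abundance(ab, basin, season, stage)
              th <- sweep_threshold(fit, basin, crit, config$sweep_window)
              th$season <- season; th$stage <- stage
              thresholds[[length(thresholds) + 1L]] <- th
              say(cell, ": bayes sweep ", basin, " (", cv, ", ", cls, ") -> ",
                  ifelse(is.na(th$days), "no crossing", paste0(th$days, " days")))
            }
          } else {
            say(cell, ": ", cv, " classified ", cls, ", no sweep")
          }
        }

        # ---- Random-forest branch ----
        d <- merge(ab, exposure, by = c("station_id", "basin_id", "year"))
        rfset <- config$rf
        rfset$seed <- stage_seed(config$seed, paste0("rf-", cell))
        rf <- fit_rf(d[, covariate_cols], d$abundance, rfset)
        rf_rows[[cell]] <- data.frame(region = region, season = season,
                                      stage = stage, oob_r2 = rf$oob_r2,
                                      retained = rf$retained,
                                      stringsAsFactors = FALSE)
        if (!rf$retained) {
          say(cell, ": rf not retained (oob r2 = ", round(rf$oob_r2, 3), ")")
          next
        }
        rank <- variable_importance(rf)
        var <- select_interpretation_variable(rank, rfset$cluster_tolerance)
        pdp <- partial_dependence(rf, var)
        cp <- detect_changepoint(pdp, floor = rfset$changepoint_floor)
        if (is.na(cp)) {
          say(cell, ": rf pdp flat for ", var, ", no changepoint")
          next
        }
        pv <- parse_exposure_column(var)
        direct <- .changepoint_direction(pdp, cp) < 0
        th <- rf_interpretation_rule(pv$window, cp,
                                     sprintf("%g-%g", pv$lower, pv$upper),
                                     pv$kind, direct = direct)
        th$region <- region; th$season <- season; th$stage <- stage
        thresholds[[length(thresholds) + 1L]] <- th
        say(cell, ": rf (oob r2 = ", round(rf$oob_r2, 3), ") variable ", var,
            ", changepoint ", cp, if (direct) " (direct)" else " (subtracted)",
            " -> ", th$salinity, " ", th$days, " ", th$exposure, " days")
      }
    }
  }

  structure(list(
    thresholds = if (length(thresholds)) do.call(rbind, thresholds) else NULL,
    model_summary = if (length(summaries)) do.call(rbind, c(summaries, make.row.names = FALSE)) else NULL,
    comparisons = comparisons,
    rf_summary = if (length(rf_rows)) do.call(rbind, c(rf_rows, make.row.names = FALSE)) else NULL,
    log = log, config = config), class = "oyster_report")
}

#' @export
print.oyster_report <- function(x, ...) {
  cat("Threshold pipeline report\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  if (!is.null(x$thresholds)) {
    cat("thresholds:\n")
    print(x$thresholds)
  }
  invisible(x)
}
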