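#' Posterior predicted mean abundance at a given exposure
#'
#' For a single-covariate fit, returns the per-draw linear predictor for one
#' basin at `d` days of exposure: the basin-level intercept draw (the mean of
#' its station intercepts), plus the year effect averaged over the posterior
#' year intercepts, plus `gamma * d` (and `gamma2 * d^2` for a quadratic fit).
#'
#' @param fit An `oyster_fit` with exactly one covariate.
#' @param basin Basin id present in the fit.
#' @param d Day count (scalar).
#' @return Numeric vector, one value per retained draw.
#' @export
predict_abundance <- function(fit, basin, d) {
  if (length(fit$spec$covariates) != 1) {
    stop("prediction requires a single-covariate fit")
  }
  flags <- .level_flags(fit$spec$levels)
  if (!flags$basin) stop("fit has no basin level")
  col <- paste0("alpha.", basin)
  if (!col %in% colnames(fit$draws)) stop("basin absent from fit: ", basin)
  mu <- fit$draws[, col]
  if (flags$year) {
    lcols <- grep("^lambda\\.", colnames(fit$draws), value = TRUE)
    mu <- mu + rowMeans(fit$draws[, lcols, drop = FALSE])
  }
  cov <- fit$spec$covariates
  mu <- mu + fit$draws[, paste0("gamma.", cov)] * d
  if (fit$spec$quadratic) {
    mu <- mu + fit$draws[, paste0("gamma.", cov, ".sq")] * d^2
  }
  as.numeric(mu)
}

# Human-readable salinity label for a covariate used in a threshold row.
.covariate_salinity_label <- function(covariate, direct = FALSE) {
  p <- parse_exposure_column(covariate)
  if (!is.na(p$level)) return(sprintf("<%g", p$level))
  if (direct) sprintf("<%g", p$upper) else sprintf("<%g", p$lower)
}

#' Sweep a fitted model for the critical-abundance day threshold
#'
#' Runs the fitted single-covariate model over integer day counts 0..123 (the
#' summer window) and reports the smallest day count at which the posterior
#' median of predicted abundance drops below the basin's critical abundance
#' (half the five-year mean). Only negative-classified relations qualify: a
#' positive or indeterminate coefficient means no day threshold is derivable
#' and the sweep refuses to run.
#'
#' @param fit Single-covariate `oyster_fit`.
#' @param basin Basin id.
#' @param critical A [critical_abundance()] result (or its numeric value).
#' @param window_length Sweep upper bound in days (123 = summer).
#' @return One-row data.frame threshold result: `method`, `region`, `basin`,
#'   `season`, `stage`, `salinity`, `exposure`, `days` (NA when the median
#'   never crosses within the window), `criterion`.
#' @export
sweep_threshold <- function(fit, basin, critical, window_length = 123) {
  cls <- classify_effect(fit, fit$spec$covariates)
  if (!cls %in% c("negative-95", "negative-50")) {
    stop("threshold sweep requires a negative-classified coefficient (got ",
         cls, "); positive relations admit no low-salinity day threshold")
  }
  crit_val <- if (is.list(critical)) critical$value else critical
  # median over draws of (base + slope*d) for every d: vectorize via outer
  base <- predict_abundance(fit, basin, 0)
  days <- 0:window_length
  med <- vapply(days, function(d)
    stats::median(predict_abundance(fit, basin, d)), numeric(1))
  hit <- which(med < crit_val)
  dstar <- if (length(hit)) days[hit[1]] else NA_integer_
  p <- parse_exposure_column(fit$spec$covariates)
  data.frame(
    method = "bayes",
    region = tryCatch(region_split(basin), error = function(e) NA_character_),
    basin = basin,
    season = if (is.list(critical) && !is.null(critical$season)) critical$season[1] else NA_character_,
    stage = if (is.list(critical) && !is.null(critical$stage)) critical$stage[1] else NA_character_,
    salinity = .covariate_salinity_label(fit$spec$covariates, direct = TRUE),
    exposure = p$kind,
    days = dstar,
    criterion = if (is.na(dstar))
      "median never below critical abundance within window" else
      ">50% probability below critical abundance",
    stringsAsFactors = FALSE)
}

#' Convert a partial-dependence changepoint into a day threshold
#'
#' The subtract-from-window interpretation: a changepoint after `d` days in a
#' "safe" bin (salinity above the limiting level) implies the abundance
#' decline is driven by the complementary days spent below the bin's lower
#' bound, i.e. a threshold of (window constant - d) days at salinity below
#' the bin lower bound. The window constant is 123 for summer and 365 for a
#' calendar year. When the partial dependence declines within the low bin
#' itself (`direct = TRUE`), the changepoint is the threshold: `d` days below
#' the bin's upper bound, with no subtraction.
#'
#' @param window_kind `"summer"` or `"calendar"`.
#' @param changepoint_days Changepoint location in days.
#' @param bin Bin label (e.g. `"7-9"`) or a row of [salinity_bins()].
#' @param exposure_kind `"total"` or `"continuous"`.
#' @param direct Pass-through mode for declines inside the low bin itself.
#' @return One-row data.frame threshold result (`method = "rf"`).
#' @export
rf_interpretation_rule <- function(window_kind = c("summer", "calendar"),
                                   changepoint_days, bin,
                                   exposure_kind = c("total", "continuous"),
                                   direct = FALSE) {
  window_kind <- match.arg(window_kind)
  exposure_kind <- match.arg(exposure_kind)
  const <- c(summer = 123, calendar = 365)[[window_kind]]
  if (changepoint_days < 0 || changepoint_days > const) {
    stop("changepoint (", changepoint_days, ") outside the ", window_kind,
         " window constant of ", const, " days")
  }
  bins <- salinity_bins()
  if (is.character(bin)) {
    i <- match(bin, bins$label)
    if (is.na(i)) stop("unknown bin label: ", bin)
    bin <- bins[i, ]
  }
  data.frame(
    method = "rf",
    region = NA_character_, basin = NA_character_,
    season = NA_character_, stage = NA_character_,
    salinity = if (direct) sprintf("<%g", bin$upper) else sprintf("<%g", bin$lower),
    exposure = exposure_kind,
    days = if (direct) changepoint_days else const - changepoint_days,
    criterion = if (direct) "partial-dependence decline within low bin" else
      sprintf("%s window constant %d - changepoint %d", window_kind, const,
              as.integer(changepoint_days)),
    stringsAsFactors = FALSE)
}
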