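#' Classify shell height into life stage
#'
#' Spat are settled juveniles below 25 mm shell height; everything at or above
#' 25 mm is counted as adult.
#'
#' @param shell_height_mm Numeric vector of shell heights (mm, >= 0).
#' @return Character vector, `"spat"` or `"adult"`.
#' @export
classify_stage <- function(shell_height_mm) {
  stopifnot(all(shell_height_mm >= 0))
  ifelse(shell_height_mm < 25, "spat", "adult")
}

# months defining each season's dredge samples
.season_months <- list(fall = c(9L, 10L), winter = c(11L, 12L))

#' Collate dredge records into seasonal abundance
#'
#' Collapses record-level counts to one mean per-dredge abundance per
#' station-year-stage over the season's months (fall = Sep/Oct, winter =
#' Nov/Dec). Records may carry a `stage` column directly, or a
#' `shell_height_class_mm` column from which the stage is derived. Counts from
#' size classes of the same stage on the same sample date are summed before
#' averaging across dates. Station-years with no records in the season get no
#' row (not a zero). Records outside the season are ignored.
#'
#' @param records Data frame with `station_id`, `basin_id`, `date`, `count`,
#'   and either `stage` or `shell_height_class_mm`.
#' @param season `"fall"` or `"winter"`.
#' @return Abundance table: `station_id`, `basin_id`, `year`, `season`,
#'   `stage`, `abundance`.
#' @export
collate_season <- function(records, season = c("fall", "winter")) {
  season <- match.arg(season)
  stopifnot(all(c("station_id", "basin_id", "date", "count") %in% names(records)))
  if (!"stage" %in% names(records)) {
    if (!"shell_height_class_mm" %in% names(records)) {
      stop("records need a 'stage' or 'shell_height_class_mm' column")
    }
    records$stage <- classify_stage(records$shell_height_class_mm)
  }
  records$date <- as.Date(records$date)
  keep <- as.integer(format(records$date, "%m")) %in% .season_months[[season]]
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    return(data.frame(station_id = character(), basin_id = character(),
                      year = integer(), season = character(), stage = character(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  records$year <- as.integer(format(records$date, "%Y"))
  # per sample date: total count per stage; then mean over sample dates
  per_date <- stats::aggregate(
    count ~ station_id + basin_id + year + stage + date, data = records, FUN = sum)
  out <- stats::aggregate(
    count ~ station_id + basin_id + year + stage, data = per_date, FUN = mean)
  names(out)[names(out) == "count"] <- "abundance"
  out$season <- season
  out <- out[order(out$station_id, out$year, out$stage),
             c("station_id", "basin_id", "year", "season", "stage", "abundance")]
  rownames(out) <- NULL
  out
}

#' Critical abundance for a basin
#'
#' Half the five-year mean abundance across all station-year rows of a
#' basin-season-stage cell: the level below which the Bayesian branch declares
#' a threshold crossing.
#'
#' @param abundance Abundance table as from [collate_season()].
#' @param basin Basin id.
#' @param season,stage Cell selectors; default to the single value present.
#' @return List with `basin_id`, `season`, `stage`, `value`.
#' @export
critical_abundance <- function(abundance, basin, season = NULL, stage = NULL) {
  rows <- abundance[abundance$basin_id == basin, , drop = FALSE]
  if (!is.null(season)) rows <- rows[rows$season == season, , drop = FALSE]
  if (!is.null(stage)) rows <- rows[rows$stage == stage, , drop = FALSE]
  if (nrow(rows) == 0) stop("no abundance rows for basin ", basin)
  list(basin_id = basin,
       season = if (is.null(season)) unique(rows$season) else season,
       stage = if (is.null(stage)) unique(rows$stage) else stage,
       value = 0.5 * mean(rows$abundance))
}
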