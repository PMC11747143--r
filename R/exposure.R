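#' Standard salinity bins for exposure covariates
#'
#' The five low-salinity bins used to build exposure covariates: 0-1 (closed
#' on both ends), then 1-3, 3-5, 5-7, 7-9, each open below and closed above.
#' Daily means above 9 psu fall in no bin. The boundary convention
#' (upper-inclusive; a day at exactly 5.0 psu counts in "3-5") is a documented
#' choice; pass a modified data frame to the counting functions to change it.
#'
#' @return A data.frame with columns `label`, `lower`, `upper` (psu).
#' @export
salinity_bins <- function() {
  data.frame(
    label = c("0-1", "1-3", "3-5", "5-7", "7-9"),
    lower = c(0, 1, 3, 5, 7),
    upper = c(1, 3, 5, 7, 9),
    stringsAsFactors = FALSE
  )
}

#' Assign daily salinity values to bins
#'
#' @param value Numeric vector of daily mean salinity (psu). Must be >= 0.
#' @param bins Bin definition as from [salinity_bins()].
#' @return Character vector of bin labels; `NA` for values above the top bin.
#' @export
assign_bin <- function(value, bins = salinity_bins()) {
  if (any(is.na(value))) stop("salinity values must not be NA; drop missing days first")
  if (any(value < 0)) stop("negative salinity value: ", min(value))
  out <- rep(NA_character_, length(value))
  # lowest bin is closed at both ends; the rest are (lower, upper]
  out[value >= bins$lower[1] & value <= bins$upper[1]] <- bins$label[1]
  for (i in seq_len(nrow(bins))[-1]) {
    out[value > bins$lower[i] & value <= bins$upper[i]] <- bins$label[i]
  }
  out
}

#' Construct an exposure window
#'
#' @param kind `"summer"` (May 1 - Aug 31) or `"calendar"` (Jan 1 - Dec 31).
#' @param year Calendar year.
#' @return An object of class `exposure_window`.
#' @export
exposure_window <- function(kind = c("summer", "calendar"), year) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(year), length(year) == 1, year == round(year))
  structure(list(kind = kind, year = as.integer(year)), class = "exposure_window")
}

#' Dates covered by a window
#' @param window An [exposure_window()].
#' @return Vector of class `Date`.
#' @export
window_dates <- function(window) {
  y <- window$year
  if (window$kind == "summer") {
    seq(as.Date(sprintf("%d-05-01", y)), as.Date(sprintf("%d-08-31", y)), by = "day")
  } else {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
  }
}

#' Number of days in a window
#'
#' Summer windows (May 1 - Aug 31) are always 123 days; calendar windows are
#' 365 or 366 by the leap rule.
#'
#' @inheritParams window_dates
#' @return Integer day count.
#' @export
window_days <- function(window) {
  length(window_dates(window))
}

# Restrict a per-station series to a window, keeping the full window date
# grid so that missing days are visible as NA. Errors when the window does
# not overlap the series at all.
.window_values <- function(series, window) {
  stopifnot(all(c("date", "salinity") %in% names(series)))
  dates <- as.Date(series$date)
  if (any(duplicated(dates))) stop("duplicate dates in salinity series")
  wd <- window_dates(window)
  if (max(dates) < wd[1] || min(dates) > wd[length(wd)]) {
    stop("window ", window$kind, " ", window$year, " lies entirely outside the series date range")
  }
  series$salinity[match(wd, dates)]
}

#' Total days within a salinity bin over a window
#'
#' Counts window days whose daily mean falls inside the bin. Missing days are
#' never counted.
#'
#' @param series Data frame for one station with columns `date`, `salinity`.
#' @param window An [exposure_window()].
#' @param bin A bin label (e.g. `"1-3"`) or one row of [salinity_bins()].
#' @param bins Bin table used to resolve a label.
#' @return Integer count.
#' @export
total_days_in_bin <- function(series, window, bin, bins = salinity_bins()) {
  v <- .window_values(series, window)
  lab <- if (is.character(bin)) bin else bin$label
  a <- assign_bin(v[!is.na(v)], bins)
  sum(a == lab, na.rm = TRUE)
}

#' Maximum consecutive days within a salinity bin over a window
#'
#' Length of the longest run of consecutive calendar days inside the window
#' all falling in the bin. A missing day breaks a run.
#'
#' @inheritParams total_days_in_bin
#' @return Integer run length.
#' @export
max_consecutive_days_in_bin <- function(series, window, bin, bins = salinity_bins()) {
  v <- .window_values(series, window)
  lab <- if (is.character(bin)) bin else bin$label
  inbin <- rep(FALSE, length(v))
  ok <- !is.na(v)
  hit <- assign_bin(v[ok], bins) == lab   # NA for values above the top bin
  inbin[ok] <- !is.na(hit) & hit
  if (!any(inbin)) return(0L)
  r <- rle(inbin)
  max(r$lengths[r$values])
}

#' Total days below a salinity level over a window
#'
#' Strictly-below counting at the levels used for accumulated-exposure
#' covariates (1, 3, 5, 7, 9 psu).
#'
#' @inheritParams total_days_in_bin
#' @param level One of 1, 3, 5, 7, 9 (psu).
#' @return Integer count of window days with salinity `< level`.
#' @export
total_days_below <- function(series, window, level) {
  if (!level %in% c(1, 3, 5, 7, 9)) stop("unsupported level: ", level)
  v <- .window_values(series, window)
  sum(v < level, na.rm = TRUE)
}

#' Maximum consecutive days below a salinity level over a window
#'
#' @inheritParams total_days_below
#' @return Integer run length of days with salinity `< level`.
#' @export
max_consecutive_days_below <- function(series, window, level) {
  if (!level %in% c(1, 3, 5, 7, 9)) stop("unsupported level: ", level)
  v <- .window_values(series, window)
  below <- !is.na(v) & v < level
  if (!any(below)) return(0L)
  r <- rle(below)
  max(r$lengths[r$values])
}

# Column code for a window kind: "su" (summer) / "an" (annual).
.window_code <- function(kind) c(summer = "su", calendar = "an")[[kind]]

#' Exposure covariate column names
#'
#' Columns follow the field convention: total days in a bin is
#' `s_d_<win><lo>.<hi>` and maximum consecutive days is `c.d_<win><lo>.<hi>`,
#' e.g. `s_d_su7.9` and `c.d_su7.9` for the 7-9 psu bin in summer. Below-level
#' accumulated columns use `lt<level>` in place of `<lo>.<hi>`.
#'
#' @param kind `"summer"` or `"calendar"`.
#' @param bins Bin table.
#' @param below Optional vector of below-levels to include.
#' @return Character vector of column names (total-days then consecutive-days
#'   per bin, then any below-level pairs).
#' @export
exposure_column_names <- function(kind = "summer", bins = salinity_bins(), below = NULL) {
  code <- .window_code(kind)
  nm <- as.vector(rbind(
    sprintf("s_d_%s%g.%g", code, bins$lower, bins$upper),
    sprintf("c.d_%s%g.%g", code, bins$lower, bins$upper)
  ))
  if (length(below)) {
    nm <- c(nm, as.vector(rbind(
      sprintf("s_d_%slt%g", code, below),
      sprintf("c.d_%slt%g", code, below)
    )))
  }
  nm
}

# Parse an exposure column name into its parts. Returns a list with
# kind ("total"/"continuous"), window ("summer"/"calendar"), and either
# bin lower/upper bounds or a below-level.
parse_exposure_column <- function(name) {
  kind <- if (startsWith(name, "s_d_")) "total" else if (startsWith(name, "c.d_")) "continuous" else
    stop("not an exposure column: ", name)
  rest <- sub("^(s_d_|c\\.d_)", "", name)
  win <- if (startsWith(rest, "su")) "summer" else if (startsWith(rest, "an")) "calendar" else
    stop("unknown window code in column: ", name)
  rest <- substring(rest, 3)
  if (startsWith(rest, "lt")) {
    list(kind = kind, window = win, level = as.numeric(substring(rest, 3)),
         lower = 0, upper = as.numeric(substring(rest, 3)))
  } else {
    bounds <- as.numeric(strsplit(rest, ".", fixed = TRUE)[[1]])
    if (length(bounds) != 2 || any(is.na(bounds))) stop("cannot parse bin bounds in: ", name)
    list(kind = kind, window = win, level = NA_real_, lower = bounds[1], upper = bounds[2])
  }
}

#' Build the exposure covariate table
#'
#' One row per station-year; for each requested window kind, 10 covariate
#' columns (5 bins x total days / max consecutive days), plus optional
#' accumulated below-level pairs.
#'
#' @param salinity Long data frame of daily salinity: `station_id`,
#'   `basin_id`, `date`, `salinity` (as written by [generate_salinity()]).
#' @param years Years to cover; defaults to all years present.
#' @param window_kinds `"summer"`, `"calendar"`, or both.
#' @param bins Bin table.
#' @param below Optional below-levels (subset of 1,3,5,7,9) to add as
#'   accumulated columns.
#' @return Data frame with `station_id`, `basin_id`, `year`, and the covariate
#'   columns of [exposure_column_names()].
#' @export
build_exposure_table <- function(salinity, years = NULL,
                                 window_kinds = "summer",
                                 bins = salinity_bins(), below = NULL) {
  stopifnot(all(c("station_id", "basin_id", "date", "salinity") %in% names(salinity)))
  if (nrow(salinity) == 0) {
    out <- data.frame(station_id = character(), basin_id = character(), year = integer())
    for (k in window_kinds) for (nm in exposure_column_names(k, bins, below)) out[[nm]] <- integer()
    return(out)
  }
  salinity$date <- as.Date(salinity$date)
  if (is.null(years)) years <- sort(unique(as.integer(format(salinity$date, "%Y"))))
  stations <- unique(salinity[, c("station_id", "basin_id")])
  if (anyDuplicated(stations$station_id)) stop("station assigned to more than one basin")
  rows <- list()
  for (si in seq_len(nrow(stations))) {
    st <- stations$station_id[si]
    ser <- salinity[salinity$station_id == st, c("date", "salinity")]
    for (y in years) {
      row <- list(station_id = st, basin_id = stations$basin_id[si], year = as.integer(y))
      for (k in window_kinds) {
        w <- exposure_window(k, y)
        code <- .window_code(k)
        for (bi in seq_len(nrow(bins))) {
          b <- bins[bi, ]
          row[[sprintf("s_d_%s%g.%g", code, b$lower, b$upper)]] <-
            total_days_in_bin(ser, w, b$label, bins)
          row[[sprintf("c.d_%s%g.%g", code, b$lower, b$upper)]] <-
            max_consecutive_days_in_bin(ser, w, b$label, bins)
        }
        for (lv in below) {
          row[[sprintf("s_d_%slt%g", code, lv)]] <- total_days_below(ser, w, lv)
          row[[sprintf("c.d_%slt%g", code, lv)]] <- max_consecutive_days_below(ser, w, lv)
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[, c("station_id", "year")])) stop("duplicate station-year rows")
  rownames(out) <- NULL
  out
}
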