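#' Monitoring-site selector for AQS hourly files
#'
#' Identifies one monitor in an EPA AQS pre-generated hourly file by its
#' printed WGS84 coordinates (matched within a decimal tolerance) and,
#' optionally, the pollutant parameter name and datum.
#'
#' @param longitude,latitude decimal degrees.
#' @param parameter AQS parameter name to match, or `NULL` to skip.
#' @param datum datum string to match, or `NULL` to skip.
#' @param tol coordinate matching tolerance in degrees (default 1e-5).
#' @return an object of class `site_selector`.
#' @examples
#' site_selector(-118.22688, 34.06659)
#' @export
site_selector <- function(longitude, latitude,
                          parameter = "Nitrogen dioxide (NO2)",
                          datum = "WGS84", tol = 1e-5) {
  if (!is.numeric(longitude) || abs(longitude) > 180)
    stop("`longitude` must lie in [-180, 180]")
  if (!is.numeric(latitude) || abs(latitude) > 90)
    stop("`latitude` must lie in [-90, 90]")
  structure(list(longitude = longitude, latitude = latitude,
                 parameter = parameter, datum = datum, tol = tol),
            class = "site_selector")
}

#' Read an EPA AQS pre-generated hourly file onto a continuous hourly grid
#'
#' Reads the comma-separated AQS hourly dialect (header row; per-reading
#' rows carrying site coordinates, local date/time and the sample
#' measurement), selects the rows matching `selector`, strips coded-error
#' readings (non-empty `Qualifier`, or measurements equal to a sentinel in
#' `error_values`), averages multiple readings within the same hour, and
#' returns one value per hour on an exact hourly grid; absent hours are
#' `NA`.  Timestamps are taken from the local-standard-time columns
#' (`Date Local`/`Time Local`) because daily and weekly human-activity
#' periodicity is phase-locked to local clock time; set `time_cols` to use
#' the GMT columns instead.
#'
#' @param path CSV file path (e.g. an `hourly_42602_YYYY.csv` extract).
#' @param selector a [site_selector()], or `NULL` to keep all rows.
#' @param start,end `POSIXct` bounds of the requested hourly grid; default
#'   to the span of the selected data.
#' @param error_values sentinel measurement values treated as coded errors.
#' @param time_cols which timestamp columns to use: `"local"` or `"gmt"`.
#' @return a [periodic_series()] with a `cleaning` attribute; see
#'   [cleaning_report()].
#' @export
read_aqs_hourly <- function(path, selector = NULL, start = NULL, end = NULL,
                            error_values = -999, time_cols = c("local", "gmt")) {
  time_cols <- match.arg(time_cols)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  dcol <- if (time_cols == "local") "Date Local" else "Date GMT"
  tcol <- if (time_cols == "local") "Time Local" else "Time GMT"
  need <- c("Latitude", "Longitude", dcol, tcol, "Sample Measurement")
  if (!all(need %in% names(df)))
    stop("file is not in the AQS hourly dialect; missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))

  if (!is.null(selector)) {
    stopifnot(inherits(selector, "site_selector"))
    keep <- abs(df$Longitude - selector$longitude) <= selector$tol &
      abs(df$Latitude - selector$latitude) <= selector$tol
    if (!is.null(selector$parameter) && "Parameter Name" %in% names(df))
      keep <- keep & df[["Parameter Name"]] == selector$parameter
    if (!is.null(selector$datum) && "Datum" %in% names(df))
      keep <- keep & df[["Datum"]] == selector$datum
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows matching the site selector")
  }

  ts <- as.POSIXct(paste(df[[dcol]], df[[tcol]]),
                   format = "%Y-%m-%d %H:%M", tz = "UTC")
  rejected <- sum(is.na(ts))
  if (rejected > 0) {
    warning(sprintf("%d row(s) with unparseable timestamps rejected", rejected))
    df <- df[!is.na(ts), , drop = FALSE]
    ts <- ts[!is.na(ts)]
  }

  meas <- suppressWarnings(as.numeric(df[["Sample Measurement"]]))
  qual <- if ("Qualifier" %in% names(df)) trimws(as.character(df$Qualifier)) else ""
  qual[is.na(qual)] <- ""
  is_err <- qual != "" | meas %in% error_values | !is.finite(meas)
  n_err <- sum(is_err)
  ts <- ts[!is_err]
  meas <- meas[!is_err]

  # floor to the hour, then average replicate readings within each hour
  hr <- as.numeric(ts) %/% 3600 * 3600
  if (is.null(start)) start <- as.POSIXct(min(hr), origin = "1970-01-01", tz = "UTC")
  if (is.null(end)) end <- as.POSIXct(max(hr), origin = "1970-01-01", tz = "UTC")
  if (end < start) stop("`end` precedes `start`")
  in_range <- hr >= as.numeric(start) & hr <= as.numeric(end)
  hr <- hr[in_range]
  meas <- meas[in_range]

  ngrid <- as.integer((as.numeric(end) - as.numeric(start)) %/% 3600) + 1L
  out <- rep(NA_real_, ngrid)
  if (length(meas) > 0) {
    key <- as.integer((hr - as.numeric(start)) %/% 3600) + 1L
    sums <- rowsum(meas, key)
    cnts <- rowsum(rep(1, length(key)), key)
    out[as.integer(rownames(sums))] <- sums[, 1L] / cnts[, 1L]
  }

  series <- periodic_series(out, start = start)
  attr(series, "cleaning") <- list(
    retained = length(meas),
    coded_errors = n_err,
    missing_hours = sum(is.na(out)),
    rejected_timestamps = rejected
  )
  series
}

#' Cleaning report of an AQS read
#'
#' Totals recorded while reading an AQS hourly file: readings retained,
#' coded-error exclusions, missing hours on the output grid, and rows
#' rejected for unparseable timestamps.
#'
#' @param x a series produced by [read_aqs_hourly()].
#' @return list with `retained`, `coded_errors`, `missing_hours`,
#'   `rejected_timestamps`.  A series without cleaning metadata yields an
#'   all-zero report with a warning.
#' @export
cleaning_report <- function(x) {
  rep <- attr(x, "cleaning")
  if (is.null(rep)) {
    warning("no cleaning metadata on this series; returning an all-zero report")
    rep <- list(retained = 0L, coded_errors = 0L, missing_hours = 0L,
                rejected_timestamps = 0L)
  }
  rep
}

#' Write a series as a tidy two-column hourly CSV
#'
#' Columns `time` (ISO-8601 hour) and `value`; missing hours have a blank
#' value field.
#'
#' @param x a [periodic_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(x, path) {
  stopifnot(inherits(x, "periodic_series"))
  df <- data.frame(time = format(series_time(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   value = x$values)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
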