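#' Regularly sampled series container
#'
#' A `periodic_series` is a plain container for a regularly sampled (by
#' default hourly) sequence of measurements.  Missing observations are held
#' as `NA`; the sampling grid is implicit (a start time plus a constant
#' interval), so the series always covers a complete arithmetic time grid
#' with no gaps in the index.
#'
#' @param values numeric vector of measurements; `NA` marks a missing hour.
#' @param start `POSIXct` timestamp of the first sample.
#' @param interval_hours sampling interval in hours (default 1).
#' @return an object of class `periodic_series`.
#' @examples
#' x <- periodic_series(c(10, NA, 12.5))
#' series_time(x)
#' @export
periodic_series <- function(values,
                            start = as.POSIXct("2010-01-01 00:00:00", tz = "UTC"),
                            interval_hours = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must contain at least one sample")
  if (!is.numeric(interval_hours) || interval_hours <= 0)
    stop("`interval_hours` must be a positive number")
  structure(
    list(values = values, start = start, interval_hours = interval_hours),
    class = "periodic_series"
  )
}

#' @export
print.periodic_series <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf(
    "<periodic_series> %d samples every %g h from %s (%d missing, %.1f%%)\n",
    n, x$interval_hours, format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
    miss, 100 * miss / n
  ))
  invisible(x)
}

#' Timestamps of a periodic series
#'
#' @param x a [periodic_series()].
#' @return `POSIXct` vector, one timestamp per sample.
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "periodic_series"))
  x$start + (seq_along(x$values) - 1) * 3600 * x$interval_hours
}

#' Extract the numeric values of a series-like object
#'
#' Accepts a bare numeric vector, a [periodic_series()], or a
#' `component_estimate` and returns the underlying numeric values.
#'
#' @param x series-like object.
#' @return numeric vector.
#' @export
series_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "periodic_series")) return(x$values)
  if (inherits(x, "component_estimate")) return(x$values)
  stop("cannot extract values from an object of class ",
       paste(class(x), collapse = "/"))
}

# Valid-observation mask shared by the periodic-mean and bootstrap code:
# finite values only, and for filtered components also the edge-validity mask.
series_valid <- function(x) {
  if (inherits(x, "component_estimate")) {
    return(x$valid & is.finite(x$values))
  }
  is.finite(series_values(x))
}

#' Replace coded-error sentinel values with missing values
#'
#' Measurement files sometimes carry coded errors as sentinel readings
#' (for example -999).  This replaces them with `NA` so that downstream
#' statistics skip them, and records how many were stripped.
#'
#' @param x series-like object.
#' @param error_values numeric sentinel values to strip.
#' @return the input with sentinels replaced by `NA`; the count of stripped
#'   readings is available as `attr(, "n_coded_errors")`.
#' @export
clean_series <- function(x, error_values = -999) {
  v <- series_values(x)
  bad <- v %in% error_values
  v[bad] <- NA_real_
  out <- if (inherits(x, "periodic_series")) {
    periodic_series(v, start = x$start, interval_hours = x$interval_hours)
  } else {
    v
  }
  attr(out, "n_coded_errors") <- sum(bad)
  out
}
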