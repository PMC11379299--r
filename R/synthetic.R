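#' Ground-truth specification for a synthetic hourly pollutant series
#'
#' Describes a simulated hourly concentration series as
#' `X(t) = grand_mean + trend_slope * (t - (n-1)/2)
#'        + sum_c A_c * cos(2*pi*t/p_c + phi_c) + noise(t)`,
#' followed by injection of sporadic missing values and a handful of
#' coded-error sentinel readings.  The trend is centred so `grand_mean` is
#' the series mean regardless of the slope.  Harmonics of a fundamental are
#' expressed as additional component rows at the divided period (e.g. a
#' daily second harmonic is a period-12 row).
#'
#' The defaults emulate an urban hourly NO2 record: about 10^5 hourly
#' samples, level near 20.6 ppb, a dominant winter-high annual cycle,
#' weaker daily (with second harmonic, morning-peaked) and weekly cycles, a
#' slight negative linear trend, heavy strongly autocorrelated noise, a few
#' percent missing hours, and 5 coded-error readings.
#'
#' @param n series length in samples (hours).
#' @param grand_mean mean level, ppb.
#' @param trend_slope linear trend in ppb per hour (applied centred).
#' @param components data frame with columns `period` (samples),
#'   `amplitude` (ppb, `>= 0`) and `phase` (radians).
#' @param noise_sd marginal standard deviation of the noise, ppb.
#' @param ar1_rho lag-1 autocorrelation of the AR(1) noise, in [0, 1);
#'   0 gives white noise.
#' @param missing_rate fraction of hours set missing, in [0, 1).
#' @param n_coded_errors number of sentinel coded-error readings injected.
#' @param error_code sentinel value used for coded errors.
#' @param seed default RNG seed for [synthetic_series()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 99825,
                           grand_mean = 20.57,
                           trend_slope = -3e-5,
                           components = data.frame(
                             label = c("annual", "daily", "daily_harmonic", "weekly"),
                             period = c(8760, 24, 12, 168),
                             amplitude = c(6, 3, 1.5, 1),
                             phase = c(0, -2 * pi * 8 / 24, 0, 0)
                           ),
                           noise_sd = 8,
                           ar1_rho = 0.9,
                           missing_rate = 0.02,
                           n_coded_errors = 5,
                           error_code = -999,
                           seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("period", "amplitude", "phase") %in% names(components)))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be positive")
  if (any(components$amplitude < 0)) stop("component amplitudes must be >= 0")
  if (any(components$period < 2)) stop("component periods must be >= 2 samples")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must lie in [0, 1)")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("`ar1_rho` must lie in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (nrow(components) > 0 && n <= 2 * max(components$period))
    stop("`n` must exceed twice the longest component period")
  if (n_coded_errors < 0) stop("`n_coded_errors` must be >= 0")
  structure(
    list(n = as.integer(n), grand_mean = grand_mean, trend_slope = trend_slope,
         components = components, noise_sd = noise_sd, ar1_rho = ar1_rho,
         missing_rate = missing_rate, n_coded_errors = as.integer(n_coded_errors),
         error_code = error_code, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, mean %.2f, %d components, noise sd %.2f (AR1 rho %.2f)\n",
              x$n, x$grand_mean, nrow(x$components), x$noise_sd, x$ar1_rho))
  invisible(x)
}

#' Generate a synthetic hourly series with recorded ground truth
#'
#' Draws one realization of a [synthetic_spec()]: deterministic signal plus
#' Gaussian white or AR(1) noise, then missing values and coded-error
#' sentinels.  The same spec and seed always reproduce the identical
#' series.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @param start timestamp of the first sample.
#' @return a [periodic_series()] whose values may contain `NA` (missing
#'   hours) and `spec$error_code` sentinels, with attributes
#'   `synthetic_spec` (the ground truth) and `error_index` (positions of
#'   the injected coded errors).
#' @seealso [true_periodic_mean()] for the analytic per-phase truth,
#'   [clean_series()] to strip the sentinels before analysis.
#' @export
synthetic_series <- function(spec, seed = spec$seed,
                             start = as.POSIXct("2010-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n
  t <- seq_len(n) - 1
  v <- spec$grand_mean + spec$trend_slope * (t - (n - 1) / 2)
  for (i in seq_len(nrow(spec$components))) {
    cm <- spec$components[i, ]
    v <- v + cm$amplitude * cos(2 * pi * t / cm$period + cm$phase)
  }
  if (spec$noise_sd > 0) {
    if (spec$ar1_rho > 0) {
      innov <- stats::rnorm(n, sd = spec$noise_sd * sqrt(1 - spec$ar1_rho^2))
      e <- as.numeric(stats::filter(innov, spec$ar1_rho, method = "recursive",
                                    init = stats::rnorm(1, sd = spec$noise_sd)))
    } else {
      e <- stats::rnorm(n, sd = spec$noise_sd)
    }
    v <- v + e
  }
  miss <- stats::runif(n) < spec$missing_rate
  v[miss] <- NA_real_
  err_idx <- integer(0)
  present <- which(!miss)
  if (spec$n_coded_errors > 0 && length(present) > 0) {
    err_idx <- sort(present[sample.int(length(present),
                                       min(spec$n_coded_errors, length(present)))])
    v[err_idx] <- spec$error_code
  }
  out <- periodic_series(v, start = start)
  attr(out, "synthetic_spec") <- spec
  attr(out, "error_index") <- err_idx
  out
}

#' Analytic per-phase periodic mean implied by a synthetic spec
#'
#' The exact per-phase mean deviation at the queried period: a cosine
#' component of period `p` contributes to the phase means at period `d`
#' only when `p` divides `d` (components at other periods average to zero
#' over whole cycles, as does the centred trend).
#'
#' @param spec a [synthetic_spec()].
#' @param period queried period `d` in samples.
#' @return numeric vector of length `period`: true mean deviation at
#'   phases `0 .. period-1`.
#' @export
true_periodic_mean <- function(spec, period) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- check_period(period)
  s <- seq_len(d) - 1
  dev <- numeric(d)
  for (i in seq_len(nrow(spec$components))) {
    cm <- spec$components[i, ]
    if (d %% cm$period == 0) {
      dev <- dev + cm$amplitude * cos(2 * pi * s / cm$period + cm$phase)
    }
  }
  dev
}

#' Write a series in the EPA AQS pre-generated hourly CSV dialect
#'
#' Emits one row per non-missing hour with the site, timestamp and sample
#' measurement columns used by AQS pre-generated hourly files, so the
#' [read_aqs_hourly()] reader can be exercised round-trip on synthetic
#' data.  Values equal to `error_code` are written with a non-empty
#' `Qualifier` (coded-error) field.
#'
#' @param x a [periodic_series()].
#' @param path output file path.
#' @param longitude,latitude,datum site coordinates written on every row.
#' @param parameter AQS parameter name.
#' @param units unit string.
#' @param error_code sentinel value flagged via the qualifier column;
#'   defaults to the generating spec's code when `x` is synthetic.
#' @return `path`, invisibly.
#' @export
write_aqs_hourly <- function(x, path,
                             longitude = -118.22688, latitude = 34.06659,
                             datum = "WGS84",
                             parameter = "Nitrogen dioxide (NO2)",
                             units = "Parts per billion",
                             error_code = NULL) {
  stopifnot(inherits(x, "periodic_series"))
  if (is.null(error_code)) {
    sp <- attr(x, "synthetic_spec")
    error_code <- if (is.null(sp)) -999 else sp$error_code
  }
  tm <- series_time(x)
  keep <- !is.na(x$values)
  v <- x$values[keep]
  tm <- tm[keep]
  df <- data.frame(
    "Latitude" = latitude,
    "Longitude" = longitude,
    "Datum" = datum,
    "Parameter Name" = parameter,
    "Date Local" = format(tm, "%Y-%m-%d", tz = "UTC"),
    "Time Local" = format(tm, "%H:%M", tz = "UTC"),
    "Sample Measurement" = v,
    "Units of Measure" = units,
    "Qualifier" = ifelse(v %in% error_code, "ER - coded error", ""),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
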