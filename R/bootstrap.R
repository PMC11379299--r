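#' Bootstrap configuration
#'
#' Settings shared by the GSBB and VBPBB band constructions.
#'
#' @param n_boot number of bootstrap replicates (>= 100 for band
#'   construction; default 1000).
#' @param block_length block length in samples; `NULL` (default) means one
#'   full period per block.
#' @param alpha two-sided level of the percentile intervals (default 0.05).
#' @param seed integer seed; replicate `r` derives its own RNG stream from
#'   `(seed, r)`, so replicate sets are order-independent and bands are
#'   bit-reproducible.
#' @param circular should blocks wrap around the end of the series
#'   (default `TRUE`)?
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000, block_length = NULL, alpha = 0.05,
                             seed = 1L, circular = TRUE) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1)
    stop("`n_boot` must be a positive integer")
  if (!is.null(block_length) &&
      (!is.numeric(block_length) || length(block_length) != 1L || block_length < 1))
    stop("`block_length` must be a positive integer or NULL")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a finite integer")
  structure(
    list(n_boot = as.integer(n_boot),
         block_length = if (is.null(block_length)) NULL else as.integer(block_length),
         alpha = alpha, seed = as.integer(seed), circular = isTRUE(circular)),
    class = "bootstrap_config"
  )
}

# Deterministic per-replicate substream seed, kept below 2^31.
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 2147483647 * 1000003 + r * 7919) %% 2147483647)
}

#' Periodic mean of a series
#'
#' For period `d`, the mean of the valid observations at each phase
#' `s = 0 .. d-1` (sample indices congruent to `s` modulo `d`), returned as
#' deviations from the grand mean of all valid observations.
#'
#' @param x series-like object (raw series or `component_estimate`).
#' @param period period in samples (`>= 2`).
#' @return numeric vector of length `period` of per-phase deviations, with
#'   attributes `grand_mean` and `counts`.
#' @examples
#' periodic_mean(c(1, 2, 3, 1, 2, 3), 3)  # -1 0 1
#' @export
periodic_mean <- function(x, period) {
  d <- check_period(period)
  v <- series_values(x)
  ok <- series_valid(x)
  ph <- (seq_along(v) - 1L) %% d
  counts <- tabulate(ph[ok] + 1L, nbins = d)
  if (any(counts == 0L)) {
    stop(sprintf("no valid observations at phase %d (period %d)",
                 which(counts == 0L)[1] - 1L, d))
  }
  sums <- rowsum(v[ok], ph[ok])[, 1L]
  means <- sums / counts
  gm <- mean(v[ok])
  out <- unname(means - gm)
  attr(out, "grand_mean") <- gm
  attr(out, "counts") <- counts
  out
}

check_period <- function(period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      round(period) < 2)
    stop("`period` must be a single integer >= 2 samples")
  as.integer(round(period))
}

# Candidate block starts for each resampling slot.
#
# v has length n; the phase of v[1] is phase0 (phases refer to the original
# series' indexing).  Slots start at 1, 1+b, ...; a block filling the slot
# must start at a position of the same phase.  Returns list(starts = slot
# start positions, lens = slot block lengths, cands = list of candidate
# start positions per slot).
gsbb_slots <- function(n, phase0, d, b, circular) {
  nslots <- ceiling(n / b)
  starts <- seq.int(1L, by = b, length.out = nslots)
  lens <- rep.int(b, nslots)
  lens[nslots] <- n - b * (nslots - 1L)
  cands <- lapply(seq_len(nslots), function(s) {
    p <- seq.int(((starts[s] - 1L) %% d) + 1L, n, by = d)
    if (!circular) p <- p[p + lens[s] - 1L <= n]
    if (length(p) == 0L)
      stop("no admissible block start for a slot; series too short for this ",
           "period/block length without circular wrapping")
    p
  })
  list(starts = starts, lens = lens, cands = cands)
}

# Wrap block indices that overhang the series end back to the start while
# preserving phase: overhanging indices are reduced modulo the largest whole
# number of cycles, so the wrap is phase-neutral even when the period does
# not divide the series length.
wrap_index <- function(idx, n, d) {
  n2 <- d * (n %/% d)
  over <- idx > n
  if (any(over)) idx[over] <- (idx[over] - 1L) %% n2 + 1L
  idx
}

# Bootstrap band engine for GSBB-style phase-preserving block resampling.
#
# Each resampled block of one period length carries one estimate of the
# periodic pattern: its phase-s value, taken as a deviation from the grand
# mean of the pseudo-series it belongs to.  The band is the per-phase
# (alpha/2, 1-alpha/2) percentile interval of these per-cycle deviations,
# pooled over the blocks within and across the B replicates.  (With general
# block lengths the pooled per-cycle deviations are simply the
# pseudo-series values minus their replicate grand mean.)
#
# v: values with NA for missing; phase0: phase of v[1]; d: period;
# b: block length; B: replicates.  Returns a 2 x d matrix (lower, upper).
boot_band_quantiles <- function(v, phase0, d, b, B, circular, seed, alpha,
                                chunk_elems = 4e6) {
  n <- length(v)
  sl <- gsbb_slots(n, phase0, d, b, circular)
  nslots <- length(sl$starts)

  # Sample all block starts first: replicate r uses its own derived stream.
  starts <- matrix(0L, nrow = nslots, ncol = B)
  for (r in seq_len(B)) {
    set.seed(derive_seed(seed, r))
    starts[, r] <- vapply(sl$cands, function(cs) {
      cs[sample.int(length(cs), 1L)]
    }, integer(1))
  }

  slot_of <- rep.int(seq_len(nslots), sl$lens)      # length n
  within <- sequence(sl$lens) - 1L                  # offset inside block
  ph <- (phase0 + seq_len(n) - 1L) %% d             # phase of slot position

  devs <- matrix(NA_real_, nrow = n, ncol = B)
  chunk <- max(1L, as.integer(chunk_elems %/% n))
  for (lo in seq.int(1L, B, by = chunk)) {
    hi <- min(lo + chunk - 1L, B)
    idx <- starts[slot_of, lo:hi, drop = FALSE] + within
    if (circular) idx <- wrap_index(idx, n, d)
    vals <- matrix(v[idx], nrow = n)
    nn <- !is.na(vals)
    vals0 <- vals
    vals0[!nn] <- 0
    gmean <- colSums(vals0) / colSums(nn)
    devs[, lo:hi] <- sweep(vals, 2L, gmean)
  }

  qs <- matrix(NA_real_, nrow = 2L, ncol = d)
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (s in seq_len(d)) {
    pool <- devs[ph == s - 1L, , drop = FALSE]
    pool <- pool[!is.na(pool)]
    if (length(pool) > 0L)
      qs[, s] <- stats::quantile(pool, probs = probs, names = FALSE, type = 7)
  }
  qs
}

#' One GSBB pseudo-series
#'
#' Draws a single General Seasonal Block Bootstrap resample: the series is
#' rebuilt from blocks of `block_length` samples whose start positions are
#' drawn uniformly among the positions sharing the phase (modulo `period`)
#' of the slot they fill, so the periodic structure at `period` is
#' preserved.  With `circular = TRUE` blocks may wrap around the series
#' end.  With `period = 1` this reduces to the ordinary (non-seasonal)
#' moving block bootstrap.
#'
#' @param x series-like object of length at least `2 * period`.
#' @param period period in samples.
#' @param cfg a [bootstrap_config()]; `cfg$seed` determines the draw.
#' @return numeric vector of the same length as the input.
#' @export
gsbb_resample <- function(x, period, cfg = bootstrap_config()) {
  d <- if (period == 1) 1L else check_period(period)
  v <- series_values(x)
  n <- length(v)
  if (d > n) stop("`period` exceeds the series length")
  if (n < 2L * d) stop("series must be at least twice the period")
  b <- if (is.null(cfg$block_length)) d else cfg$block_length
  sl <- gsbb_slots(n, 0L, d, b, cfg$circular)
  set.seed(derive_seed(cfg$seed, 1L))
  starts <- vapply(sl$cands, function(cs) cs[sample.int(length(cs), 1L)],
                   integer(1))
  idx <- rep.int(starts, sl$lens) + (sequence(sl$lens) - 1L)
  if (cfg$circular) idx <- wrap_index(idx, n, d)
  v[idx]
}

#' Bootstrap confidence band for the periodic mean
#'
#' Builds the per-phase percentile confidence band of the periodic-mean
#' deviations at the given period, using either
#'
#' * `method = "GSBB"`: phase-preserving block resampling of the raw
#'   series, or
#' * `method = "VBPBB"`: the series is first bandpass-filtered with the
#'   KZFT filter `spec` to isolate the component at `1/period`, and the
#'   resampling runs on the filtered component over its edge-valid region.
#'
#' Each resampled block of one period length carries one bootstrap estimate
#' of the periodic pattern: its value at phase `s`, expressed as a
#' deviation from the grand mean of the pseudo-series it belongs to.  The
#' band is the per-phase (`alpha/2`, `1 - alpha/2`) percentile interval of
#' these per-cycle deviations pooled over the blocks within and across the
#' `n_boot` replicates (linear-interpolation quantiles).  The band centre
#' is the periodic-mean point estimate from the unresampled input.  Built
#' this way the band reflects the cycle-to-cycle variability of the
#' periodic component -- for the raw series (GSBB) it approaches the
#' per-phase spread of the data, while for the bandpass-filtered component
#' (VBPBB) interfering frequencies and noise have been suppressed, which is
#' what makes the VBPBB band far narrower; the horizontal-line criterion
#' ([significance()]) then retains its error control across phases (see the
#' methods vignette for the discussion of this construction).
#'
#' @param x series-like object, or a precomputed `component_estimate` for
#'   VBPBB.
#' @param period period in samples.
#' @param cfg a [bootstrap_config()].
#' @param method `"VBPBB"` or `"GSBB"`.
#' @param spec a [filter_spec()] for VBPBB; defaults to
#'   `filter_spec(period = period, k = 2)`.
#' @param ... passed to [kzft_transform()] when VBPBB filters internally.
#' @return an object of class `confidence_band`: data frame with columns
#'   `phase`, `lower`, `center`, `upper`, plus attributes `period`,
#'   `method`, `alpha`, `n_boot`, `spec`.
#' @export
band_from_bootstrap <- function(x, period, cfg = bootstrap_config(),
                                method = c("VBPBB", "GSBB"), spec = NULL, ...) {
  method <- match.arg(method)
  d <- check_period(period)
  if (cfg$n_boot < 100L)
    stop("band construction requires `n_boot` >= 100")

  if (method == "VBPBB") {
    comp <- if (inherits(x, "component_estimate")) {
      x
    } else {
      if (is.null(spec)) spec <- filter_spec(period = d, k = 2)
      kzft_component(x, spec, ...)
    }
    spec <- comp$spec
    ok <- comp$valid & is.finite(comp$values)
    if (!any(ok)) stop("insufficient valid data after filtering")
    first <- which(ok)[1L]
    last <- which(ok)[sum(ok)]
    v <- comp$values[first:last]
    v[!ok[first:last]] <- NA_real_
    if (length(v) < 2L * d)
      stop("insufficient valid data after filtering: fewer than two periods remain")
    phase0 <- (first - 1L) %% d
    center <- periodic_mean(comp, d)
  } else {
    v <- series_values(x)
    v[!series_valid(x)] <- NA_real_
    if (length(v) < 2L * d) stop("series must be at least twice the period")
    phase0 <- 0L
    center <- periodic_mean(x, d)
    spec <- NULL
  }

  b <- if (is.null(cfg$block_length)) d else cfg$block_length
  qs <- boot_band_quantiles(v, phase0, d, b, cfg$n_boot, cfg$circular,
                            cfg$seed, cfg$alpha)

  out <- data.frame(phase = 0:(d - 1L),
                    lower = qs[1L, ],
                    center = as.numeric(center),
                    upper = qs[2L, ])
  structure(out,
            class = c("confidence_band", "data.frame"),
            period = d, method = method, alpha = cfg$alpha,
            n_boot = cfg$n_boot, spec = spec, seed = cfg$seed)
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf("<confidence_band> %s, period %d, %d%% level, %d replicates\n",
              attr(x, "method"), attr(x, "period"),
              round(100 * (1 - attr(x, "alpha"))), attr(x, "n_boot")))
  cat(sprintf("  center range [%.4g, %.4g]; median width %.4g\n",
              min(x$center), max(x$center), stats::median(x$upper - x$lower)))
  invisible(x)
}

#' Horizontal-line significance of a confidence band
#'
#' The periodic mean variation is significantly different from zero when no
#' horizontal line fits inside the band, i.e. when the largest per-phase
#' lower limit exceeds the smallest per-phase upper limit.  Also reports
#' the percentage of phases whose individual interval excludes zero.
#'
#' @param band a `confidence_band`.
#' @return list with elements `significant` (logical) and
#'   `pct_excluding_zero` (percentage in [0, 100]).
#' @export
significance <- function(band) {
  stopifnot(inherits(band, "confidence_band"))
  list(
    significant = max(band$lower) > min(band$upper),
    pct_excluding_zero = 100 * mean(band$lower > 0 | band$upper < 0)
  )
}

#' Confidence intervals at the band's extreme phases
#'
#' The per-phase interval at the phase where the band centre attains its
#' minimum, and at the phase of its maximum (ties broken by the earliest
#' phase) -- the points of greatest variation from the mean.
#'
#' @param band a `confidence_band`.
#' @return list with `min_range` and `max_range` (each `c(lower, upper)`)
#'   and the corresponding `min_phase`, `max_phase`.
#' @export
band_extremes <- function(band) {
  stopifnot(inherits(band, "confidence_band"))
  imin <- which.min(band$center)
  imax <- which.max(band$center)
  list(
    min_range = c(lower = band$lower[imin], upper = band$upper[imin]),
    max_range = c(lower = band$lower[imax], upper = band$upper[imax]),
    min_phase = band$phase[imin],
    max_phase = band$phase[imax]
  )
}

#' Per-phase width ratio of two confidence bands
#'
#' Compares band widths phase by phase --
#' `(upper - lower)[GSBB] / (upper - lower)[VBPBB]` -- and summarizes the
#' distribution of ratios by its median and quartiles.
#'
#' @param gsbb,vbpbb `confidence_band`s over the same period and phase
#'   grid (conventionally GSBB in the numerator).
#' @return list with `median`, `q1`, `q3` and the per-phase `ratios`.
#' @export
width_ratio <- function(gsbb, vbpbb) {
  stopifnot(inherits(gsbb, "confidence_band"), inherits(vbpbb, "confidence_band"))
  if (attr(gsbb, "period") != attr(vbpbb, "period"))
    stop("bands must share the same period")
  wg <- gsbb$upper - gsbb$lower
  wv <- vbpbb$upper - vbpbb$lower
  if (any(wv <= 0))
    stop("degenerate (zero-width) VBPBB interval; width ratio undefined")
  r <- wg / wv
  qq <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
  list(median = stats::median(r), q1 = qq[1L], q3 = qq[2L], ratios = r)
}

#' Proportion of series variation explained by a component
#'
#' Squared Pearson correlation between a bandpass component and the
#' original series over their joint valid region.
#'
#' @param component a `component_estimate`.
#' @param x the source series.
#' @return squared correlation in [0, 1]; a constant component yields 0
#'   with a warning.
#' @export
r_squared <- function(component, x) {
  stopifnot(inherits(component, "component_estimate"))
  v <- series_values(x)
  if (length(v) != length(component$values))
    stop("`component` and `x` must have the same length")
  ok <- series_valid(component) & is.finite(v)
  if (sum(ok) < 3L) stop("overlapping valid region is empty or too small")
  if (stats::sd(component$values[ok]) == 0) {
    warning("constant component; r_squared defined as 0")
    return(0)
  }
  stats::cor(component$values[ok], v[ok])^2
}

#' Write or read a confidence band as CSV
#'
#' Columns: `phase`, `lower`, `center`, `upper`, `method`, `period`.
#'
#' @param band a `confidence_band`.
#' @param path file path.
#' @return `write_band_csv`: `path` invisibly; `read_band_csv`: a
#'   `confidence_band`.
#' @export
write_band_csv <- function(band, path) {
  stopifnot(inherits(band, "confidence_band"))
  df <- data.frame(phase = band$phase, lower = band$lower,
                   center = band$center, upper = band$upper,
                   method = attr(band, "method"), period = attr(band, "period"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_csv
#' @export
read_band_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "lower", "center", "upper", "method", "period")
  if (!all(need %in% names(df))) stop("not a band CSV: missing columns")
  out <- df[, c("phase", "lower", "center", "upper")]
  structure(out,
            class = c("confidence_band", "data.frame"),
            period = as.integer(df$period[1L]), method = df$method[1L],
            alpha = NA_real_, n_boot = NA_integer_, spec = NULL)
}
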