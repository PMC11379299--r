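#' KZFT filter specification
#'
#' Bundles the three arguments of the Kolmogorov-Zurbenko Fourier Transform
#' bandpass filter: the centre frequency `nu` (cycles per sample), the
#' moving-average window length `m` (odd), and the iteration count `k`.
#' The filter's half-width, `k(m-1)/2` samples, is derived; the first and
#' last `half_width` samples of a filtered series are incompletely averaged.
#'
#' When built from a target `period` p (in samples), `nu = 1/p` and the
#' default window is `m = 2p + 1` (see [window_for_period()]), which places
#' the filter's first transfer-function null halfway to the neighbouring
#' frequencies of interest.
#'
#' @param period target period in samples; used to derive `nu` (and the
#'   default `m`) when `nu` is not given directly.
#' @param nu centre frequency in cycles per sample, in (0, 0.5].
#' @param m odd positive window length; default `2 * round(period) + 1`.
#' @param k positive integer number of filter iterations.  `k = 1` is a
#'   plain moving average; larger `k` approaches a Gaussian kernel and
#'   narrows the energy transfer function.
#' @return an object of class `kzft_spec` with fields `nu`, `m`, `k`,
#'   `half_width`.
#' @examples
#' filter_spec(period = 24)            # daily component, m = 49, k = 2
#' filter_spec(nu = 1 / 24, m = 49, k = 1)
#' @export
filter_spec <- function(period = NULL, nu = NULL, m = NULL, k = 2) {
  if (is.null(nu)) {
    if (is.null(period)) stop("supply either `period` or `nu`")
    period <- round(period)
    if (!is.finite(period) || period < 2) stop("`period` must be at least 2 samples")
    nu <- 1 / period
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0 || nu > 0.5)
    stop("`nu` must be a single frequency in (0, 0.5] cycles per sample")
  if (is.null(m)) {
    if (is.null(period)) period <- round(1 / nu)
    m <- window_for_period(period)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m) || m %% 2 != 1)
    stop("`m` must be an odd positive integer")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  m <- as.integer(m)
  k <- as.integer(k)
  structure(
    list(nu = nu, m = m, k = k, half_width = as.integer(k * (m - 1L) / 2L)),
    class = "kzft_spec"
  )
}

#' @export
print.kzft_spec <- function(x, ...) {
  cat(sprintf("<kzft_spec> nu = %.6g (period %.6g samples), m = %d, k = %d, half-width = %d\n",
              x$nu, 1 / x$nu, x$m, x$k, x$half_width))
  invisible(x)
}

#' Default KZFT window length for a target period
#'
#' Returns `2p + 1` for a period of `p` samples: the smallest odd window
#' whose moving average fully cancels the component of period `p` itself,
#' placing the transfer-function nulls so that neighbouring frequencies of
#' interest are strongly attenuated.  Fractional periods are rounded to the
#' nearest integer first.
#'
#' @param p period in samples, `p >= 1`.
#' @return odd integer window length.
#' @examples
#' window_for_period(24)    # 49
#' window_for_period(8760)  # 17521
#' @export
window_for_period <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1)
    stop("`p` must be a single period >= 1 sample")
  as.integer(2L * as.integer(round(p)) + 1L)
}

#' Iterated moving-average (Kolmogorov-Zurbenko) filter coefficients
#'
#' The KZFT weight vector of order (`m`, `k`): the normalized polynomial
#' coefficients of (1 + z + ... + z^(m-1))^k, i.e. the k-fold
#' self-convolution of the uniform kernel of length `m`.  The `k(m-1)+1`
#' weights are symmetric, strictly positive and sum to one.
#'
#' @param m odd positive integer window length.
#' @param k positive integer iteration count.
#' @return numeric vector of `k(m-1)+1` weights, with an `offsets`
#'   attribute giving the sample offsets `-k(m-1)/2 ... k(m-1)/2`.
#' @examples
#' kz_coefficients(3, 1)  # 1/3 1/3 1/3
#' kz_coefficients(3, 2)  # 1/9 2/9 3/9 2/9 1/9
#' @export
kz_coefficients <- function(m, k) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m) || m %% 2 != 1)
    stop("`m` must be an odd positive integer")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  m <- as.integer(m)
  k <- as.integer(k)
  u <- rep(1 / m, m)
  w <- u
  if (k > 1L) {
    for (i in seq_len(k - 1L)) w <- conv_full(w, u)
  }
  # FFT convolution can leave ~1e-17 residue; restore exact unit sum.
  w <- w / sum(w)
  h <- k * (m - 1L) / 2L
  attr(w, "offsets") <- seq.int(-h, h)
  w
}

# Full (polynomial-product) convolution of two numeric vectors.
conv_full <- function(a, b) {
  if (length(a) == 1L || length(b) == 1L) return(as.numeric(outer(a, b)))
  stats::convolve(a, rev(b), type = "open")
}

# Centered cross-correlation: out[t] = sum_u kern[u + h + 1] * x[t + u],
# for u in -h..h, with x taken as 0 outside its range.
xcorr_centered <- function(x, kern) {
  n <- length(x)
  h <- (length(kern) - 1L) / 2L
  out <- conv_full(x, rev(kern))   # correlation = convolution with reversed kernel
  out[(h + 1L):(h + n)]
}

#' Kolmogorov-Zurbenko Fourier Transform of a series
#'
#' Applies the KZFT bandpass filter: the iterated moving-average weights
#' `a_u/m^k` are modulated by `exp(-2i*pi*nu*u)` and the windowed sum is
#' demodulated by the carrier `exp(-2i*pi*nu*t)`, so the output is the
#' complex envelope of the series' component at frequency `nu`.  For an
#' input `A*cos(2*pi*nu*t + phi)` the output is approximately
#' `(A/2)*exp(1i*phi)` on the valid region; [reconstruct_component()]
#' re-modulates it back to a real bandpass component.
#'
#' Missing interior values are handled by renormalizing the weights over
#' the available in-window samples, provided no more than `max_missing` of
#' the total coefficient mass is missing; otherwise the output sample is
#' flagged invalid.  Window edges are treated the same way: with
#' `edges = "mask"` (default) the first and last `half_width` samples are
#' always flagged invalid, while `edges = "renormalize"` keeps edge samples
#' whose available coefficient mass reaches `1 - max_missing`.
#'
#' @param x series-like object (numeric, [periodic_series()]); `NA` marks
#'   missing samples.
#' @param spec a [filter_spec()].
#' @param edges `"mask"` or `"renormalize"`; see Details.
#' @param max_missing maximum missing coefficient-mass fraction tolerated
#'   inside a window (default 0.2).
#' @return complex vector of the same length as the input with attributes
#'   `valid` (logical mask) and `spec`.
#' @export
kzft_transform <- function(x, spec, edges = c("mask", "renormalize"),
                           max_missing = 0.2) {
  stopifnot(inherits(spec, "kzft_spec"))
  edges <- match.arg(edges)
  v <- series_values(x)
  n <- length(v)
  if (n < 1L) stop("series must contain at least one sample")
  w <- kz_coefficients(spec$m, spec$k)
  u <- attr(w, "offsets")
  h <- spec$half_width

  avail <- is.finite(v)
  v0 <- ifelse(avail, v, 0)
  g <- w * exp(-2i * pi * spec$nu * u)
  num <- complex(
    real      = xcorr_centered(v0, Re(g)),
    imaginary = xcorr_centered(v0, Im(g))
  )
  wsum <- xcorr_centered(as.numeric(avail), w)

  valid <- wsum >= (1 - max_missing) - 1e-12
  if (edges == "mask" && n > 1L) {
    edge <- seq_len(n) <= h | seq_len(n) > n - h
    valid <- valid & !edge
  }
  z <- ifelse(wsum > 0, num / wsum, NA_complex_)
  z[!valid] <- NA_complex_
  z <- z * exp(-2i * pi * spec$nu * (seq_len(n) - 1))

  structure(z, valid = valid, spec = spec, class = "kzft_transform")
}

#' Reconstruct the real bandpass component from a KZFT envelope
#'
#' Re-modulates the complex envelope returned by [kzft_transform()] back to
#' a real-valued oscillation at the filter's centre frequency:
#' `values(t) = 2 * Re(exp(+2i*pi*nu*t) * z(t))`.
#'
#' @param z output of [kzft_transform()].
#' @param spec the same [filter_spec()] used for the transform.
#' @return an object of class `component_estimate`: list with `values`
#'   (numeric, `NA` where invalid), `valid` (logical) and `spec`.
#' @export
reconstruct_component <- function(z, spec) {
  zspec <- attr(z, "spec")
  if (is.null(zspec)) stop("`z` must be produced by kzft_transform()")
  stopifnot(inherits(spec, "kzft_spec"))
  if (!isTRUE(all.equal(zspec$nu, spec$nu)) || zspec$m != spec$m || zspec$k != spec$k)
    stop("`spec` does not match the specification `z` was computed with")
  n <- length(z)
  vals <- 2 * Re(exp(2i * pi * spec$nu * (seq_len(n) - 1)) * as.complex(z))
  valid <- attr(z, "valid")
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, spec = spec),
            class = "component_estimate")
}

#' @export
print.component_estimate <- function(x, ...) {
  cat(sprintf("<component_estimate> %d samples at nu = %.6g (m = %d, k = %d); %d valid\n",
              length(x$values), x$spec$nu, x$spec$m, x$spec$k, sum(x$valid)))
  invisible(x)
}

#' Bandpass-filter a series into one periodic component
#'
#' Convenience wrapper: [kzft_transform()] followed by
#' [reconstruct_component()].
#'
#' @inheritParams kzft_transform
#' @param ... passed to [kzft_transform()] (`edges`, `max_missing`).
#' @return a `component_estimate`.
#' @examples
#' x <- cos(2 * pi * (0:999) / 24)
#' comp <- kzft_component(x, filter_spec(period = 24, k = 2))
#' @export
kzft_component <- function(x, spec, ...) {
  reconstruct_component(kzft_transform(x, spec, ...), spec)
}

#' Energy transfer function of a KZFT filter
#'
#' The gain `|sum_u w_u exp(-2i*pi*(f - nu)*u)|` of the filter at each
#' input frequency `f`.  Equals 1 at `f = nu` and, because the iterated
#' kernel's transfer function is the k-th power of the single moving
#' average's Dirichlet kernel, is non-increasing in `k` at any fixed
#' `f != nu`.
#'
#' @param spec a [filter_spec()].
#' @param freqs frequencies in cycles per sample, within [0, 0.5].
#' @return numeric vector of gains in [0, 1].
#' @export
transfer_function <- function(spec, freqs) {
  stopifnot(inherits(spec, "kzft_spec"))
  if (!is.numeric(freqs) || any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 0.5))
    stop("`freqs` must lie within [0, 0.5] cycles per sample")
  w <- kz_coefficients(spec$m, spec$k)
  u <- attr(w, "offsets")
  vapply(freqs, function(f) {
    Mod(sum(w * exp(-2i * pi * (f - spec$nu) * u)))
  }, numeric(1))
}
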