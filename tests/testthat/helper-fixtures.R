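# Shared helpers: independent oracles and small constructors used across
# the test files.

# O(L^2) direct polynomial-product convolution, independent of the FFT path
# used inside the package.
loop_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# k-fold self-convolution of the uniform kernel of length m (coefficient
# oracle).
kz_coef_oracle <- function(m, k) {
  u <- rep(1 / m, m)
  w <- u
  if (k > 1) for (i in seq_len(k - 1)) w <- loop_conv(w, u)
  w
}

# Direct windowed-summation KZFT oracle with missing-value renormalization,
# mirroring the documented contract sample by sample.
direct_kzft <- function(x, spec, edges = "mask", max_missing = 0.2) {
  n <- length(x)
  w <- kz_coef_oracle(spec$m, spec$k)
  h <- spec$half_width
  u <- seq.int(-h, h)
  z <- rep(NA_complex_, n)
  valid <- logical(n)
  for (t in seq_len(n)) {
    idx <- t + u
    inr <- idx >= 1 & idx <= n
    av <- inr
    av[inr] <- !is.na(x[idx[inr]])
    W <- sum(w[av])
    ok <- W >= (1 - max_missing) - 1e-12
    if (edges == "mask" && (t <= h || t > n - h)) ok <- FALSE
    if (ok) {
      valid[t] <- TRUE
      z[t] <- exp(-2i * pi * spec$nu * (t - 1)) *
        sum(w[av] * exp(-2i * pi * spec$nu * u[av]) * x[idx[av]]) / W
    }
  }
  list(z = z, valid = valid)
}

# Least-squares amplitude/phase of a sinusoid at a known period: the
# recovery oracle for bandpass reconstruction.
ls_sinusoid_fit <- function(values, period, t = seq_along(values) - 1) {
  ok <- is.finite(values)
  cc <- cos(2 * pi * t[ok] / period)
  ss <- sin(2 * pi * t[ok] / period)
  fit <- stats::lm(values[ok] ~ cc + ss - 1)
  b <- stats::coef(fit)
  list(amplitude = sqrt(sum(b^2)), phase = atan2(-b[[2]], b[[1]]))
}

# Hand-built confidence band for unit-testing the band summaries.
make_band <- function(lower, center, upper, period = length(center),
                      method = "VBPBB") {
  structure(
    data.frame(phase = seq_along(center) - 1L, lower = lower,
               center = center, upper = upper),
    class = c("confidence_band", "data.frame"),
    period = as.integer(period), method = method, alpha = 0.05,
    n_boot = NA_integer_, spec = NULL
  )
}

# Desk-scale analogue of the default synthetic spec: the study's component
# structure with the annual period shortened to 720 samples so whole
# pipelines run in seconds (the period scaling convention is documented in
# the methods vignette).
desk_spec <- function(n = 20000, annual_amplitude = 6, seed = 7, ...) {
  synthetic_spec(
    n = n,
    components = data.frame(
      label = c("annual", "daily", "daily_harmonic", "weekly"),
      period = c(720, 24, 12, 168),
      amplitude = c(annual_amplitude, 3, 1.5, 1),
      phase = c(0, -2 * pi * 8 / 24, 0, 0)
    ),
    seed = seed,
    ...
  )
}
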