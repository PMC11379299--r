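test_that("periodic mean returns per-phase deviations from the grand mean", {
  pm <- periodic_mean(c(1, 2, 3, 1, 2, 3), 3)
  expect_equal(as.numeric(pm), c(-1, 0, 1))
  expect_equal(attr(pm, "grand_mean"), 2)
  expect_equal(attr(pm, "counts"), c(2L, 2L, 2L))
  expect_equal(as.numeric(periodic_mean(rep(7, 30), 5)), rep(0, 5))
  x <- c(1, NA, 3, 1, NA, 3)
  expect_error(periodic_mean(x, 3), "phase 1")
})

test_that("GSBB resampling preserves phase and degenerates correctly", {
  # only one admissible block when the block spans the whole series
  x <- rnorm(24)
  cfg <- bootstrap_config(seed = 3, circular = FALSE, block_length = 24)
  expect_identical(gsbb_resample(x, 4, cfg), x)

  # every resampled value comes from a source position of the same phase
  xu <- seq_len(40) * 10
  for (s in 1:4) {
    r <- gsbb_resample(xu, 5, bootstrap_config(seed = s))
    src <- match(r, xu)
    expect_true(all((src - seq_along(src)) %% 5 == 0))
  }

  # an exactly periodic series has invariant per-phase means
  xp <- rep(c(1, 5, 2, 8), 6)
  base <- periodic_mean(xp, 4)
  for (s in 1:5) {
    r <- gsbb_resample(xp, 4, bootstrap_config(seed = s))
    expect_equal(as.numeric(periodic_mean(r, 4)), as.numeric(base))
  }

  expect_error(gsbb_resample(rnorm(10), 20), "exceeds")
  expect_error(gsbb_resample(rnorm(10), 7), "twice the period")
})

test_that("period 1 reduces to the ordinary moving block bootstrap", {
  xu <- seq_len(30)
  r <- gsbb_resample(xu, 1, bootstrap_config(seed = 2, block_length = 5))
  expect_length(r, 30)
  src <- match(r, xu)
  # blocks of 5 are contiguous in the source
  for (b in seq(1, 30, by = 5)) {
    expect_equal(diff(src[b:(b + 4)]) %% 30, rep(1, 4))
  }
})

test_that("a noise-free periodic series yields a degenerate band on the pattern", {
  t <- 0:2399
  A <- 3
  x <- A * cos(2 * pi * t / 24)
  vb <- band_from_bootstrap(x, 24, bootstrap_config(n_boot = 200, seed = 1),
                            method = "VBPBB")
  expect_lt(max(vb$upper - vb$lower), 0.01 * A)
  expect_equal(vb$center, A * cos(2 * pi * (0:23) / 24), tolerance = 0.01)
  expect_true(all(vb$lower <= vb$center + 1e-8 & vb$center <= vb$upper + 1e-8))
})

test_that("bands are nested across confidence levels and reproducible by seed", {
  set.seed(9)
  x <- rnorm(2000) + cos(2 * pi * (0:1999) / 20)
  wide <- band_from_bootstrap(x, 20, bootstrap_config(n_boot = 300, seed = 4),
                              method = "GSBB")
  tight <- band_from_bootstrap(x, 20, bootstrap_config(n_boot = 300, seed = 4,
                                                       alpha = 0.5),
                               method = "GSBB")
  expect_true(all(tight$lower > wide$lower))
  expect_true(all(tight$upper < wide$upper))

  again <- band_from_bootstrap(x, 20, bootstrap_config(n_boot = 300, seed = 4),
                               method = "GSBB")
  expect_identical(wide$lower, again$lower)
  expect_identical(wide$upper, again$upper)
})

test_that("the horizontal-line criterion reads the band geometry", {
  sig <- significance(make_band(lower = c(-1, 2), center = c(-0.5, 2.5),
                                upper = c(0, 3)))
  expect_true(sig$significant)      # max lower 2 > min upper 0
  expect_equal(sig$pct_excluding_zero, 50)
  flat <- significance(make_band(lower = c(-1, -1), center = c(0, 0),
                                 upper = c(1, 1)))
  expect_false(flat$significant)    # the zero line fits
  expect_equal(flat$pct_excluding_zero, 0)
})

test_that("band extremes report the intervals at the extreme centre phases", {
  b <- make_band(lower = c(-3, -1, 4), center = c(-2, 0, 5), upper = c(-1, 1, 6))
  ex <- band_extremes(b)
  expect_equal(unname(ex$min_range), c(-3, -1))
  expect_equal(unname(ex$max_range), c(4, 6))
  # constant centre: ties resolve to the earliest phase
  bc <- make_band(lower = rep(-1, 4), center = rep(0, 4), upper = rep(1, 4))
  exc <- band_extremes(bc)
  expect_equal(exc$min_phase, 0)
  expect_equal(exc$max_phase, 0)
  # a sinusoidal centre has extremes half a period apart
  ph <- 0:23
  bs <- make_band(lower = cos(2 * pi * ph / 24) - 1, center = cos(2 * pi * ph / 24),
                  upper = cos(2 * pi * ph / 24) + 1)
  exs <- band_extremes(bs)
  expect_equal(abs(exs$max_phase - exs$min_phase), 12)
})

test_that("width ratios summarize per-phase band width comparisons", {
  g <- make_band(lower = c(-2, -3), center = c(0, 0), upper = c(2, 3),
                 method = "GSBB")
  v <- make_band(lower = c(-0.5, -1), center = c(0, 0), upper = c(0.5, 1))
  wr <- width_ratio(g, v)
  expect_equal(wr$ratios, c(4, 3))
  expect_equal(wr$median, 3.5)
  expect_equal(width_ratio(g, g)$median, 1)
  degenerate <- make_band(lower = c(0, 0), center = c(0, 0), upper = c(0, 0))
  expect_error(width_ratio(g, degenerate), "degenerate")
})

test_that("r_squared measures the variance share of a component", {
  set.seed(12)
  x <- rnorm(500)
  full <- structure(list(values = x - mean(x), valid = rep(TRUE, 500),
                         spec = filter_spec(period = 10)),
                    class = "component_estimate")
  expect_equal(r_squared(full, x), 1)
  ortho <- structure(list(values = sin(2 * pi * (0:499) / 10),
                          valid = rep(TRUE, 500),
                          spec = filter_spec(period = 10)),
                     class = "component_estimate")
  expect_lt(r_squared(ortho, x), 0.05)
  const <- structure(list(values = rep(2, 500), valid = rep(TRUE, 500),
                          spec = filter_spec(period = 10)),
                     class = "component_estimate")
  expect_warning(r2 <- r_squared(const, x), "constant")
  expect_equal(r2, 0)
})

test_that("VBPBB bands cover the true periodic pattern", {
  n_rep <- 20
  cover <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    spc <- synthetic_spec(n = 4800, grand_mean = 10, trend_slope = 0,
                          components = data.frame(label = "cycle", period = 48,
                                                  amplitude = 3, phase = 0.4),
                          noise_sd = 4, ar1_rho = 0, missing_rate = 0,
                          n_coded_errors = 0, seed = 700 + i)
    x <- synthetic_series(spc)
    vb <- band_from_bootstrap(x, 48, bootstrap_config(n_boot = 200, seed = 700 + i),
                              method = "VBPBB")
    tr <- true_periodic_mean(spc, 48)
    cover[i] <- mean(tr >= vb$lower & tr <= vb$upper)
  }
  expect_gte(mean(cover), 0.90)
})

test_that("band width shrinks as the noise level drops", {
  widths <- vapply(c(8, 4, 2, 1), function(sdv) {
    spc <- synthetic_spec(n = 4800, grand_mean = 10, trend_slope = 0,
                          components = data.frame(label = "cycle", period = 48,
                                                  amplitude = 3, phase = 0),
                          noise_sd = sdv, ar1_rho = 0, missing_rate = 0,
                          n_coded_errors = 0, seed = 55)
    x <- synthetic_series(spc)
    vb <- band_from_bootstrap(x, 48, bootstrap_config(n_boot = 200, seed = 55),
                              method = "VBPBB")
    stats::median(vb$upper - vb$lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("VBPBB refuses a series with no filterable interior", {
  expect_error(
    band_from_bootstrap(rnorm(100), 48, bootstrap_config(n_boot = 100, seed = 1),
                        method = "VBPBB"),
    "insufficient valid data"
  )
})

test_that("band CSV round-trips", {
  x <- rnorm(2000) + cos(2 * pi * (0:1999) / 20)
  b <- band_from_bootstrap(x, 20, bootstrap_config(n_boot = 150, seed = 8),
                           method = "GSBB")
  path <- tempfile(fileext = ".csv")
  write_band_csv(b, path)
  back <- read_band_csv(path)
  expect_equal(back$lower, b$lower)
  expect_equal(back$center, b$center)
  expect_equal(back$upper, b$upper)
  expect_identical(attr(back, "period"), attr(b, "period"))
  expect_identical(attr(back, "method"), "GSBB")
  unlink(path)
})
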