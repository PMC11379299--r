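test_that("filter coefficients match hand expansion and reject bad parameters", {
  expect_equal(as.numeric(kz_coefficients(3, 1)), rep(1 / 3, 3))
  # (1 + z + z^2)^2 = 1 + 2z + 3z^2 + 2z^3 + z^4, divided by 9
  expect_equal(as.numeric(kz_coefficients(3, 2)), c(1, 2, 3, 2, 1) / 9)
  expect_error(kz_coefficients(4, 1), "odd")
  expect_error(kz_coefficients(-3, 1), "odd")
  expect_error(kz_coefficients(3, 0), "positive")
})

test_that("coefficients equal iterated self-convolution of the uniform kernel", {
  for (m in c(3, 7, 15)) {
    for (k in 1:3) {
      w <- kz_coefficients(m, k)
      expect_length(w, k * (m - 1) + 1)
      expect_equal(as.numeric(w), kz_coef_oracle(m, k), tolerance = 1e-12)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_equal(as.numeric(w), rev(as.numeric(w)))   # symmetry
      expect_true(all(w > 0))
    }
  }
})

test_that("window rule doubles the period and adds one", {
  expect_identical(window_for_period(24), 49L)
  expect_identical(window_for_period(168), 337L)
  expect_identical(window_for_period(8760), 17521L)
  expect_identical(window_for_period(23.6), 49L)   # rounded first
  expect_error(window_for_period(0.5), ">= 1")
})

test_that("transfer function is 1 at the centre and matches the Dirichlet form", {
  sp <- filter_spec(period = 24, m = 49, k = 1)
  expect_equal(transfer_function(sp, 1 / 24), 1)
  f <- seq(0, 0.5, by = 1e-3)
  got <- transfer_function(sp, f)
  delta <- f - 1 / 24
  expected <- abs(sin(pi * 49 * delta) / (49 * sin(pi * delta)))
  expected[abs(delta) < 1e-12] <- 1
  expect_equal(got, expected, tolerance = 1e-10)
  # first null of the moving average at |f - nu| = 1/m
  expect_lt(transfer_function(sp, 1 / 24 + 1 / 49), 1e-12)
  expect_error(transfer_function(sp, 0.6), "0.5")
})

test_that("iterating the filter never increases off-centre gain", {
  f <- seq(0, 0.5, by = 1e-3)
  g1 <- transfer_function(filter_spec(period = 24, m = 49, k = 1), f)
  g2 <- transfer_function(filter_spec(period = 24, m = 49, k = 2), f)
  g3 <- transfer_function(filter_spec(period = 24, m = 49, k = 3), f)
  expect_true(all(g2 <= g1 + 1e-12))
  expect_true(all(g3 <= g2 + 1e-12))
  # iterated transfer is the k-th power of the k = 1 transfer
  expect_equal(g2, g1^2, tolerance = 1e-10)
})

test_that("transform equals direct windowed summation, including gaps and edges", {
  set.seed(101)
  x <- rnorm(80)
  x[c(12, 13, 40)] <- NA
  sp <- filter_spec(period = 8, m = 9, k = 2)
  for (edges in c("mask", "renormalize")) {
    z <- kzft_transform(x, sp, edges = edges)
    ref <- direct_kzft(x, sp, edges = edges)
    expect_identical(attr(z, "valid"), ref$valid)
    ok <- ref$valid
    expect_lt(max(Mod(as.complex(z)[ok] - ref$z[ok])), 1e-10)
  }
  # heavy local missingness voids the window
  y <- rnorm(60)
  y[20:28] <- NA
  zy <- kzft_transform(y, filter_spec(period = 6, m = 7, k = 2))
  expect_false(any(attr(zy, "valid")[22:26]))
})

test_that("transform is linear, kills constants off-band, and maps zero to zero", {
  sp <- filter_spec(period = 24, k = 2)
  set.seed(5)
  x <- rnorm(600); y <- rnorm(600)
  zx <- as.complex(kzft_transform(x, sp))
  zy <- as.complex(kzft_transform(y, sp))
  zc <- as.complex(kzft_transform(2 * x - 3 * y, sp))
  ok <- attr(kzft_transform(x, sp), "valid")
  expect_equal(zc[ok], 2 * zx[ok] - 3 * zy[ok], tolerance = 1e-10)
  # constants live at frequency 0, far outside the passband
  z0 <- kzft_transform(rep(10, 600), sp)
  expect_lt(max(Mod(as.complex(z0)[attr(z0, "valid")])), 0.05 * 10)
  zz <- kzft_transform(rep(0, 600), sp)
  expect_equal(max(Mod(as.complex(zz)[attr(zz, "valid")])), 0)
})

test_that("bandpass reconstruction recovers a noisy sinusoid's amplitude and phase", {
  set.seed(42)
  n <- 4800; t <- 0:(n - 1)
  A <- 2.5; phi <- 0.7
  x <- A * cos(2 * pi * t / 24 + phi) + rnorm(n, sd = 1)
  comp <- kzft_component(x, filter_spec(period = 24, k = 2))
  fit <- ls_sinusoid_fit(comp$values, 24)
  expect_lt(abs(fit$amplitude - A) / A, 0.10)
  expect_lt(abs(fit$phase - phi), 0.1)
  # pure sinusoid: amplitude error below 5%
  comp0 <- kzft_component(A * cos(2 * pi * t / 24 + phi), filter_spec(period = 24, k = 2))
  fit0 <- ls_sinusoid_fit(comp0$values, 24)
  expect_lt(abs(fit0$amplitude - A) / A, 0.05)
})

test_that("a neighbouring frequency is strongly attenuated", {
  n <- 6000; t <- 0:(n - 1)
  x <- 2 * cos(2 * pi * t / 24) + 2 * cos(2 * pi * t / 168)
  # daily target with the window sized for daily/weekly separation
  comp <- kzft_component(x, filter_spec(nu = 1 / 24, m = 337, k = 2))
  leak <- ls_sinusoid_fit(comp$values, 168)
  expect_lt(leak$amplitude / 2, 0.10)
  daily <- ls_sinusoid_fit(comp$values, 24)
  expect_lt(abs(daily$amplitude - 2) / 2, 0.05)
})

test_that("edge handling masks or renormalizes the incomplete windows", {
  x <- rnorm(300)
  sp <- filter_spec(period = 12, m = 25, k = 2)
  h <- sp$half_width
  zm <- kzft_transform(x, sp, edges = "mask")
  vm <- attr(zm, "valid")
  expect_identical(which(!vm), c(seq_len(h), (300 - h + 1):300))
  zr <- kzft_transform(x, sp, edges = "renormalize")
  vr <- attr(zr, "valid")
  expect_gt(sum(vr), sum(vm))
  # interior values are unchanged by the edge mode
  expect_equal(as.complex(zm)[vm], as.complex(zr)[vm])
})

test_that("reconstruction validates its spec and respects zero input", {
  x <- rnorm(200)
  sp <- filter_spec(period = 12, k = 2)
  z <- kzft_transform(x, sp)
  expect_error(reconstruct_component(z, filter_spec(period = 12, k = 3)),
               "does not match")
  z0 <- kzft_transform(rep(0, 200), sp)
  comp0 <- reconstruct_component(z0, sp)
  expect_equal(max(abs(comp0$values[comp0$valid])), 0)
})
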