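test_that("harmonic decomposition follows the Fourier-series convention", {
  t <- 0:449
  const <- harmonic_decomposition(uniform_series(rep(3.5, 450)))
  expect_equal(const$a0_mean, 3.5)
  expect_equal(const$harmonics$amp, rep(0, 4), tolerance = 1e-12)

  cosine <- harmonic_decomposition(uniform_series(10 * cos(2 * pi * t / 450)))
  expect_equal(cosine$harmonics$amp[1], 5, tolerance = 1e-9)
  expect_equal(cosine$harmonics$amp[2:4], rep(0, 3), tolerance = 1e-9)
  expect_equal(cosine$f1, 1 / 450)

  # third harmonic lands at h = 3 regardless of phase
  mixed <- harmonic_decomposition(uniform_series(4 * sin(2 * pi * 3 * t / 450 + 1)))
  expect_equal(mixed$harmonics$amp[3], 2, tolerance = 1e-9)

  expect_error(harmonic_decomposition(uniform_series(rep(1, 300)), period = 450),
               "one period")
})

test_that("truncated reconstruction with factor 2 recovers a band-limited signal", {
  t <- 0:449
  x <- 600 + 30 * cos(2 * pi * t / 450) + 12 * sin(2 * pi * 4 * t / 450)
  d <- harmonic_decomposition(uniform_series(x), H = 4)
  rec <- d$a0_mean
  for (i in 1:4) {
    hh <- d$harmonics
    rec <- rec + 2 * (hh$A[i] * cos(2 * pi * i * t / 450) +
                      hh$B[i] * sin(2 * pi * i * t / 450))
  }
  expect_equal(rec, x, tolerance = 1e-9)
})

test_that("a memoryless system has flat gain and MNG = 100%", {
  wr <- std_protocol()
  k <- 9.5  # ml/min per W
  scaled <- uniform_series(k * wr$values)
  fit <- mng_fit(scaled, wr)
  expect_equal(unname(coef(fit)[1:3]), rep(k, 3), tolerance = 1e-9)
  expect_equal(fit$mng, 100, tolerance = 1e-9)
  expect_equal(mean_gain(fit$profile), k, tolerance = 1e-9)
})

test_that("MNG is invariant to affine transforms of the output", {
  wr <- std_protocol()
  y <- first_order_response(wr, first_order_params(300, 700, 25))
  ref <- mng_fit(y, wr)$mng
  shifted <- uniform_series(y$values + 250)
  expect_equal(mng_fit(shifted, wr)$mng, ref, tolerance = 1e-9)
  scaled <- uniform_series(3.2 * y$values)
  expect_equal(mng_fit(scaled, wr)$mng, ref, tolerance = 1e-9)
})

test_that("gain profile rejects mismatched or degenerate inputs", {
  wr <- std_protocol()
  in_dec <- harmonic_decomposition(uniform_series(wr$values))
  flat <- harmonic_decomposition(uniform_series(rep(500, 450)))
  expect_error(gain_profile(flat, in_dec), "zero input amplitude")
  other <- harmonic_decomposition(uniform_series(rep(1:2, 150)))
  expect_error(gain_profile(other, in_dec), "fundamental")
})

test_that("mean_gain averages absolute gains over the requested harmonics", {
  wr <- std_protocol()
  fit <- mng_fit(uniform_series(4 * wr$values), wr)
  expect_equal(mean_gain(fit$profile, 2:4), 4, tolerance = 1e-9)
  expect_equal(mean_gain(fit$profile, 1:2), 4, tolerance = 1e-9)
  expect_error(mean_gain(fit$profile, integer(0)), "non-empty")
  expect_error(mean_gain(fit$profile, 2:9), "outside")
})

test_that("closed-form MNG has the right limits, monotonicity and range", {
  expect_equal(analytic_mng(1e-9), 100, tolerance = 1e-6)
  expect_equal(analytic_mng(1e7), 100 * mean(1 / (2:4)), tolerance = 1e-3)
  grid <- analytic_mng(10^seq(-3, 3.2, length.out = 200))
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 100 * mean(1 / (2:4)) & grid <= 100))
  expect_error(analytic_mng(0), "> 0")
})

test_that("mng_fit accepts raw breath records", {
  wr <- std_protocol()
  y <- first_order_response(wr, first_order_params(300, 700, 20))
  # pad the periodic signal so breaths cover the full analysis grid
  ypad <- pad_periodic(y, 12)
  b <- breath_sample(ypad, interval_jitter = 0.15, noise_sd = 0, seed = 3)
  fit_b <- mng_fit(b, wr)
  fit_u <- mng_fit(y, wr)
  expect_lt(abs(fit_b$mng - fit_u$mng), 1)
})
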