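test_that("constant input drives the output to its steady state", {
  high <- prbs_protocol(rep(1L, 15))
  y <- first_order_response(high, first_order_params(300, 700, 15))
  expect_equal(y$values, rep(1000, 450), tolerance = 1e-8)
  low <- prbs_protocol(rep(0L, 15))
  y0 <- first_order_response(low, first_order_params(300, 700, 15))
  expect_equal(y0$values, rep(300, 450), tolerance = 1e-8)
})

test_that("final period equals the brute-force convolution of input with the impulse response", {
  wr <- std_protocol()
  for (tau in c(8, 34)) {
    p <- first_order_params(280, 720, tau)
    y <- first_order_response(wr, p)$values
    # oracle: discrete convolution with the ZOH-sampled impulse response over
    # a long (12-period) history, so the initial condition has fully decayed
    nwarm <- 12L
    u <- rep(wr$values, nwarm + 1L)
    G <- p$a1 / (wr$high - wr$low)
    drive <- G * (u - wr$low)
    al <- exp(-wr$dt / tau)
    J <- length(u) - 1L
    h <- (1 - al) * al^(0:(J - 1))
    N <- length(wr$values)
    idx <- (nwarm * N + 1L):((nwarm + 1L) * N)
    conv <- vapply(idx, function(k) {
      j <- seq_len(min(k - 1L, J))          # y(k) responds to u up to k-1
      p$a0 + sum(h[j] * drive[k - j])
    }, 1)
    expect_equal(y, conv, tolerance = 1e-6)
  }
})

test_that("warm-up beyond the default changes the returned period negligibly", {
  wr <- std_protocol()
  p <- first_order_params(300, 700, 100)
  y2 <- first_order_response(wr, p, n_warmup_periods = 2)$values
  y8 <- first_order_response(wr, p, n_warmup_periods = 8)$values
  expect_lt(max(abs(y2 - y8)) / max(abs(y8)), 1e-6)
})

test_that("a pure delay shifts the response whether or not it is a whole sample", {
  wr <- step_protocol()
  y0 <- first_order_response(wr, first_order_params(300, 700, 20, td = 0))$values
  y5 <- first_order_response(wr, first_order_params(300, 700, 20, td = 5))$values
  # integer delay of a periodic steady-state cycle is a circular shift
  expect_equal(y5, y0[((seq_len(450) - 1 - 5) %% 450) + 1], tolerance = 1e-9)
  # fractional delay lies between the bracketing integer shifts
  y55 <- first_order_response(wr, first_order_params(300, 700, 20, td = 5.5))$values
  y6 <- first_order_response(wr, first_order_params(300, 700, 20, td = 6))$values
  mid <- (y5 + y6) / 2
  expect_lt(max(abs(y55 - mid)), max(abs(y5 - y6)))
})

test_that("breath sampling is reproducible and recovers the signal when noiseless", {
  wr <- std_protocol()
  y <- first_order_response(wr, first_order_params(300, 700, 30))
  b1 <- breath_sample(y, seed = 42)
  b2 <- breath_sample(y, seed = 42)
  expect_identical(b1$times, b2$times)
  expect_identical(b1$vo2, b2$vo2)
  b3 <- breath_sample(y, seed = 43)
  expect_false(identical(b3$times, b1$times))
  # jitter = 0, noise = 0: interpolation round trip
  b0 <- breath_sample(y, mean_breath_interval = 3, interval_jitter = 0,
                      noise_sd = 0, seed = 1)
  yi <- interpolate_1s(b0, grid_start = 3, grid_end = 447)
  truth <- y$values[4:448]
  expect_lt(max(abs(yi$values - truth)), 25)   # linear-interp error across 3-s gaps
  expect_lt(mean(abs(yi$values - truth)), 5)
})

test_that("empirical breath-noise sd matches the requested noise_sd", {
  wr <- std_protocol()
  y <- first_order_response(wr, first_order_params(300, 700, 30))
  res <- unlist(lapply(1:50, function(s) {
    b <- breath_sample(y, interval_jitter = 0, noise_sd = 100, seed = s)
    truth <- approx(series_time(y), y$values, xout = b$times)$y
    b$vo2 - truth
  }))
  expect_equal(sd(res), 100, tolerance = 0.03)
})

test_that("invalid simulation and sampling parameters are rejected", {
  wr <- std_protocol()
  expect_error(first_order_params(300, 700, tau_s = 0), "tau")
  expect_error(first_order_params(300, -1, 15), "a1")
  expect_error(breath_sample(uniform_series(1), 3), ">= 2 samples")
  expect_error(breath_sample(first_order_response(wr, first_order_params(300, 700, 15)),
                             mean_breath_interval = 0), "> 0")
})

test_that("the in-silico study agrees with the closed-form first-order oracle", {
  tab <- run_insilico_study()
  expect_equal(nrow(tab), 10)
  for (i in seq_len(nrow(tab)))
    expect_lt(abs(tab$mng[i] - analytic_mng(tab$tau_s[i])), 1)
  # steady-state gain recovered at the fundamental within the sweep
  expect_true(all(tab$mean_gain > 0))
})
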