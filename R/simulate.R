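#' First-order VO2 response parameters
#'
#' Parameter set for the first-order (mono-exponential) VO2 model used by the
#' in-silico engine: baseline `a0` at the low work rate, steady-state
#' amplitude `a1` from the low to the high level, time constant `tau_s`, and
#' an optional pure transport delay `td` (0 for the muscular response).
#'
#' @param a0 baseline VO2 at the low level (ml·min^-1).
#' @param a1 low-to-high steady-state amplitude (ml·min^-1), >= 0.
#' @param tau_s time constant (s), > 0.
#' @param td pure delay (s), >= 0 (default 0).
#' @return list of class `first_order_params`.
#' @export
first_order_params <- function(a0, a1, tau_s, td = 0) {
  if (!is.finite(tau_s) || tau_s <= 0) stop("'tau_s' must be > 0")
  if (!is.finite(a1) || a1 < 0) stop("'a1' must be >= 0")
  if (!is.finite(td) || td < 0) stop("'td' must be >= 0")
  structure(list(a0 = a0, a1 = a1, tau_s = tau_s, td = td),
            class = "first_order_params")
}

#' @export
print.first_order_params <- function(x, ...) {
  cat(sprintf("<first_order_params> a0 = %g, a1 = %g ml/min; tau = %g s; td = %g s\n",
              x$a0, x$a1, x$tau_s, x$td))
  invisible(x)
}

# Exact zero-order-hold integration of dy/dt = (g(t) - y)/tau where
# g(t) = a0 + G * (u(t - td) - low) and u is piecewise constant per sample.
# Each dt step is split at the (delayed) input switch when td is not a
# multiple of dt, so the update is exact, not an Euler approximation.
zoh_simulate <- function(u, dt, a0, G, low, tau, td = 0, y0 = NULL) {
  n <- length(u)
  target <- a0 + G * (u - low)
  if (is.null(y0)) y0 <- target[1L]
  y <- numeric(n)
  if (td == 0 || abs(td / dt - round(td / dt)) < 1e-9) {
    # delay is a whole number of samples: shift the target sequence
    s <- round(td / dt)
    tg <- if (s == 0) target else c(rep(target[1L], s), target[seq_len(n - s)])
    al <- exp(-dt / tau)
    yk <- y0
    for (k in seq_len(n)) {
      y[k] <- yk
      yk <- tg[k] + (yk - tg[k]) * al
    }
  } else {
    # fractional delay: the delayed input switches inside each step
    frac <- td / dt - floor(td / dt)
    l1 <- frac * dt           # first sub-step uses the earlier input sample
    l2 <- dt - l1
    a1e <- exp(-l1 / tau); a2e <- exp(-l2 / tau)
    idx0 <- floor(-td / dt + seq_len(n) - 1)   # delayed bin at step start
    yk <- y0
    for (k in seq_len(n)) {
      y[k] <- yk
      j <- idx0[k]
      g1 <- target[max(j, 0L) + 1L]
      g2 <- target[min(max(j + 1L, 0L), n - 1L) + 1L]
      yk <- g1 + (yk - g1) * a1e
      yk <- g2 + (yk - g2) * a2e
    }
  }
  y
}

#' Simulate the first-order VO2 response to a PRBS protocol
#'
#' Integrates `dy/dt = (a0 + G (u(t - td) - low) - y) / tau` with the exact
#' zero-order-hold (piecewise-exponential) update, where
#' `G = a1 / (high - low)` is the static gain in ml·min^-1·W^-1. The system
#' is run for `n_warmup_periods` discarded periods plus one returned period,
#' mirroring the warm-up sequence discarded in PRBS testing; for long time
#' constants the warm-up is extended automatically until the returned period
#' is periodic to within 1e-6 relative.
#'
#' @param protocol a [prbs_protocol()] object (>= 1 period).
#' @param params a [first_order_params()] object.
#' @param n_warmup_periods discarded warm-up periods (default 2).
#' @return `uniform_series` holding the final period (steady-state cycle) at
#'   the protocol's sampling grid, `t0 = 0`. Steady state maps the low level
#'   to `a0` and the high level to `a0 + a1`.
#' @examples
#' wr <- prbs_protocol(generate_msequence())
#' y <- first_order_response(wr, first_order_params(300, 700, 15))
#' range(y$values)
#' @export
first_order_response <- function(protocol, params, n_warmup_periods = 2L) {
  stopifnot(inherits(protocol, "work_rate_series"))
  if (!inherits(params, "first_order_params"))
    params <- do.call(first_order_params, as.list(params))
  if (n_warmup_periods < 1L) stop("'n_warmup_periods' must be >= 1")
  dt <- protocol$dt
  u1 <- protocol_period(protocol)
  N <- length(u1)
  G <- params$a1 / (protocol$high - protocol$low)
  nw <- as.integer(n_warmup_periods)
  # transient decays like exp(-period/tau) per period; pre-extend for slow systems
  nw <- max(nw, ceiling(14 * params$tau_s / protocol$period_s))
  repeat {
    u <- rep(u1, nw + 1L)
    y <- zoh_simulate(u, dt, params$a0, G, protocol$low,
                      params$tau_s, params$td)
    last <- y[(nw * N + 1L):((nw + 1L) * N)]
    prev <- y[((nw - 1L) * N + 1L):(nw * N)]
    if (max(abs(last - prev)) <= 1e-6 * max(abs(last)) || nw >= 512L) break
    nw <- nw * 2L
  }
  uniform_series(last, t0 = 0, dt = dt)
}

#' Sample a uniform signal as noisy breath-by-breath data
#'
#' Measurement model for synthetic data: breath end-times are drawn
#' sequentially with log-normal intervals of the stated mean and coefficient
#' of variation, and each breath's VO2 is the signal value at that time plus
#' i.i.d. Gaussian noise (level-independent, truncated at zero since a
#' negative uptake cannot be measured).
#'
#' @param signal a `uniform_series` (e.g. a simulated response).
#' @param mean_breath_interval mean breath-to-breath interval (s), default 3.
#' @param interval_jitter coefficient of variation of the interval
#'   (dimensionless, default 0.2; 0 gives a regular grid).
#' @param noise_sd standard deviation of the additive breath noise
#'   (ml·min^-1, default 0).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return a [breath_series()] spanning the signal support.
#' @export
breath_sample <- function(signal, mean_breath_interval = 3,
                          interval_jitter = 0.2, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(signal, "uniform_series"))
  if (length(signal$values) < 2L) stop("'signal' must have >= 2 samples")
  if (mean_breath_interval <= 0) stop("'mean_breath_interval' must be > 0")
  if (interval_jitter < 0) stop("'interval_jitter' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  t_end <- signal$t0 + (length(signal$values) - 1) * signal$dt
  span <- t_end - signal$t0
  n_max <- ceiling(span / mean_breath_interval * 2) + 10L
  if (interval_jitter > 0) {
    sdlog <- sqrt(log(1 + interval_jitter^2))
    meanlog <- log(mean_breath_interval) - sdlog^2 / 2
    iv <- stats::rlnorm(n_max, meanlog, sdlog)
  } else {
    iv <- rep(mean_breath_interval, n_max)
  }
  times <- signal$t0 + cumsum(iv)
  times <- times[times <= t_end]
  if (length(times) < 2L) stop("signal too short for the breath interval")
  vo2 <- stats::approx(series_time(signal), signal$values, xout = times)$y
  if (noise_sd > 0) vo2 <- vo2 + stats::rnorm(length(vo2), 0, noise_sd)
  breath_series(times, pmax(vo2, 0))
}

#' Reference parameter sets for the in-silico simulation study
#'
#' The ten published (a0, a1, tau_s) combinations used to characterize the
#' mean normalized gain against the first-order time constant, spanning
#' baselines 125-400 ml·min^-1, amplitudes 600-900 ml·min^-1 and time
#' constants 15-52 s.
#'
#' @return data.frame with columns `simulation`, `a0`, `a1`, `tau_s`.
#' @export
insilico_params <- function() {
  data.frame(
    simulation = 1:10,
    a0  = c(300, 400, 350, 250, 200, 150, 125, 350, 250, 330),
    a1  = c(700, 800, 750, 900, 750, 600, 800, 600, 750, 650),
    tau_s = c(15, 45, 25, 21, 39, 52, 42, 35, 48, 19))
}

#' Run the ten-simulation in-silico study
#'
#' For each parameter set of [insilico_params()] (or a user-supplied table),
#' simulates the noiseless first-order response to the standard 450-s PRBS,
#' decomposes input and output into harmonics 1-4, and reports the average
#' absolute gain and the mean normalized gain over harmonics 2-4.
#'
#' @param params data.frame with columns `a0`, `a1`, `tau_s` (default
#'   [insilico_params()]).
#' @param protocol PRBS protocol; default the standard 25/100 W, 15 x 30 s.
#' @param h_range harmonics used for the averages (default 2:4).
#' @return data.frame with columns `a0`, `a1`, `tau_s`, `mean_gain`
#'   (ml·min^-1·W^-1) and `mng` (%).
#' @examples
#' run_insilico_study()
#' @export
run_insilico_study <- function(params = insilico_params(),
                               protocol = prbs_protocol(generate_msequence()),
                               h_range = 2:4) {
  stopifnot(all(c("a0", "a1", "tau_s") %in% names(params)))
  in_dec <- harmonic_decomposition(protocol, H = max(h_range))
  out <- lapply(seq_len(nrow(params)), function(i) {
    p <- first_order_params(params$a0[i], params$a1[i], params$tau_s[i])
    y <- first_order_response(protocol, p)
    gp <- gain_profile(in_dec, harmonic_decomposition(y, H = max(h_range)),
                       h_range = h_range)
    data.frame(a0 = p$a0, a1 = p$a1, tau_s = p$tau_s,
               mean_gain = mean_gain(gp), mng = gp$mng)
  })
  do.call(rbind, out)
}

#' Mean normalized gain across extreme time constants and harmonic ranges
#'
#' Sweeps the time constant over a wide (including non-physiological) grid
#' and computes the pipeline MNG for each harmonic range, the study used to
#' establish the sigmoidal MNG-vs-log10(tau) relationship and its
#' range-dependent plateaus.
#'
#' @param taus time constants (s), all > 0. Default the published grid
#'   0.001-1500 s.
#' @param h_ranges list of harmonic ranges (default `2:3`, `2:4`, `2:5`,
#'   `2:10`).
#' @param a0,a1 amplitude parameters held constant across the sweep.
#' @param protocol PRBS protocol (default standard).
#' @return data.frame with columns `tau_s`, `h_min`, `h_max`, `mng`.
#' @export
run_extreme_tau_study <- function(taus = c(0.001, 0.1, 1, 5, 15, 35, 80, 200, 500, 1500),
                                  h_ranges = list(2:3, 2:4, 2:5, 2:10),
                                  a0 = 300, a1 = 700,
                                  protocol = prbs_protocol(generate_msequence())) {
  if (any(taus <= 0)) stop("'taus' must be > 0")
  H <- max(vapply(h_ranges, max, 1L))
  in_dec <- harmonic_decomposition(protocol, H = H)
  rows <- list()
  for (tau in taus) {
    y <- first_order_response(protocol, first_order_params(a0, a1, tau))
    out_dec <- harmonic_decomposition(y, H = H)
    for (hr in h_ranges) {
      gp <- gain_profile(in_dec, out_dec, h_range = hr)
      rows[[length(rows) + 1L]] <-
        data.frame(tau_s = tau, h_min = min(hr), h_max = max(hr), mng = gp$mng)
    }
  }
  do.call(rbind, rows)
}
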