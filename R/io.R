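#' Read and write the package's delimited text formats
#'
#' All files are comma-separated UTF-8 with a mandatory header row; units
#' are embedded in the column names (`t_s`, `vo2_ml_min`, `time_s`,
#' `watts`). Readers validate the header and the series invariants
#' (strictly increasing timestamps, two-level protocols) and report the
#' offending line on failure.
#'
#' @param path file path.
#' @name mngkin-io
NULL

check_header <- function(found, expected, path) {
  if (!identical(names(found), expected))
    stop(sprintf("'%s': expected header %s but found %s",
                 path, paste(expected, collapse = ","),
                 paste(names(found), collapse = ",")))
}

#' @rdname mngkin-io
#' @param breaths a [breath_series()].
#' @export
write_breath_csv <- function(breaths, path) {
  stopifnot(inherits(breaths, "breath_series"))
  utils::write.csv(as.data.frame(breaths), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mngkin-io
#' @export
read_breath_csv <- function(path) {
  d <- utils::read.csv(path)
  check_header(d, c("t_s", "vo2_ml_min"), path)
  bad <- which(diff(d$t_s) <= 0)
  if (length(bad))
    stop(sprintf("'%s': timestamps not strictly increasing at line %d",
                 path, bad[1L] + 2L))  # +1 header, +1 second row of the pair
  breath_series(d$t_s, d$vo2_ml_min)
}

#' @rdname mngkin-io
#' @param series a `uniform_series` of VO2.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "uniform_series"))
  d <- data.frame(t_s = series_time(series), vo2_ml_min = series$values)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mngkin-io
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  check_header(d, c("t_s", "vo2_ml_min"), path)
  if (nrow(d) < 2L) stop(sprintf("'%s': need >= 2 rows", path))
  dts <- diff(d$t_s)
  if (any(abs(dts - dts[1L]) > 1e-6))
    stop(sprintf("'%s': grid not uniform near line %d", path,
                 which(abs(dts - dts[1L]) > 1e-6)[1L] + 2L))
  uniform_series(d$vo2_ml_min, t0 = d$t_s[1L], dt = dts[1L])
}

#' @rdname mngkin-io
#' @param protocol a `work_rate_series`.
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "work_rate_series"))
  d <- data.frame(time_s = series_time(protocol), watts = protocol$values)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mngkin-io
#' @export
read_protocol_csv <- function(path) {
  d <- utils::read.csv(path)
  check_header(d, c("time_s", "watts"), path)
  lv <- sort(unique(d$watts))
  if (length(lv) != 2L)
    stop(sprintf("'%s': protocol must have exactly two levels, found %d",
                 path, length(lv)))
  dts <- diff(d$time_s)
  if (any(dts <= 0) || any(abs(dts - dts[1L]) > 1e-6))
    stop(sprintf("'%s': time grid not uniform/increasing", path))
  dt <- dts[1L]
  # recover unit structure from run lengths (all runs share a gcd duration)
  r <- rle(d$watts)
  unit <- min(r$lengths) * dt
  obj <- uniform_series(d$watts, t0 = d$time_s[1L], dt = dt)
  obj$bits <- as.integer(d$watts[seq(1, nrow(d), by = max(1, round(unit / dt)))] == lv[2L])
  obj$low <- lv[1L]; obj$high <- lv[2L]
  obj$unit_duration <- unit
  obj$n_periods <- 1L
  obj$period_s <- nrow(d) * dt
  class(obj) <- c("work_rate_series", class(obj))
  obj
}

#' @rdname mngkin-io
#' @param profile a [gain_profile()].
#' @export
write_harmonic_csv <- function(profile, path) {
  stopifnot(inherits(profile, "gain_profile"))
  utils::write.csv(profile$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mngkin-io
#' @param fit a [fit_monoexp()] result.
#' @export
write_expfit_json <- function(fit, path) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing JSON requires the 'jsonlite' package")
  out <- list(
    parameters = as.list(fit$coefficients),
    mrt = fit$mrt, r2 = fit$r2, sse = fit$sse,
    ci95 = apply(fit$ci95, 1, as.list),
    p = as.list(fit$p),
    bounds_hit = fit$bounds_hit,
    n = nrow(fit$data))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end PRBS analysis pipeline
#'
#' Drives a full reproducible study from a single configuration: builds (or
#' accepts) the PRBS protocol, simulates first-order responses per parameter
#' set with optional breath-by-breath noise, applies the configured
#' preprocessing (moving average, low-pass, ensemble averaging over
#' repetitions), and reports the MNG and, where the protocol phase admits
#' the step window, the time-domain parameters. Every stochastic step draws
#' from an explicit per-repetition seed, so rerunning the same
#' configuration reproduces the report exactly.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{protocol}{list(seed, unit_duration, low, high, dt) for
#'       [prbs_protocol()]; default the standard 25/100 W protocol.}
#'     \item{simulations}{data.frame with columns `a0`, `a1`, `tau_s` and
#'       optionally `td`.}
#'     \item{noise}{list(noise_sd, mean_breath_interval, interval_jitter);
#'       omit for noiseless second-by-second output.}
#'     \item{n_repetitions}{repetitions ensemble-averaged per condition
#'       (default 1).}
#'     \item{seed}{base integer seed; repetition k of simulation i uses
#'       `seed + 1000 i + k`.}
#'     \item{moving_average}{odd window (s) or NULL.}
#'     \item{lowpass}{cutoff in Hz, TRUE for 0.075, or NULL.}
#'     \item{h_range}{harmonics for the MNG (default 2:4).}
#'     \item{fit_window}{a [fit_window()] to add time-domain parameters, or
#'       NULL.}
#'   }
#' @param verbose log every preprocessing decision (default TRUE).
#' @return data.frame, one row per simulation: the parameters, `mng`,
#'   `mean_gain`, and when fitted `tau_hat`, `td_hat`, `mrt`, `r2`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  pc <- config$protocol
  protocol <- prbs_protocol(
    generate_msequence(if (is.null(pc$seed)) c(1L, 1L, 1L, 1L) else pc$seed),
    unit_duration = if (is.null(pc$unit_duration)) 30 else pc$unit_duration,
    low = if (is.null(pc$low)) 25 else pc$low,
    high = if (is.null(pc$high)) 100 else pc$high,
    dt = if (is.null(pc$dt)) 1 else pc$dt)
  sims <- config$simulations
  if (is.null(sims)) stop("config$simulations is required")
  stopifnot(all(c("a0", "a1", "tau_s") %in% names(sims)))
  h_range <- if (is.null(config$h_range)) 2:4 else config$h_range
  nrep <- if (is.null(config$n_repetitions)) 1L else as.integer(config$n_repetitions)
  base_seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say("protocol: %d x %g s units at %g/%g W; harmonics %d..%d; %d repetition(s)",
      length(protocol$bits), protocol$unit_duration, protocol$low,
      protocol$high, min(h_range), max(h_range), nrep)
  rows <- lapply(seq_len(nrow(sims)), function(i) {
    p <- first_order_params(sims$a0[i], sims$a1[i], sims$tau_s[i],
                            td = if ("td" %in% names(sims)) sims$td[i] else 0)
    truth <- first_order_response(protocol, p)
    reps <- lapply(seq_len(nrep), function(k) {
      if (is.null(config$noise)) return(truth)
      nz <- config$noise
      padded <- pad_periodic(truth, 15)
      b <- breath_sample(padded,
                         mean_breath_interval = if (is.null(nz$mean_breath_interval)) 3 else nz$mean_breath_interval,
                         interval_jitter = if (is.null(nz$interval_jitter)) 0.2 else nz$interval_jitter,
                         noise_sd = if (is.null(nz$noise_sd)) 0 else nz$noise_sd,
                         seed = base_seed + 1000L * i + k)
      interpolate_1s(b, grid_start = 0,
                     grid_end = protocol$period_s - protocol$dt, dt = protocol$dt)
    })
    y <- if (nrep > 1L) ensemble_average(reps) else reps[[1L]]
    if (!is.null(config$noise))
      say("simulation %d: breath-sampled %d repetition(s), seeds %d..%d",
          i, nrep, base_seed + 1000L * i + 1L, base_seed + 1000L * i + nrep)
    if (!is.null(config$moving_average)) {
      y <- moving_average(y, config$moving_average)
      say("simulation %d: moving average %g s", i, config$moving_average)
    }
    lp <- config$lowpass
    if (!is.null(lp) && !identical(lp, FALSE)) {
      cutoff <- if (isTRUE(lp)) 0.075 else lp
      y <- lowpass(y, cutoff)
      say("simulation %d: low-pass %g Hz (zero-phase)", i, cutoff)
    }
    fit <- mng_fit(y, protocol, h_range = h_range)
    row <- data.frame(a0 = p$a0, a1 = p$a1, tau_s = p$tau_s, td = p$td,
                      mng = fit$mng, mean_gain = mean_gain(fit$profile))
    if (!is.null(config$fit_window)) {
      seg <- extract_fit_window(y, config$fit_window, protocol = protocol)
      ef <- fit_monoexp(seg)
      row$tau_hat <- ef$coefficients[["tau"]]
      row$td_hat <- ef$coefficients[["td"]]
      row$mrt <- ef$mrt
      row$r2 <- ef$r2
    }
    row
  })
  do.call(rbind, rows)
}
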