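#' Fourier harmonic decomposition over one PRBS period
#'
#' Computes the Fourier-series coefficients of a signal spanning exactly one
#' protocol period: for harmonic `h` of the fundamental `f1 = 1/period`,
#' `A_h = (1/N) sum x(t) cos(2 pi h f1 t)` and
#' `B_h = (1/N) sum x(t) sin(2 pi h f1 t)`, with amplitude
#' `Amp_h = sqrt(A_h^2 + B_h^2)`. The reconstruction
#' `x(t) ~ a0 + 2 sum_h (A_h cos + B_h sin)` carries the factor 2, so a pure
#' input `10 cos(2 pi f1 t)` has `Amp_1 = 5`. No taper, window or
#' zero-padding is applied: the PRBS is periodic by design and the
#' decomposition is a Fourier-series statement, not a spectral estimate.
#'
#' @param series a `uniform_series` spanning exactly one period
#'   (`length * dt == period`).
#' @param H number of harmonics (default 4, the linear range of the VO2
#'   response; frequencies above ~0.01 Hz are distorted by circulatory
#'   dynamics and are excluded by design).
#' @param period the period in s; defaults to the series span.
#' @return object of class `harmonic_decomposition`: list with `f1`,
#'   `a0_mean`, and a data.frame `harmonics` (`h`, `freq_hz`, `A`, `B`,
#'   `amp`).
#' @examples
#' t <- 0:449
#' d <- harmonic_decomposition(uniform_series(10 * cos(2 * pi * t / 450)))
#' d$harmonics$amp  # 5 at h = 1, ~0 above
#' @export
harmonic_decomposition <- function(series, H = 4L, period = NULL) {
  stopifnot(inherits(series, "uniform_series"))
  H <- as.integer(H)
  if (H < 1L) stop("'H' must be >= 1")
  N <- length(series$values)
  if (is.null(period)) period <- N * series$dt
  if (abs(N * series$dt - period) > 1e-9)
    stop(sprintf("series spans %g s but one period is %g s: decomposition requires exactly one period",
                 N * series$dt, period))
  f1 <- 1 / period
  t <- (seq_len(N) - 1) * series$dt
  x <- series$values
  h <- seq_len(H)
  A <- vapply(h, function(k) sum(x * cos(2 * pi * k * f1 * t)) / N, 1)
  B <- vapply(h, function(k) sum(x * sin(2 * pi * k * f1 * t)) / N, 1)
  structure(list(
    f1 = f1,
    a0_mean = mean(x),
    harmonics = data.frame(h = h, freq_hz = h * f1, A = A, B = B,
                           amp = sqrt(A^2 + B^2))),
    class = "harmonic_decomposition")
}

#' @export
print.harmonic_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<harmonic_decomposition> f1 = %.5f Hz, mean level = %.2f\n",
              x$f1, x$a0_mean))
  print(format(x$harmonics, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Harmonic input:output gains and the mean normalized gain
#'
#' The gain at harmonic `h` is the ratio of output (VO2) to input (work
#' rate) amplitude, `gAmp_h = VO2Amp_h / WAmp_h` (ml·min^-1·W^-1). Gains are
#' normalized as a percentage of `gAmp_1`, which removes the steady-state
#' (static) gain and isolates the temporal dynamics; the mean normalized
#' gain (MNG) is the average of the normalized gains over `h_range`
#' (default harmonics 2-4). A fast system keeps its gain across harmonics
#' (MNG near 100%); a slow one attenuates the higher harmonics (low MNG).
#'
#' @param input_dec harmonic decomposition of the work-rate protocol.
#' @param output_dec harmonic decomposition of the VO2 response on the same
#'   fundamental.
#' @param h_range harmonics averaged into the MNG (default 2:4).
#' @return object of class `gain_profile`: data.frame `table` with columns
#'   `h`, `freq_hz`, `input_amp`, `output_amp`, `gain`,
#'   `normalized_gain_pct`, plus `mng` (%) and `h_range`.
#' @export
gain_profile <- function(input_dec, output_dec, h_range = 2:4) {
  stopifnot(inherits(input_dec, "harmonic_decomposition"),
            inherits(output_dec, "harmonic_decomposition"))
  if (abs(input_dec$f1 - output_dec$f1) > 1e-12)
    stop("input and output decompositions have different fundamental frequencies")
  H <- min(nrow(input_dec$harmonics), nrow(output_dec$harmonics))
  h_range <- as.integer(h_range)
  if (!all(h_range %in% seq_len(H)) || !1L %in% seq_len(H))
    stop("'h_range' (and harmonic 1) must be within the computed harmonics")
  inp <- input_dec$harmonics$amp[seq_len(H)]
  zero_tol <- 1e-9 * max(abs(input_dec$a0_mean), inp, 1)
  if (any(inp[c(1L, h_range)] <= zero_tol))
    stop("zero input amplitude at a harmonic used for the gain ratio")
  gain <- output_dec$harmonics$amp[seq_len(H)] / inp
  tab <- data.frame(
    h = seq_len(H),
    freq_hz = input_dec$harmonics$freq_hz[seq_len(H)],
    input_amp = inp,
    output_amp = output_dec$harmonics$amp[seq_len(H)],
    gain = gain,
    normalized_gain_pct = 100 * gain / gain[1L])
  structure(list(table = tab,
                 mng = mean(tab$normalized_gain_pct[h_range]),
                 h_range = h_range),
            class = "gain_profile")
}

#' @export
print.gain_profile <- function(x, digits = 4, ...) {
  cat("<gain_profile>\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("MNG over h = %d..%d: %.2f %%\n",
              min(x$h_range), max(x$h_range), x$mng))
  invisible(x)
}

#' Average absolute harmonic gain
#'
#' Arithmetic mean of the absolute gains `gAmp_h` over a harmonic range
#' (default the profile's own range, harmonics 2-4).
#'
#' @param profile a [gain_profile()].
#' @param h_range harmonics to average.
#' @return mean gain in ml·min^-1·W^-1.
#' @export
mean_gain <- function(profile, h_range = profile$h_range) {
  stopifnot(inherits(profile, "gain_profile"))
  h_range <- as.integer(h_range)
  if (!length(h_range)) stop("'h_range' must be non-empty")
  if (!all(h_range %in% profile$table$h))
    stop("'h_range' outside the computed harmonics")
  mean(abs(profile$table$gain[match(h_range, profile$table$h)]))
}

#' Closed-form MNG of a first-order system
#'
#' For a first-order linear system the gain magnitude at frequency `f` is
#' `G / sqrt(1 + (2 pi f tau)^2)`, so the MNG has the closed form
#' `100 * mean_h sqrt((1 + (2 pi f1 tau)^2) / (1 + (2 pi h f1 tau)^2))`.
#' This is independent of baseline and amplitude, strictly decreasing in
#' `tau`, and for `h_range = 2:4` spans (36.11%, 100%) over
#' `tau` in (0, Inf). Serves as the analytic oracle for the simulation +
#' decomposition pipeline.
#'
#' @param tau time constant(s) in s (vectorized), > 0.
#' @param f1 fundamental frequency (Hz), default 1/450.
#' @param h_range harmonics (default 2:4).
#' @return MNG in percent, same length as `tau`.
#' @examples
#' analytic_mng(15)   # ~86
#' @export
analytic_mng <- function(tau, f1 = 1 / 450, h_range = 2:4) {
  if (any(tau <= 0)) stop("'tau' must be > 0")
  vapply(tau, function(tt) {
    num <- 1 + (2 * pi * f1 * tt)^2
    100 * mean(sqrt(num / (1 + (2 * pi * h_range * f1 * tt)^2)))
  }, 1)
}

#' Fit the mean normalized gain to a VO2 response
#'
#' The frequency-domain estimator: decomposes the work-rate input and the
#' VO2 output over one PRBS period into Fourier harmonics, forms the
#' input:output gains, normalizes them by the fundamental gain and averages
#' over `h_range`. Accepts either a second-by-second series spanning one
#' period or a raw breath record (interpolated onto the protocol grid
#' first).
#'
#' @param vo2 a `uniform_series` spanning one protocol period, or a
#'   `breath_series` covering it.
#' @param protocol the [prbs_protocol()] driving the response (its first
#'   period defines the grid and fundamental frequency).
#' @param h_range harmonics averaged into the MNG (default 2:4).
#' @param H harmonics computed (default `max(h_range)`).
#' @return object of class `mng_fit` with components `mng` (%), `profile`
#'   ([gain_profile()]), `input_dec`, `output_dec`, `h_range`, `call`.
#' @examples
#' wr <- prbs_protocol(generate_msequence())
#' y <- first_order_response(wr, first_order_params(300, 700, 15))
#' fit <- mng_fit(y, wr)
#' fit
#' @export
mng_fit <- function(vo2, protocol, h_range = 2:4, H = max(h_range)) {
  stopifnot(inherits(protocol, "work_rate_series"))
  if (inherits(vo2, "breath_series")) {
    vo2 <- interpolate_1s(vo2, grid_start = 0,
                          grid_end = protocol$period_s - protocol$dt,
                          dt = protocol$dt)
  }
  if (!inherits(vo2, "uniform_series"))
    stop("'vo2' must be a uniform_series or breath_series")
  one <- uniform_series(protocol_period(protocol), t0 = 0, dt = protocol$dt)
  in_dec <- harmonic_decomposition(one, H = H)
  out_dec <- harmonic_decomposition(vo2, H = H, period = protocol$period_s)
  prof <- gain_profile(in_dec, out_dec, h_range = h_range)
  structure(list(mng = prof$mng, profile = prof, input_dec = in_dec,
                 output_dec = out_dec, h_range = h_range,
                 call = match.call()),
            class = "mng_fit")
}

#' @export
print.mng_fit <- function(x, ...) {
  cat("Mean normalized gain fit\n")
  cat(sprintf("  MNG (h = %d..%d): %.1f %%\n",
              min(x$h_range), max(x$h_range), x$mng))
  cat(sprintf("  fundamental: %.5f Hz; mean VO2: %.0f ml/min\n",
              x$output_dec$f1, x$output_dec$a0_mean))
  invisible(x)
}

#' @export
summary.mng_fit <- function(object, ...) {
  cat("Mean normalized gain fit\n\n")
  print(object$profile)
  cat(sprintf("Mean absolute gain over h = %d..%d: %.2f ml/min/W\n",
              min(object$h_range), max(object$h_range),
              mean_gain(object$profile)))
  invisible(object)
}

#' @export
coef.mng_fit <- function(object, ...) {
  g <- object$profile$table$gain
  names(g) <- paste0("gAmp_", object$profile$table$h)
  c(g, mng = object$mng)
}

#' @export
plot.mng_fit <- function(x, ...) {
  tab <- x$profile$table
  graphics::plot(tab$h, tab$normalized_gain_pct, type = "b", pch = 19,
                 xlab = "harmonic", ylab = "normalized gain (%)",
                 ylim = c(0, 105), ...)
  graphics::abline(h = x$mng, lty = 2)
  graphics::mtext(sprintf("MNG = %.1f%%", x$mng), side = 3, line = 0.2,
                  adj = 1, cex = 0.9)
  invisible(x)
}
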