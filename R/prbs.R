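#' Generate one period of the 4-stage maximal-length binary sequence
#'
#' The pseudorandom binary sequence (PRBS) work-rate protocol is driven by a
#' 4-stage linear feedback shift register: at every step the feedback bit is
#' the modulo-2 sum of the first and fourth stage, the register shifts right,
#' the feedback bit enters stage 1 and the bit shifted out of stage 4 is the
#' output. Any non-zero seed yields the same maximal-length sequence of
#' period 2^4 - 1 = 15 (up to cyclic rotation), containing 8 of one symbol
#' and 7 of the other.
#'
#' @param seed integer vector of 4 bits (0/1), not all zero. The all-zero
#'   state is a fixed point of the register and is rejected. The seed only
#'   rotates the sequence; harmonic amplitude spectra (and hence the mean
#'   normalized gain) are invariant to it.
#' @return integer vector of 15 bits (one full period), with the seed kept
#'   as attribute `"seed"`.
#' @examples
#' generate_msequence()
#' sum(generate_msequence(c(0, 1, 0, 0)))  # 8 ones, 7 zeros
#' @export
generate_msequence <- function(seed = c(1L, 1L, 1L, 1L)) {
  seed <- as.integer(seed)
  if (length(seed) != 4L || !all(seed %in% c(0L, 1L)))
    stop("'seed' must be 4 binary values")
  if (all(seed == 0L))
    stop("all-zero register state is a fixed point and generates a constant sequence")
  s <- seed
  out <- integer(15L)
  for (i in 1:15) {
    fb <- (s[1L] + s[4L]) %% 2L
    out[i] <- s[4L]          # bit shifted out of the last stage
    s <- c(fb, s[1:3])       # right shift, feedback enters stage 1
  }
  attr(out, "seed") <- seed
  out
}

#' Build a PRBS work-rate protocol from a bit sequence
#'
#' Maps each bit to one of two work-rate levels and holds it for
#' `unit_duration` seconds; the standard protocol is 15 units of 30 s at
#' 25 or 100 W, i.e. a 450-s period.
#'
#' @param bits binary vector (one PRBS period, typically from
#'   [generate_msequence()]).
#' @param unit_duration seconds each bit is held (default 30).
#' @param low,high the two work-rate levels in W (default 25 and 100);
#'   bit 1 maps to `high`.
#' @param dt sampling interval in s; must divide `unit_duration`.
#' @param n_periods number of concatenated periods.
#' @return An object of class `c("work_rate_series", "uniform_series")` with
#'   fields `values` (W), `dt`, `t0 = 0`, plus `bits`, `low`, `high`,
#'   `unit_duration`, `n_periods` and `period_s`.
#' @examples
#' wr <- prbs_protocol(generate_msequence())
#' length(wr$values)  # 450 samples at dt = 1
#' @export
prbs_protocol <- function(bits, unit_duration = 30, low = 25, high = 100,
                          dt = 1, n_periods = 1L) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("'bits' must be binary")
  if (unit_duration <= 0) stop("'unit_duration' must be > 0")
  if (low >= high) stop("'low' must be < 'high'")
  if (dt <= 0) stop("'dt' must be > 0")
  k <- unit_duration / dt
  if (abs(k - round(k)) > 1e-9)
    stop("'dt' must divide 'unit_duration'")
  if (n_periods < 1L) stop("'n_periods' must be >= 1")
  one <- rep(ifelse(bits == 1L, high, low), each = round(k))
  obj <- uniform_series(rep(one, n_periods), t0 = 0, dt = dt)
  obj$bits <- bits
  obj$low <- low
  obj$high <- high
  obj$unit_duration <- unit_duration
  obj$n_periods <- as.integer(n_periods)
  obj$period_s <- length(bits) * unit_duration
  class(obj) <- c("work_rate_series", class(obj))
  obj
}

#' @export
print.work_rate_series <- function(x, ...) {
  cat(sprintf("<work_rate_series> %d period(s) of %d x %g s units at %g/%g W (dt = %g s)\n",
              x$n_periods, length(x$bits), x$unit_duration, x$low, x$high, x$dt))
  invisible(x)
}

# one period of the protocol as a plain numeric vector (first period)
protocol_period <- function(protocol) {
  stopifnot(inherits(protocol, "work_rate_series"))
  n <- protocol$period_s / protocol$dt
  protocol$values[seq_len(n)]
}
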