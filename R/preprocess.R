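#' Interpolate breath-by-breath VO2 onto the second-by-second grid
#'
#' Linear interpolation between consecutive breath values evaluated on a
#' uniform grid. No extrapolation: the grid must lie within the breath
#' support.
#'
#' @param breaths a [breath_series()] with >= 2 breaths.
#' @param grid_start,grid_end grid limits (s); defaults to the integer
#'   seconds covered by the breaths.
#' @param dt grid spacing (s), default 1.
#' @return a [uniform_series()].
#' @examples
#' b <- breath_series(c(0, 2), c(400, 600))
#' interpolate_1s(b)$values  # 400 500 600
#' @export
interpolate_1s <- function(breaths, grid_start = NULL, grid_end = NULL, dt = 1) {
  stopifnot(inherits(breaths, "breath_series"))
  if (length(breaths$times) < 2L) stop("need >= 2 breaths to interpolate")
  if (is.null(grid_start)) grid_start <- ceiling(breaths$times[1L] / dt) * dt
  if (is.null(grid_end)) grid_end <- floor(breaths$times[length(breaths$times)] / dt) * dt
  if (grid_start < breaths$times[1L] - 1e-9 ||
      grid_end > breaths$times[length(breaths$times)] + 1e-9)
    stop("grid extends beyond the breath record; extrapolation is not supported")
  grid <- seq(grid_start, grid_end, by = dt)
  v <- stats::approx(breaths$times, breaths$vo2, xout = grid, rule = 1)$y
  uniform_series(v, t0 = grid_start, dt = dt)
}

#' Centered moving-average filter
#'
#' Running mean over an odd window (3, 5 or 7 s in standard use). Output
#' length equals input length: at the edges the window is truncated to the
#' available samples rather than padding with fabricated data.
#'
#' @param series a `uniform_series`.
#' @param window odd window length in samples (at `dt = 1`, seconds).
#' @return filtered `uniform_series` of the same length.
#' @export
moving_average <- function(series, window) {
  stopifnot(inherits(series, "uniform_series"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer")
  if (window == 1L) return(series)
  x <- series$values
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  uniform_series(out, t0 = series$t0, dt = series$dt)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward, giving zero phase
#' shift so the timing information that both analysis branches rely on is
#' preserved. Default cutoff 0.075 Hz. The series is extended by odd
#' (point-symmetric) reflection at both ends before filtering and trimmed
#' afterwards, which suppresses the start-up transients of the recursive
#' filter; a constant series passes through unchanged.
#'
#' @param series a `uniform_series`.
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist frequency
#'   `1/(2 dt)`.
#' @param order filter order (default 4).
#' @return filtered `uniform_series` of the same length.
#' @export
lowpass <- function(series, cutoff = 0.075, order = 4) {
  stopifnot(inherits(series, "uniform_series"))
  nyq <- 1 / (2 * series$dt)
  if (cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("'cutoff' must be in (0, %g) Hz", nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  x <- series$values
  n <- length(x)
  npad <- min(n - 1L, ceiling(10 / (cutoff * series$dt)))
  if (npad > 0L) {
    head_ref <- 2 * x[1L] - x[(npad + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(head_ref, x, tail_ref)
    out <- signal::filtfilt(bf, xp)[(npad + 1L):(npad + n)]
  } else {
    out <- signal::filtfilt(bf, x)
  }
  uniform_series(out, t0 = series$t0, dt = series$dt)
}

#' Periodic padding of a steady-state cycle
#'
#' Extends a series that represents one period of a periodic steady state by
#' wrapping samples from the opposite end onto each side. Useful before
#' breath-by-breath resampling, so that interpolation back onto the original
#' grid never runs out of support at the period boundaries.
#'
#' @param series a `uniform_series` holding exactly one period.
#' @param pad_s seconds to wrap onto each side (must be shorter than the
#'   period).
#' @return a longer `uniform_series` starting at `t0 - pad_s`.
#' @export
pad_periodic <- function(series, pad_s) {
  stopifnot(inherits(series, "uniform_series"))
  k <- round(pad_s / series$dt)
  n <- length(series$values)
  if (k < 1L || k >= n) stop("'pad_s' must be positive and shorter than the period")
  v <- series$values
  uniform_series(c(v[(n - k + 1L):n], v, v[1:k]),
                 t0 = series$t0 - k * series$dt, dt = series$dt)
}

#' Ensemble-average aligned repetitions
#'
#' Pointwise mean of time-aligned repetitions of the same protocol. All
#' series must share `t0`, `dt` and length; alignment itself is the caller's
#' contract (repetitions cut from a continuous record are aligned by
#' construction).
#'
#' @param replicates list of `uniform_series` on a common grid.
#' @return the pointwise-mean `uniform_series`.
#' @export
ensemble_average <- function(replicates) {
  if (!length(replicates)) stop("'replicates' must be non-empty")
  if (!all(vapply(replicates, inherits, TRUE, "uniform_series")))
    stop("all replicates must be uniform_series")
  ref <- replicates[[1L]]
  ok <- vapply(replicates, function(s)
    isTRUE(all.equal(s$t0, ref$t0)) && isTRUE(all.equal(s$dt, ref$dt)) &&
      length(s$values) == length(ref$values), TRUE)
  if (!all(ok))
    stop("replicates are not aligned: t0, dt and length must match across the list")
  m <- rowMeans(vapply(replicates, `[[`, numeric(length(ref$values)), "values"))
  uniform_series(m, t0 = ref$t0, dt = ref$dt)
}
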