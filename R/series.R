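#' Second-by-second uniform time series
#'
#' Container for a uniformly sampled signal, typically VO2 in ml·min^-1 on the
#' 1-s analysis grid that both the frequency-domain and time-domain branches
#' operate on.
#'
#' @param values numeric vector of signal values (finite).
#' @param t0 start time in seconds.
#' @param dt sampling interval in seconds (> 0).
#' @return An object of class `uniform_series` with fields `t0`, `dt`,
#'   `values`.
#' @examples
#' s <- uniform_series(sin(2 * pi * (0:449) / 450))
#' s
#' @export
uniform_series <- function(values, t0 = 0, dt = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  structure(list(t0 = t0, dt = dt, values = values), class = "uniform_series")
}

#' Sample times of a uniform series
#' @param x a `uniform_series`.
#' @return numeric vector of sample times (s).
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> n = %d, t0 = %g s, dt = %g s, span = %g s\n",
              length(x$values), x$t0, x$dt, length(x$values) * x$dt))
  cat(sprintf("  values: mean %.1f, range [%.1f, %.1f]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.uniform_series <- function(x, ...) {
  data.frame(t_s = series_time(x), value = x$values)
}

#' Breath-by-breath VO2 record
#'
#' Raw measurement container: one VO2 value per breath at its end-timestamp.
#' Timestamps must be strictly increasing; VO2 must be finite and
#' non-negative.
#'
#' @param times breath end-timestamps (s), strictly increasing.
#' @param vo2 per-breath VO2 (ml·min^-1), finite, >= 0.
#' @return An object of class `breath_series`.
#' @export
breath_series <- function(times, vo2) {
  times <- as.numeric(times); vo2 <- as.numeric(vo2)
  if (length(times) != length(vo2)) stop("'times' and 'vo2' lengths differ")
  if (length(times) < 1L) stop("empty breath record")
  if (!all(is.finite(times))) stop("breath times must be finite")
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("breath times must be strictly increasing (violation at row %d)", bad))
  }
  if (!all(is.finite(vo2))) stop("vo2 must be finite")
  if (any(vo2 < 0)) stop("vo2 must be non-negative")
  structure(list(times = times, vo2 = vo2), class = "breath_series")
}

#' @export
length.breath_series <- function(x) length(x$times)

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths over [%.1f, %.1f] s, mean interval %.2f s\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              if (length(x$times) > 1) mean(diff(x$times)) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.breath_series <- function(x, ...) {
  data.frame(t_s = x$times, vo2_ml_min = x$vo2)
}
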