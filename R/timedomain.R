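#' Time-domain fit window inside the PRBS period
#'
#' The mono-exponential analysis uses the longest stretch of the PRBS
#' without input variation: the final seconds of a low-level period followed
#' by the longest high-level run. The standard window is the final 10 s of a
#' 90-s period at 25 W followed by 120 s at 100 W, with the step onset at
#' the 180th second of the period; the first 20 s after onset are excluded
#' as the cardio-dynamic phase.
#'
#' @param start onset time (s) into the PRBS period where the step begins.
#' @param baseline_span seconds of low-level baseline retained before onset.
#' @param step_span seconds of high-level response after onset.
#' @param cardio_exclusion seconds after onset excluded from fitting.
#' @return list of class `fit_window`.
#' @export
fit_window <- function(start = 180, baseline_span = 10, step_span = 120,
                       cardio_exclusion = 20) {
  if (baseline_span <= 0 || step_span <= 0) stop("window spans must be positive")
  if (cardio_exclusion < 0 || cardio_exclusion >= step_span)
    stop("'cardio_exclusion' must be in [0, step_span)")
  structure(list(start = start, baseline_span = baseline_span,
                 step_span = step_span, cardio_exclusion = cardio_exclusion),
            class = "fit_window")
}

# human-readable run table of a protocol period, used in error messages
protocol_runs <- function(protocol) {
  v <- protocol_period(protocol)
  r <- rle(v)
  starts <- cumsum(c(0, r$lengths[-length(r$lengths)])) * protocol$dt
  data.frame(start_s = starts, duration_s = r$lengths * protocol$dt,
             watts = r$values)
}

#' Extract the step-response segment for time-domain fitting
#'
#' Cuts the baseline and step segments of [fit_window()] out of a one-period
#' second-by-second series. When the driving protocol is supplied, the
#' window is checked against the actual work-rate runs (the low run must
#' cover the baseline span and the high run the step span); if the protocol
#' phase does not contain the requested window, the available runs are
#' reported so a matching onset (or register seed) can be chosen.
#'
#' @param series `uniform_series` covering one PRBS period from `t0 = 0`.
#' @param window a [fit_window()].
#' @param protocol optional `work_rate_series` used to validate the window
#'   against the input runs.
#' @return list of class `fit_segments`: `baseline` and `step` data.frames
#'   (columns `t` — onset-relative time, negative in the baseline — `vo2`,
#'   and `excluded` for the cardio-dynamic samples), plus `window`.
#' @export
extract_fit_window <- function(series, window = fit_window(), protocol = NULL) {
  stopifnot(inherits(series, "uniform_series"), inherits(window, "fit_window"))
  tt <- series_time(series)
  t_lo <- window$start - window$baseline_span
  t_hi <- window$start + window$step_span
  if (t_lo < tt[1L] - 1e-9 || t_hi - series$dt > tt[length(tt)] + 1e-9)
    stop(sprintf("fit window [%g, %g) s is outside the series support [%g, %g] s",
                 t_lo, t_hi, tt[1L], tt[length(tt)]))
  if (!is.null(protocol)) {
    u <- protocol_period(protocol)
    ut <- (seq_along(u) - 1) * protocol$dt
    base_idx <- ut >= t_lo - 1e-9 & ut < window$start - 1e-9
    step_idx <- ut >= window$start - 1e-9 & ut < t_hi - 1e-9
    if (!all(u[base_idx] == protocol$low) || !all(u[step_idx] == protocol$high)) {
      runs <- protocol_runs(protocol)
      stop(paste0(
        "protocol does not hold a low->high step at the requested window; ",
        "available runs (start_s/duration_s/watts):\n",
        paste(sprintf("  %6g %6g %5g", runs$start_s, runs$duration_s, runs$watts),
              collapse = "\n")))
    }
  }
  bsel <- tt >= t_lo - 1e-9 & tt < window$start - 1e-9
  ssel <- tt >= window$start - 1e-9 & tt < t_hi - 1e-9
  t_rel_b <- tt[bsel] - window$start
  t_rel_s <- tt[ssel] - window$start
  structure(list(
    baseline = data.frame(t = t_rel_b, vo2 = series$values[bsel],
                          excluded = FALSE),
    step = data.frame(t = t_rel_s, vo2 = series$values[ssel],
                      excluded = t_rel_s < window$cardio_exclusion),
    window = window),
    class = "fit_segments")
}

#' @export
print.fit_segments <- function(x, ...) {
  cat(sprintf("<fit_segments> baseline %d s, step %d s (%d excluded as cardio-dynamic)\n",
              nrow(x$baseline), nrow(x$step), sum(x$step$excluded)))
  invisible(x)
}

#' Mono-exponential time-domain fit of the VO2 on-transient
#'
#' Fits the delayed mono-exponential
#' `VO2(t) = a0 + a (1 - exp(-(t - TD)/tau))` for `t >= TD`, with
#' `VO2(t) = a0` before the delay, to the non-excluded samples of a step
#' window by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nlsLM()]). Baseline samples participate in the fit through
#' the model value `a0`. The mean response time is `MRT = tau + TD`.
#'
#' Starts are `a0 = mean(baseline)`, `a = mean(last 30 s of step) - a0`,
#' `tau = 30 s`, `TD = 15 s`; bounds `tau` in (0.1, 200] s and `TD` in
#' [0, 60] s cover and exceed the physiological range (10 < tau < 100 s).
#' Per-parameter 95% confidence intervals and p-values come from the
#' asymptotic normal approximation of the least-squares estimator.
#'
#' @param segments a [extract_fit_window()] result, or a data.frame with
#'   columns `t` (onset-relative s), `vo2` and optionally `excluded`.
#' @param tau_bounds,td_bounds parameter bounds `c(lower, upper)`.
#' @return object of class `monoexp_fit` with `coefficients`
#'   (`a0`, `a`, `tau`, `td`), `mrt`, `r2`, `sse`, `sigma`, `ci95`, `p`,
#'   `se`, `bounds_hit`, the underlying `nls` object and the fitted data.
#' @examples
#' t <- c(-9:-1, 20:119)
#' y <- 900 + 750 * (1 - exp(-(t - 15) / 34)) * (t >= 15)
#' fit <- fit_monoexp(data.frame(t = t, vo2 = y))
#' coef(fit)
#' @export
fit_monoexp <- function(segments, tau_bounds = c(0.1, 200),
                        td_bounds = c(0, 60)) {
  if (inherits(segments, "fit_segments")) {
    dat <- rbind(segments$baseline, segments$step)
  } else {
    dat <- as.data.frame(segments)
    if (is.null(dat$excluded)) dat$excluded <- FALSE
  }
  stopifnot(all(c("t", "vo2") %in% names(dat)))
  fitdat <- dat[!dat$excluded, , drop = FALSE]
  if (nrow(fitdat) < 4L)
    stop("need >= 4 non-excluded samples to fit 4 parameters")
  base <- fitdat$vo2[fitdat$t < 0]
  a0_start <- if (length(base)) mean(base) else fitdat$vo2[1L]
  tail30 <- fitdat$vo2[fitdat$t >= max(fitdat$t) - 30]
  start <- list(a0 = a0_start, a = mean(tail30) - a0_start, tau = 30, td = 15)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vo2 ~ a0 + a * (1 - exp(-(t - td) / tau)) * (t >= td),
      data = fitdat, start = start,
      lower = c(a0 = -Inf, a = -Inf, tau = tau_bounds[1L], td = td_bounds[1L]),
      upper = c(a0 = Inf, a = Inf, tau = tau_bounds[2L], td = td_bounds[2L]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("mono-exponential fit failed to converge: %s (n = %d, starts a0 = %.1f, a = %.1f)",
                   conditionMessage(e), nrow(fitdat), start$a0, start$a),
           call. = FALSE))
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  pv <- sm$coefficients[, "Pr(>|t|)"]
  dfree <- nrow(fitdat) - length(cf)
  ci <- cbind(lower = cf - stats::qt(0.975, dfree) * se,
              upper = cf + stats::qt(0.975, dfree) * se)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((fitdat$vo2 - mean(fitdat$vo2))^2)
  bounds_hit <- character(0)
  if (cf[["tau"]] <= tau_bounds[1L] + 1e-6 || cf[["tau"]] >= tau_bounds[2L] - 1e-6)
    bounds_hit <- c(bounds_hit, "tau")
  if (cf[["td"]] >= td_bounds[2L] - 1e-6) bounds_hit <- c(bounds_hit, "td")
  structure(list(
    coefficients = cf,
    mrt = cf[["tau"]] + cf[["td"]],
    r2 = if (sst > 0) max(0, 1 - sse / sst) else NA_real_,
    sse = sse,
    sigma = sm$sigma,
    ci95 = ci, p = pv, se = se,
    bounds_hit = bounds_hit,
    nls = fit, data = fitdat, excluded = dat[dat$excluded, , drop = FALSE],
    call = match.call()),
    class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Mono-exponential VO2 kinetics fit\n")
  cat(sprintf("  a0 = %.1f ml/min, a = %.1f ml/min, tau = %.1f s, TD = %.1f s\n",
              cf[["a0"]], cf[["a"]], cf[["tau"]], cf[["td"]]))
  cat(sprintf("  MRT = %.1f s, r2 = %.4f, SSE = %.1f (n = %d)\n",
              x$mrt, x$r2, x$sse, nrow(x$data)))
  if (length(x$bounds_hit))
    cat("  warning: parameter(s) at bounds:", paste(x$bounds_hit, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.monoexp_fit <- function(object, ...) {
  print(object)
  cat("\nParameter table:\n")
  tab <- cbind(estimate = object$coefficients, se = object$se,
               object$ci95, p = object$p)
  print(round(tab, 4))
  invisible(object)
}

#' @export
coef.monoexp_fit <- function(object, ...) object$coefficients

#' @export
fitted.monoexp_fit <- function(object, ...) as.numeric(stats::fitted(object$nls))

#' @export
residuals.monoexp_fit <- function(object, ...) as.numeric(stats::residuals(object$nls))

#' Predicted VO2 of a fitted mono-exponential model
#' @param object a `monoexp_fit`.
#' @param newdata data.frame with column `t` (onset-relative s) or a numeric
#'   vector of times; defaults to the fitted times.
#' @param ... unused.
#' @return numeric vector of model VO2 values.
#' @export
predict.monoexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  cf <- object$coefficients
  cf[["a0"]] + cf[["a"]] * (1 - exp(-(t - cf[["td"]]) / cf[["tau"]])) * (t >= cf[["td"]])
}

#' Simulate responses from a fitted mono-exponential model
#'
#' Draws replicate datasets at the fitted time points: model prediction plus
#' Gaussian noise with the residual standard deviation.
#'
#' @param object a `monoexp_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with the fitted times and one `sim_*` column per
#'   replicate.
#' @export
simulate.monoexp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  mu <- predict(object)
  sims <- replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma))
  out <- data.frame(t = object$data$t, sims)
  names(out)[-1L] <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.monoexp_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$vo2, pch = 1, col = "grey40",
                 xlab = "time from step onset (s)", ylab = "VO2 (ml/min)", ...)
  if (nrow(x$excluded))
    graphics::points(x$excluded$t, x$excluded$vo2, pch = 4, col = "grey70")
  tt <- seq(min(x$data$t), max(x$data$t), by = 0.5)
  graphics::lines(tt, predict(x, tt), lwd = 2)
  graphics::abline(v = x$coefficients[["td"]], lty = 3)
  invisible(x)
}
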