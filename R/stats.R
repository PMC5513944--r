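#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] that rejects degenerate
#' (zero-variance) input instead of returning `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and two-sided `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference `x - y`) and 95% limits of agreement
#' (1.96 SD of the differences), each also expressed as a percentage of the
#' total variation of the pooled values. "Total variation" is not a
#' standardized denominator; the default is the range (max - min) of the
#' pooled paired values, switchable to the pooled mean.
#'
#' @param x,y paired measurements (equal length >= 2).
#' @param denominator `"range"` (default) or `"mean"` of the pooled values,
#'   used for the percentage scaling.
#' @return list of class `bland_altman`: `bias`, `loa` (1.96 SD), `bias_pct`,
#'   `loa_pct`, `n`, `denominator`, `denom_value`.
#' @examples
#' bland_altman(c(80, 70, 60), c(81, 69, 62))
#' @export
bland_altman <- function(x, y, denominator = c("range", "mean")) {
  denominator <- match.arg(denominator)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  if (length(x) < 2L) stop("need >= 2 pairs")
  d <- x - y
  bias <- mean(d)
  loa <- 1.96 * stats::sd(d)
  pooled <- c(x, y)
  denom <- if (denominator == "range") diff(range(pooled)) else mean(pooled)
  structure(list(bias = bias, loa = loa,
                 bias_pct = if (denom != 0) 100 * abs(bias) / denom else NA_real_,
                 loa_pct = if (denom != 0) 100 * loa / denom else NA_real_,
                 n = length(x), denominator = denominator, denom_value = denom),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.3f, LoA (1.96 SD) = %.3f\n",
              x$n, x$bias, x$loa))
  cat(sprintf("  as %% of pooled %s (%.3f): bias %.2f%%, CI95 %.2f%%\n",
              x$denominator, x$denom_value, x$bias_pct, x$loa_pct))
  invisible(x)
}

#' Group 95% confidence interval as a percentage of the mean
#'
#' `100 * 1.96 * sd(values) / mean(values)` — the group-level CI95 used to
#' compare the spread of time-constant and MNG estimates on a common,
#' unit-free scale.
#'
#' @param values numeric vector, n >= 2, non-zero mean.
#' @return CI95 as a percentage of the group mean.
#' @export
group_ci95_pct <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: percentage CI95 undefined")
  100 * 1.96 * stats::sd(values) / m
}

#' Sample size versus effect size for t-tests
#'
#' Number of subjects (per group for the two-sample test) needed to detect
#' each effect size at the given power and significance level, via the
#' noncentral-t power computation of [stats::power.t.test()], rounded up
#' and floored at 2.
#'
#' @param effect_sizes vector of effect sizes (same units as `sd`), > 0.
#' @param sd standard deviation of the index, > 0.
#' @param power target power (default 0.8).
#' @param sig_level significance level (default 0.05).
#' @param paired use the paired t-test instead of two-sample.
#' @return data.frame with columns `effect_size` and `n`.
#' @examples
#' sample_size_curve(c(5, 10, 20), sd = 10)
#' @export
sample_size_curve <- function(effect_sizes, sd, power = 0.8,
                              sig_level = 0.05, paired = FALSE) {
  if (any(effect_sizes <= 0)) stop("'effect_sizes' must be > 0")
  if (sd <= 0) stop("'sd' must be > 0")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  type <- if (paired) "paired" else "two.sample"
  n <- vapply(effect_sizes, function(d) {
    res <- tryCatch(
      stats::power.t.test(delta = d, sd = sd, power = power,
                          sig.level = sig_level, type = type),
      error = function(e) NULL)  # huge effects: below the solver's n floor
    if (is.null(res)) 2 else max(2, ceiling(res$n))
  }, 1)
  data.frame(effect_size = effect_sizes, n = as.integer(n))
}

#' Sigmoid description of MNG versus the time constant
#'
#' Fits the 4-parameter logistic
#' `MNG = lower + (upper - lower) / (1 + 10^(slope (log10(tau) - inflection)))`
#' by Levenberg-Marquardt least squares. Over the physiological range
#' (10 < tau < 100 s) the logistic mid-section is nearly linear on the
#' log10(tau) axis, so a linear fit in log10(tau) over that sub-range is
#' reported alongside for comparison.
#'
#' @param taus time constants (s), > 0, >= 5 points spanning the transition.
#' @param mngs MNG values (%) matching `taus`.
#' @param phys_range tau range (s) for the linear comparison fit, default
#'   c(10, 100).
#' @return object of class `sigmoid_fit`: `coefficients` (`lower`, `upper`,
#'   `inflection` in log10 s, `slope`), `r` (correlation of fitted vs
#'   observed), `linear_r` (Pearson r of MNG vs log10(tau) on the
#'   physiological sub-range, `NA` if fewer than 3 points fall in it), and
#'   the `nls` object.
#' @export
sigmoid_fit <- function(taus, mngs, phys_range = c(10, 100)) {
  if (length(taus) != length(mngs)) stop("'taus' and 'mngs' lengths differ")
  if (length(taus) < 5L) stop("need >= 5 points to fit 4 parameters")
  if (any(taus <= 0)) stop("'taus' must be > 0")
  dat <- data.frame(lt = log10(taus), mng = mngs)
  start <- list(lower = min(mngs), upper = max(mngs),
                inflection = stats::median(dat$lt), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mng ~ lower + (upper - lower) / (1 + 10^(slope * (lt - inflection))),
      data = dat, start = start,
      lower = c(lower = -Inf, upper = -Inf, inflection = -Inf, slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("sigmoid fit failed to converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  if (cf[["lower"]] >= cf[["upper"]])
    stop("degenerate sigmoid: lower asymptote >= upper asymptote")
  in_phys <- taus >= phys_range[1L] & taus <= phys_range[2L]
  linear_r <- if (sum(in_phys) >= 3L)
    stats::cor(log10(taus[in_phys]), mngs[in_phys]) else NA_real_
  structure(list(coefficients = cf,
                 r = stats::cor(stats::fitted(fit), mngs),
                 linear_r = linear_r, phys_range = phys_range, nls = fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Sigmoid (4-parameter logistic) fit of MNG vs log10(tau)\n")
  cat(sprintf("  asymptotes %.1f%% .. %.1f%%, inflection at tau = %.1f s, slope = %.2f\n",
              cf[["lower"]], cf[["upper"]], 10^cf[["inflection"]], cf[["slope"]]))
  cat(sprintf("  r = %.4f; linear r over tau in [%g, %g] s: %.4f\n",
              x$r, x$phys_range[1L], x$phys_range[2L], x$linear_r))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) 10^object$nls$m$getEnv()$lt
         else if (is.data.frame(newdata)) newdata$tau else as.numeric(newdata)
  cf <- object$coefficients
  cf[["lower"]] + (cf[["upper"]] - cf[["lower"]]) /
    (1 + 10^(cf[["slope"]] * (log10(tau) - cf[["inflection"]])))
}
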