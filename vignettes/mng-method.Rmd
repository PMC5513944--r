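---
title: "Mean normalized gain: frequency-domain assessment of VO2 kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean normalized gain: frequency-domain assessment of VO2 kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mngkin)
```

## The problem

The speed at which pulmonary oxygen uptake (VO2) adapts to a change in work
rate is a marker of aerobic fitness: a fast response (small time constant
τ) indicates an aerobic system that meets a new energy demand quickly. The
classical measurement fits a delayed mono-exponential to the on-transient of
a constant-load step,

VO2(t) = a0 + a (1 − e^−(t−TD)/τ),

but breath-by-breath VO2 is noisy (approximately white Gaussian
fluctuation around the underlying response), so a single step test yields a
τ with a very wide confidence interval, and practice is to repeat and
ensemble-average many transitions.

The mean normalized gain (MNG) is a frequency-domain alternative built on
pseudorandom binary sequence (PRBS) exercise: the work rate switches
pseudo-randomly between two moderate levels, the periodic response is
decomposed into Fourier harmonics, and the dynamics are summarized by how
well the system preserves its gain at higher harmonics. Because only
periodic components at known frequencies enter the calculation,
non-periodic noise is inherently filtered out, and no kinetic model has to
be assumed.

## The protocol

The PRBS is generated by a 4-stage linear feedback shift register
(`generate_msequence()`): the feedback bit is the modulo-2 sum of stages 1
and 4, the register shifts right, and the ejected bit is the output. Every
non-zero seed walks through all 15 non-zero states, so the output is the
maximal-length sequence of period 15 with an 8:7 symbol balance; different
seeds produce cyclic rotations of the same sequence. Each bit is held for
30 s at 25 W (bit 0) or 100 W (bit 1), giving a 450-s period
(`prbs_protocol()`) and a fundamental frequency f1 = 1/450 ≈ 0.0022 Hz.
Both levels stay within moderate intensity, where the VO2 response is
adequately linear.

Two register conventions are not dictated by the method and are exposed as
parameters: the seed (default `c(1,1,1,1)`) and the bit-to-level mapping
(1 → high). Neither affects the MNG, because rotations and complements of
the bit sequence change only the phases of the harmonics, never their
amplitudes; a property test asserts this shift invariance. The phase does
matter for the *time-domain* window (below): the default seed places the
longest high run at the start of the period, whereas the rotated seed
`c(0,1,0,0)` places the canonical 90-s-low → 120-s-high stretch so that the
step onset falls at t = 180 s. `extract_fit_window()` validates the
requested window against the actual runs and lists them when the phase does
not match.

## Frequency-domain estimator

`harmonic_decomposition()` computes, over exactly one period (no taper, no
zero-padding — the signal is periodic by construction),

A_h = (1/N) Σ x(t) cos(2π h f1 t),  B_h = (1/N) Σ x(t) sin(2π h f1 t),
Amp_h = √(A_h² + B_h²),

so the reconstruction carries a factor 2 and a pure cosine of amplitude 10
at f1 has Amp_1 = 5. The convention is irrelevant for every reported
quantity: gains are ratios of output to input amplitudes and the MNG is
additionally normalized, so any common scaling cancels (tested).

`gain_profile()` forms gAmp_h = VO2Amp_h / WAmp_h (ml·min⁻¹·W⁻¹),
normalizes each gain as a percentage of gAmp_1, and averages harmonics 2–4
into the MNG. Harmonic 1 carries essentially the steady-state (static)
gain, which varies between individuals for reasons unrelated to kinetics;
dividing by it isolates the temporal dynamics. The analysis stops at h = 4
(0.009 Hz) because circulatory distortions compromise linearity above
roughly 0.01 Hz; `run_extreme_tau_study()` supports the wider ranges 2–3,
2–5 and 2–10 for methodological exploration. For a first-order system the
closed form

MNG(τ) = 100 · mean_h √((1 + (2π f1 τ)²) / (1 + (2π h f1 τ)²))

(`analytic_mng()`) is strictly decreasing in τ and spans (36.1%, 100%) for
h = 2–4; it is the independent oracle against which the whole
simulate → decompose → gain pipeline is tested (agreement well within 1
percentage point for τ between 10 and 100 s).

The user-facing estimator is `mng_fit(vo2, protocol)`, which accepts a
second-by-second series spanning one period or a raw breath record, and has
`print`, `summary`, `coef` and `plot` methods.

## Synthetic data

`first_order_response()` integrates dy/dt = (a0 + G(u(t−td) − low) − y)/τ
with the exact zero-order-hold update: within every interval where the
(possibly delayed) input is constant, y relaxes exponentially toward its
target, so the discrete solution is exact and the only approximation in the
pipeline is 1-s sampling. Euler integration was rejected because its
step-size error would contaminate the gain spectrum. The simulation runs
`n_warmup_periods` (default 2) discarded periods before the returned one,
mirroring the discarded warm-up PRBS of testing practice; for τ > ~65 s
the warm-up extends automatically until consecutive periods agree to 1e-6
relative, which matters only for the extreme-τ sweep (up to 1500 s).

The reference in-silico study (`run_insilico_study()`) uses ten published
(a0, a1, τ) combinations spanning baselines 125–400 ml·min⁻¹, amplitudes
600–900 ml·min⁻¹ and time constants 15–52 s; the package reproduces all
ten printed MNG values (integer percent) and average absolute gains (one
decimal) at printed precision, and the acceptance script recomputes a
subset of them from scratch. A grid over the same a0/a1 ranges at fixed τ
moves the MNG by less than 0.1 percentage points — the normalization
really does remove the amplitude parameters.

`breath_sample()` is the measurement model: breath end-times with
log-normal intervals (mean 3 s, CV 0.2 by default — a typical moderate-
exercise breathing rate) and i.i.d. Gaussian noise per breath,
level-independent, truncated at zero. These parameters are the package's
own plumbing choices (the white-noise characterization of breath-to-breath
fluctuation motivates the Gaussian form but prescribes no generator) and
are all exposed. What the generator does **not** emulate: the
cardio-dynamic (phase I) component, slow-component nonlinearity above
moderate intensity, CO2/ventilation coupling, or any periodic noise from
circulation. Passing tests therefore demonstrate correctness of the
*method*, not every property of human data — in particular, experimental
MNG values sit systematically below the first-order prediction because the
mouth-measured response includes transport delay and dispersion that a
pure first-order muscle model lacks.

## Preprocessing

Breath records are linearly interpolated second-by-second
(`interpolate_1s()`, no extrapolation; each breath value anchored at its
end-timestamp). The optional moving average (`moving_average()`, windows
3/5/7 s) truncates its window at the edges — the mean of available samples
— rather than padding, preserving length without fabricating data. The
optional low-pass filter (`lowpass()`) is a 4th-order Butterworth at
0.075 Hz applied forward and backward, because zero phase is essential for
both the harmonic phases and the time-domain onset; the realization was an
open choice (only the cutoff is standard). The recursive filter is
initialized by odd-reflection padding (10/cutoff samples) so a constant
passes unchanged and edge transients are suppressed. `ensemble_average()`
requires pre-aligned grids and refuses anything else: "time alignment"
across repetitions is a protocol property (repetitions are cut from a
continuous record), not something the package guesses. All four operators
are linear and preserve the period mean to better than 0.1%; tests assert
that MNG changes by under 1 percentage point with any moving-average
window, which is why filtering choices barely matter for the
frequency-domain branch.

## Time-domain reference

`extract_fit_window()` cuts the final 10 s of the 90-s low period and the
120 s of the following high period, flagging the first 20 s after onset as
the cardio-dynamic phase; `fit_monoexp()` then fits the delayed
exponential by Levenberg–Marquardt with starts a0 = baseline mean,
a = last-30-s mean − a0, τ = 30 s, TD = 15 s and bounds τ ∈ (0.1, 200] s,
TD ∈ [0, 60] s (generous around the physiological 10–100 s). Baseline
samples enter the fit with model value a0 for t < TD — the model is
otherwise undefined before the delay, and joint fitting of the baseline is
the standard phase-II convention; on model-generated data the fit is exact
to solver tolerance either way. Confidence intervals and p-values use the
asymptotic normal approximation (estimate ± t·SE); MRT = τ + TD by
construction. The fit object supports `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals`, `simulate` and `plot`.

Two simulation studies frame the comparison with the MNG. First, parameter
recovery: with white Gaussian noise (sd 120 ml·min⁻¹) on the
second-by-second window — the scale the fit operates on — the mean of 200
single-repetition τ estimates is within 2 s of the truth, and
ensemble-averaging 8 repetitions before fitting visibly narrows the τ
spread. When noise is instead injected per breath and interpolated, the
single-repetition τ distribution becomes strongly right-skewed (only ~40
independent breaths cover the window), which is precisely the elevated
single-test τ variability that motivates the frequency-domain index; the
recovery test deliberately uses the grid-noise design so it measures the
estimator, not the resampler. Second, the variability ordering: across
matched noisy replicates, the group CI95 (1.96·SD as % of the mean,
`group_ci95_pct()`) of single-repetition τ estimates exceeds that of MNG
estimates computed from the very same series. Only the ordering is
asserted — the published ≈70%/≈30% levels belong to human data this
package does not claim to reproduce.

## Agreement statistics

`bland_altman()` reports bias and 1.96·SD limits of agreement, expressed
as percentages of the "total variation" of the pooled values. That
denominator is genuinely ambiguous in the source literature; the package
defaults to the pooled range (max − min) and exposes a mean-based
alternative rather than pretending the convention is settled.
`sample_size_curve()` wraps the noncentral-t power computation
(`stats::power.t.test`) for two-sample and paired designs, rounding up and
flooring at n = 2. `sigmoid_fit()` describes MNG versus τ with a
4-parameter logistic in log10 τ,

MNG = lower + (upper − lower) / (1 + 10^(slope·(log10 τ − inflection))),

recovering the analytic asymptotes (≈100% and ≈36% for h 2–4) on the
extreme-τ sweep. The companion linear fit is reported on the log10 τ
scale over τ ∈ [10, 100] s: on that axis the logistic mid-section is
nearly linear (|r| within 0.01 of the sigmoid's), which is the quantitative
sense in which the sigmoid can be simplified to a line over the
physiological range. On the raw τ axis the curvature is noticeably larger,
so the scale matters and is stated explicitly wherever the linear
simplification is used.

## Numerical choices and problem sizes

- Simulation and analysis grid: dt = 1 s, N = 450 samples per period —
  matching the second-by-second convention of breath-data practice.
- Exact ZOH updates throughout; fractional delays split each sampling step
  at the delayed input switch, so td need not be a multiple of dt.
- Warm-up: 2 periods by default; automatic extension (periodicity < 1e-6
  relative, doubling up to a cap) for slow systems.
- Harmonic sums are plain O(N·H) projections (H ≤ 10); no FFT is needed at
  this size and the direct sums keep the one-period contract explicit.
- Monte-Carlo test sizes: 200 seeds for τ recovery, 25 groups of 8 for the
  ensemble comparison, 60 matched replicates for the variability ordering,
  50 seeds for the breath-noise sd check — sizes at which the asserted
  effects are far larger than Monte-Carlo error while the whole suite runs
  in seconds.
- Degenerate inputs fail loudly: all-zero register seeds, non-dividing dt,
  grids outside breath support, even moving-average windows, cutoffs at or
  above Nyquist, zero input amplitudes, all-equal correlation inputs, and
  non-converging fits all raise informative errors rather than returning
  silently wrong numbers.

## Limitations

The package analyzes and simulates first-order linear responses. Real VO2
data contain a cardio-dynamic phase, possible slow components, and
circulatory distortions concentrated at higher frequencies; the MNG's
restriction to h ≤ 4 and the 20-s exclusion in the time-domain branch are
mitigations, not removals, of these effects. The time-domain window is
nested inside the PRBS, so its baseline is only 90 s of low work rate —
fits on simulated PRBS-embedded windows recover τ well but show a slightly
elevated baseline, exactly as expected when the low period has not fully
settled. Nothing in the package attempts to reproduce specific human
results; the validated claims are the ones its own simulations and tests
compute.
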