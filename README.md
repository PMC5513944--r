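# mngkin

Mean normalized gain (MNG) analysis of oxygen-uptake kinetics during
pseudorandom binary sequence (PRBS) exercise.

## What it is for

Exercise physiologists characterize aerobic fitness by how fast pulmonary
VO2 adapts to a change in work rate. The classical index is the time
constant τ of a delayed mono-exponential fitted to a step on-transient,

&nbsp;&nbsp;&nbsp;&nbsp;VO2(t) = a0 + a (1 − e^−(t−TD)/τ),

but breath-by-breath noise makes single-test τ estimates very uncertain,
forcing many repeated transitions. The MNG is a frequency-domain
alternative computed from a PRBS protocol — work rate switching
pseudo-randomly between 25 and 100 W in fifteen 30-s units (450-s period).
Input and output are decomposed into Fourier harmonics of the fundamental
f1 = 1/450 Hz, the harmonic gains

&nbsp;&nbsp;&nbsp;&nbsp;gAmp_h = VO2Amp_h / WAmp_h&nbsp;&nbsp;(ml·min⁻¹·W⁻¹)

are normalized by the fundamental gain, and

&nbsp;&nbsp;&nbsp;&nbsp;MNG = 100 · mean(gAmp_2, gAmp_3, gAmp_4) / gAmp_1&nbsp;&nbsp;(%).

A fast aerobic system keeps its gain at higher harmonics (MNG near 100%);
a slow one attenuates them (for a first-order system the MNG decreases
monotonically from 100% toward 36.1% as τ grows). Because only periodic
components at known frequencies enter, random breath noise is inherently
filtered out and no kinetic model is assumed.

The package implements the full chain: PRBS generation from a 4-stage
shift register, an exact first-order simulator with a breath-by-breath
measurement model, preprocessing (1-s interpolation, moving average,
zero-phase low-pass, ensemble averaging), the MNG estimator, the
mono-exponential time-domain reference fit (τ, TD, MRT), and the
agreement/consistency statistics used to compare the two (Pearson,
Bland–Altman, group CI95, t-test sample-size curves, sigmoid description
of MNG vs τ).

## Worked example

```r
library(mngkin)

## frequency branch: simulate a fast responder (tau = 15 s) and estimate MNG
wr  <- prbs_protocol(generate_msequence())                      # 25/100 W, 15 x 30 s
y   <- first_order_response(wr, first_order_params(a0 = 300, a1 = 700, tau_s = 15))
fit <- mng_fit(y, wr)
summary(fit)
#> <gain_profile>
#>  h  freq_hz input_amp output_amp  gain normalized_gain_pct
#>  1 0.002222     9.927      90.69 9.135              100.00
#>  2 0.004444     9.710      83.60 8.609               94.24
#>  3 0.006667     9.356      73.94 7.903               86.52
#>  4 0.008889     8.872      63.48 7.155               78.33
#> MNG over h = 2..4: 86.36 %
#> Mean absolute gain over h = 2..4: 7.89 ml/min/W
```

The gain at harmonic 1 (9.1 ml·min⁻¹·W⁻¹ here) is essentially the static
gain; the decline across harmonics 2–4 reflects the 15-s time constant,
and their normalized mean — MNG = 86% — is the kinetics index. Slower
systems give lower values (τ = 45 s → 58%).

```r
## time-domain branch: the embedded 90 s low -> 120 s high window
wr2 <- prbs_protocol(generate_msequence(c(0, 1, 0, 0)))  # phase with onset at 180 s
y2  <- first_order_response(wr2, first_order_params(900, 750, 34, td = 15))
ef  <- fit_monoexp(extract_fit_window(y2, fit_window(), protocol = wr2))
ef
#> Mono-exponential VO2 kinetics fit
#>   a0 = 963.2 ml/min, a = 686.8 ml/min, tau = 34.0 s, TD = 16.4 s
#>   MRT = 50.4 s, r2 = 0.9999, SSE = 284.9 (n = 110)
```

The time constant is recovered exactly; the slightly elevated baseline is
real — the 90-s low period inside a PRBS never fully settles, which is one
reason the frequency-domain index is attractive.

For noisy end-to-end studies see `run_pipeline()`,
`run_insilico_study()` (the ten-parameter-set reference study) and
`run_extreme_tau_study()`; a thin command-line wrapper with subcommands
`protocol`, `simulate`, `mng`, `fit`, `agree`, `power` and `study` is in
`inst/scripts/mngkin.R`.

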