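Package: mngkin
Title: Mean Normalized Gain Analysis of Oxygen Uptake Kinetics During
    Pseudorandom Binary Sequence Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the temporal dynamics of pulmonary
    oxygen uptake (VO2) during pseudorandom binary sequence (PRBS) exercise
    testing. Generates the two-level PRBS work-rate protocol from a 4-stage
    linear feedback shift register, simulates first-order VO2 responses with
    an exact zero-order-hold update and a breath-by-breath measurement model,
    preprocesses breath data (second-by-second interpolation, moving-average
    and zero-phase low-pass filtering, ensemble averaging), and estimates the
    mean normalized gain (MNG) from Fourier harmonic input:output gains
    alongside the classical mono-exponential time-domain fit (time constant,
    time delay, mean response time). Includes agreement and consistency
    statistics (Pearson correlation, Bland-Altman, group 95% confidence
    intervals, t-test sample-size curves, sigmoid description of MNG versus
    the time constant).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    graphics,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
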