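test_that("pearson handles exact, null and degenerate cases", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(2, 6)), "zero variance")
  expect_error(pearson(x, x[1:3]), "equal length")
  set.seed(21)
  a <- rnorm(2000); b <- sample(a)
  expect_lt(abs(pearson(a, b)$r), 0.08)
})

test_that("time constant and MNG are strongly negatively correlated in silico", {
  tab <- run_insilico_study()
  expect_lt(pearson(tab$tau_s, tab$mng)$r, -0.9)
})

test_that("Bland-Altman bias and limits behave exactly on constructed pairs", {
  x <- c(80, 70, 60, 55)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$loa, 0)
  ba <- bland_altman(x, x + 5)
  expect_equal(ba$bias, -5)
  expect_equal(ba$loa, 0)
  expect_error(bland_altman(1, 1), ">= 2")
  # percentage denominators
  ba_r <- bland_altman(x, x + 5, denominator = "range")
  expect_equal(ba_r$denom_value, diff(range(c(x, x + 5))))
  ba_m <- bland_altman(x, x + 5, denominator = "mean")
  expect_equal(ba_m$denom_value, mean(c(x, x + 5)))
})

test_that("paired MNG replicates from two synthetic days agree without bias", {
  wr <- std_protocol()
  taus <- c(20, 28, 35, 42, 50, 60)   # six synthetic subjects
  # each "day" is an ensemble of four repetitions, as in multi-PRBS sessions
  mng_day <- function(day) vapply(seq_along(taus), function(i) {
    truth <- first_order_response(wr, first_order_params(300, 700, taus[i]))
    reps <- lapply(1:4, function(k) {
      b <- breath_sample(pad_periodic(truth, 12), noise_sd = 80,
                         seed = 10000 * day + 10 * i + k)
      interpolate_1s(b, grid_start = 0, grid_end = 449)
    })
    mng_fit(ensemble_average(reps), wr)$mng
  }, 1)
  ba <- bland_altman(mng_day(1), mng_day(2))
  expect_lt(abs(ba$bias), 3)
  expect_gt(pearson(mng_day(1), mng_day(2))$r, 0.9)
})

test_that("group CI95 percentage identities hold", {
  expect_equal(group_ci95_pct(rep(42, 5)), 0)
  v <- c(8, 10, 12)
  expect_equal(group_ci95_pct(v), 100 * 1.96 * sd(v) / mean(v))
  vv <- rnorm(50, 100, 5)
  vv <- (vv - mean(vv)) / sd(vv) * (100 / 1.96) + 100  # sd = mean/1.96
  expect_equal(group_ci95_pct(vv), 100, tolerance = 1e-9)
  expect_error(group_ci95_pct(7), ">= 2")
  expect_error(group_ci95_pct(c(-1, 1)), "zero mean")
})

test_that("sample-size curves follow classical power behaviour", {
  n17 <- sample_size_curve(10, sd = 10)$n
  expect_equal(n17, 17)
  big <- sample_size_curve(1e9, sd = 10)$n
  expect_equal(big, 2)
  curve <- sample_size_curve(c(2, 4, 8, 16), sd = 10)
  expect_true(all(diff(curve$n) < 0))      # non-increasing in effect size
  ratio <- sample_size_curve(5, sd = 10)$n / sample_size_curve(10, sd = 10)$n
  expect_gt(ratio, 3.4); expect_lt(ratio, 4.6)
  # paired test needs fewer subjects than two independent groups
  expect_lte(sample_size_curve(10, sd = 10, paired = TRUE)$n, n17)
  expect_error(sample_size_curve(10, sd = 10, power = 1.2), "power")
  expect_error(sample_size_curve(-1, sd = 10), "> 0")
})

test_that("sigmoid fit recovers known logistic parameters", {
  lt <- seq(-3, 3.2, length.out = 40)
  truth <- c(lower = 36.1, upper = 100, inflection = log10(30), slope = 1.8)
  mng <- truth["lower"] + (truth["upper"] - truth["lower"]) /
    (1 + 10^(truth["slope"] * (lt - truth["inflection"])))
  fit <- sigmoid_fit(10^lt, mng)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-4)
  expect_gt(fit$r, 0.99999)
})

test_that("extreme-tau sweep yields the analytic asymptotes and near-linear mid-section", {
  sweep <- run_extreme_tau_study(h_ranges = list(2:4))
  fit <- sigmoid_fit(sweep$tau_s, sweep$mng)
  expect_lt(abs(coef(fit)[["upper"]] - 100), 2)
  expect_lt(abs(coef(fit)[["lower"]] - 100 * mean(1 / (2:4))), 2)
  # physiological sub-range: linear (in log10 tau) fit is nearly as good
  taus <- seq(10, 100, by = 5)
  sub <- sigmoid_fit(taus, analytic_mng(taus))
  expect_lt(abs(abs(sub$r) - abs(sub$linear_r)), 0.01)
})
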