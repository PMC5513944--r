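# shared fixtures: the standard 25/100 W, 15 x 30 s protocol and the
# phase-rotated variant whose longest low->high step sits at t = 180 s
std_protocol <- function() prbs_protocol(generate_msequence())

step_protocol <- function() prbs_protocol(generate_msequence(c(0L, 1L, 0L, 0L)))

# all 15 non-zero states of the 4-stage register
all_seeds <- function() {
  g <- expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1, s4 = 0:1)
  g <- g[rowSums(g) > 0, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

# independent register oracle: one shift-register update
register_step <- function(s) c((s[1] + s[4]) %% 2L, s[1:3])

# noiseless step-window data generated straight from the delayed
# mono-exponential model (onset-relative time)
model_step_data <- function(a0 = 900, a = 750, tau = 34, td = 15,
                            baseline_span = 10, step_span = 120,
                            cardio_exclusion = 20) {
  t <- c(seq(-baseline_span, -1), seq(0, step_span - 1))
  y <- a0 + a * (1 - exp(-(t - td) / tau)) * (t >= td)
  data.frame(t = t, vo2 = y, excluded = t >= 0 & t < cardio_exclusion)
}
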