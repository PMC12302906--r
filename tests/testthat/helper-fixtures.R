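# Small shared fixtures, built in code at test time.

fix_conditions <- enumerateConditions()

fix_env_12L <- gcEnvSeries(fix_conditions[fix_conditions$condition_id == "L12_T30_D20", ],
                           days = 5)

# A generously clipped, moderately gated parameter set used across tests.
fix_nl <- nlParams(window_h = 6, lag_h = 3, gate_peak_h = 6, gate_depth = 1,
                   gate_sharp = 2, clip_lo = -100, clip_hi = 100)

# Random-but-reproducible design for linear-fit tests.
make_design <- function(n, seed = 1) {
  withr::with_seed(seed, {
    samp <- data.frame(clock_time_h = runif(n, 0, 24),
                       age_days = runif(n, 10, 40))
    x <- rnorm(n)
    list(samples = samp, x = x,
         X = designRow(samp$clock_time_h, samp$age_days, x))
  })
}

# Reference Benjamini-Hochberg step-up, written independently of p.adjust.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
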