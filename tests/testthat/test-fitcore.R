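test_that("the diel gate has the advertised shape", {
  nl0 <- nlParams(6, gate_depth = 0, gate_peak_h = 7, gate_sharp = 2)
  expect_equal(gateWeight(seq(0, 23), nl0), rep(1, 24))

  nl1 <- nlParams(6, gate_peak_h = 7, gate_depth = 1, gate_sharp = 2)
  expect_equal(gateWeight(7, nl1), 1)
  expect_equal(gateWeight(19, nl1), 0)          # peak + 12
  expect_equal(gateWeight(13, nl1), 0.25)       # ((1+0)/2)^2 at peak + 6
  # periodicity
  expect_equal(gateWeight(3.2, nl1), gateWeight(27.2, nl1))
})

test_that("gate weights stay in [1-depth, 1] and sharpen with the exponent", {
  clock <- seq(0, 24, by = 0.1)
  for (depth in c(0, 0.3, 0.8, 1)) {
    for (sharp in c(0.5, 1, 4, 16)) {
      g <- gateWeight(clock, nlParams(6, gate_peak_h = 11, gate_depth = depth,
                                      gate_sharp = sharp))
      expect_true(all(g >= 1 - depth - 1e-12 & g <= 1 + 1e-12))
    }
  }
  # the 24-h gate integral decreases monotonically in sharpness at depth 1
  ints <- vapply(c(1, 2, 4, 8, 16), function(w)
    mean(gateWeight(clock, nlParams(6, gate_peak_h = 11, gate_depth = 1,
                                    gate_sharp = w))), numeric(1))
  expect_true(all(diff(ints) < 0))
})

test_that("the gated environmental input matches a brute-force window sum", {
  env <- fix_env_12L
  # ungated mean of a constant inside the clipping range is the constant
  const_env <- EnvSeries(envTime(env), rep(23, length(env)),
                         envIrradiance(env))
  nl0 <- nlParams(6, 3, gate_depth = 0, clip_lo = -100, clip_hi = 100)
  expect_equal(envInput(const_env, c(90, 100.5), nl0, "temperature"),
               c(23, 23))
  # clipping saturation: everything above clip_hi contributes clip_hi
  nl_hi <- nlParams(6, 0, gate_peak_h = 3, gate_depth = 0.5, gate_sharp = 1,
                    clip_lo = 0, clip_hi = 10)
  x <- envInput(env, 96, nl_hi, "temperature")
  s <- envTime(env) >= 90 & envTime(env) < 96
  expect_equal(x, 10 * mean(gateWeight(envClock(env)[s], nl_hi)))

  # brute-force oracle over random parameter settings
  withr::with_seed(42, {
    for (k in 1:10) {
      nl <- nlParams(window_h = sample(c(1.5, 6, 12, 30), 1),
                     lag_h = sample(c(0, 2.5, 6), 1),
                     gate_peak_h = runif(1, 0, 24),
                     gate_depth = runif(1),
                     gate_sharp = exp(runif(1, 0, 2)),
                     clip_lo = runif(1, 15, 22), clip_hi = runif(1, 25, 40))
      tt <- runif(3, 80, 110)
      got <- envInput(env, tt, nl, "temperature")
      want <- vapply(tt, function(t) {
        s <- envTime(env)
        keep <- s >= t - nl["lag_h"] - nl["window_h"] & s < t - nl["lag_h"]
        e <- pmin(pmax(envTemperature(env)[keep], nl["clip_lo"]), nl["clip_hi"])
        mean(gateWeight(envClock(env)[keep], nl) * e)
      }, numeric(1))
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("the environmental input ignores history before the window", {
  square <- function(time) {
    clock <- time %% 24
    EnvSeries(time, ifelse(clock < 12, 30, 20),
              ifelse(clock < 12, 1, 0), clock)
  }
  env_long <- square(seq(-48, 119.5, by = 0.5))   # two extra days of history
  env_short <- square(seq(48, 119.5, by = 0.5))
  t_eval <- c(100, 105.5)
  expect_equal(envInput(env_long, t_eval, fix_nl, "temperature"),
               envInput(env_short, t_eval, fix_nl, "temperature"))
  expect_error(envInput(env_short, 50, fix_nl, "temperature"),
               "earliest valid time")
})

test_that("the design row encodes age, clock pair and interactions", {
  expect_equal(unname(designRow(0, 0, 0)[1, ]), c(1, 0, 1, 0, 0, 0, 0, 0))
  r6 <- designRow(6, 0, 0)[1, ]
  expect_equal(unname(r6[c("clock_cos", "clock_sin")]), c(0, 1),
               tolerance = 1e-12)
  r <- designRow(18, 2, 3)[1, ]
  expect_equal(unname(r), c(1, 2, cos(3 * pi / 2), sin(3 * pi / 2), 3, 6,
                            3 * cos(3 * pi / 2), 3 * sin(3 * pi / 2)),
               tolerance = 1e-12)
})

test_that("the adaptive group LASSO matches least squares at zero penalty", {
  d <- make_design(64, seed = 7)
  beta <- c(1, 0.05, 0.5, -0.3, 0.8, 0, 0.1, 0)
  withr::with_seed(8, y <- as.numeric(d$X %*% beta) + rnorm(64, 0, 0.1))
  f0 <- fitLinearAGL(d$X, y, lambdas = 0)
  ols <- unname(coef(lm(y ~ d$X[, -1])))
  expect_lt(max(abs(unname(f0$coefs) - ols)), 1e-6)
})

test_that("the adaptive group LASSO recovers single-group signals exactly", {
  # signal only in the clock group: the other groups must be zeroed and
  # the fit must match least squares on the true support
  d <- make_design(400, seed = 9)
  beta <- c(2, 0, 0.9, -0.6, 0, 0, 0, 0)
  y <- as.numeric(d$X %*% beta)
  f <- fitLinearAGL(d$X, y)
  expect_equal(unname(f$coefs[c("age", "env", "env_age", "env_cos", "env_sin")]),
               rep(0, 5))
  oracle <- unname(coef(lm(y ~ cos(2 * pi * d$samples$clock_time_h / 24) +
                             sin(2 * pi * d$samples$clock_time_h / 24))))
  expect_lt(max(abs(unname(f$coefs[c("intercept", "clock_cos", "clock_sin")]) -
                    oracle)), 1e-3)
  expect_false(f$env_selected)
})

test_that("degenerate and fully-penalized fits collapse to the intercept", {
  d <- make_design(32, seed = 10)
  expect_warning(f <- fitLinearAGL(d$X, rep(2, 32)), "intercept-only")
  expect_equal(unname(f$coefs), c(2, rep(0, 7)))
  withr::with_seed(11, y <- rnorm(32, 5))
  f_inf <- fitLinearAGL(d$X, y, lambdas = 1e6)
  expect_equal(unname(f_inf$coefs[-1]), rep(0, 7))
  expect_equal(unname(f_inf$coefs[1]), mean(y))
  expect_error(fitLinearAGL(d$X[1:10, ], y[1:10]), "16")
})

test_that("prediction composes the design with the fitted coefficients", {
  coefs <- setNames(c(1, 0, 0, 0, 2, 0, 0, 0),
                    c("intercept", "age", "clock_cos", "clock_sin",
                      "env", "env_age", "env_cos", "env_sin"))
  # constant trace at 1.5 within clipping: gated mean (depth 0) is 1.5
  env <- EnvSeries(seq(0, 119.5, by = 0.5), rep(1.5, 240), rep(0, 240))
  fit <- new("GeneModelFit", gene_id = "g", predictor = "temperature",
             nl = nlParams(6, 0, gate_depth = 0, clip_lo = -10, clip_hi = 10),
             coefs = coefs, criterion = 0, n_train = 16L)
  samp <- data.frame(sample_id = "s1", condition_id = "c", time_h = 100,
                     clock_time_h = 4, age_days = 20)
  expect_equal(predict(fit, list(c = env), samp), 4.0)

  # a 'neither' fit is independent of the environment
  nofit <- new("GeneModelFit", gene_id = "g", predictor = "neither",
               nl = fix_nl, coefs = setNames(c(3, 0.1, 1, -1, 0, 0, 0, 0),
                                             names(coefs)),
               criterion = 0, n_train = 16L)
  env2 <- EnvSeries(seq(0, 119.5, by = 0.5), rep(40, 240), rep(0, 240))
  expect_equal(predict(nofit, list(c = env), samp),
               predict(nofit, list(c = env2), samp))
})
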