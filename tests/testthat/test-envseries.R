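test_that("chamber traces are square waves matching the condition", {
  env <- fix_env_12L                   # 12L/12D, 30/20 degC
  expect_setequal(unique(envTemperature(env)), c(30, 20))
  day1 <- envClock(env) < 24 & envTime(env) < 24
  expect_true(all(envTemperature(env)[envClock(env) < 12] == 30))
  expect_true(all(envTemperature(env)[envClock(env) >= 12] == 20))
  expect_setequal(unique(envIrradiance(env)), c(1, 0))

  dark <- gcEnvSeries(fix_conditions[fix_conditions$condition_id == "L00_Txx_D25", ],
                      days = 4)
  expect_true(all(envIrradiance(dark) == 0))
  expect_true(all(envTemperature(dark) == 25))

  light <- gcEnvSeries(fix_conditions[fix_conditions$condition_id == "L24_T35_Dxx", ],
                       days = 4)
  expect_true(all(envIrradiance(light) == 1))
  expect_true(all(envTemperature(light) == 35))

  # negative DIF: warm nights make temperature and light anti-correlated
  ndif <- gcEnvSeries(fix_conditions[fix_conditions$condition_id == "L08_T20_D35", ],
                      days = 4)
  one_day <- envTime(ndif) < 24
  expect_lt(cor(envTemperature(ndif)[one_day], envIrradiance(ndif)[one_day]), 0)

  expect_error(gcEnvSeries(fix_conditions[10, ], dt = 0.7), "dt")
})

test_that("synthetic field weather couples temperature and irradiance", {
  fe <- fieldEnvSeries(days = 30, seed = 1)
  expect_gt(cor(envTemperature(fe), envIrradiance(fe)), 0.3)
  expect_true(all(envIrradiance(fe) >= 0))
  # determinism
  fe2 <- fieldEnvSeries(days = 30, seed = 1)
  expect_identical(envTemperature(fe), envTemperature(fe2))
  expect_identical(envIrradiance(fe), envIrradiance(fe2))
  expect_false(identical(envTemperature(fe),
                         envTemperature(fieldEnvSeries(days = 30, seed = 2))))
  # noiseless trace: no irradiance at local midnight
  quiet <- fieldEnvSeries(days = 5, seed = 1, ar_sd = 0, weather_sdlog = 0)
  expect_true(all(envIrradiance(quiet)[envClock(quiet) == 0] == 0))
})

test_that("the chamber grid decorrelates temperature from light given light state", {
  # Pooled across the whole grid the raw correlation is positive (the
  # light-temperature levels sit above the dark levels), but within each
  # light state temperature varies independently of irradiance - which is
  # the property that makes the predictors separable - and the pooled
  # correlation stays well below the field one.
  envs <- lapply(seq_len(nrow(fix_conditions)), function(i)
    gcEnvSeries(fix_conditions[i, ], days = 4))
  tv <- unlist(lapply(envs, envTemperature))
  iv <- unlist(lapply(envs, envIrradiance))
  light <- iv > 0
  r_within_light <- suppressWarnings(cor(tv[light], iv[light]))  # irradiance constant: NA
  expect_true(is.na(r_within_light) || abs(r_within_light) < 0.05)
  rt <- tv - ifelse(light, mean(tv[light]), mean(tv[!light]))
  expect_lt(abs(cor(rt, iv)), 0.05)

  fe <- fieldEnvSeries(days = 30, seed = 1)
  r_field <- cor(envTemperature(fe), envIrradiance(fe))
  expect_gte(r_field, 0.3)
  expect_lt(cor(tv, iv), r_field)
})
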