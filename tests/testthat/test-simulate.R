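test_that("noiseless simulation is exactly invertible by the forward model", {
  conds <- fix_conditions[c(10, 40), ]
  envs <- lapply(seq_len(nrow(conds)), function(i) gcEnvSeries(conds[i, ]))
  names(envs) <- conds$condition_id
  plan <- makeStudySamples(conds)
  truth <- makeTruthSet(3, c("temperature", "radiation", "neither"),
                        seed = 31, noise_sd = 0)
  study <- simulateExpression(truth, envs, plan, seed = 32)
  for (g in seq_along(truth)) {
    fit <- new("GeneModelFit", gene_id = truth[[g]]@gene_id,
               predictor = truth[[g]]@driver, nl = truth[[g]]@nl,
               coefs = truth[[g]]@coefs, criterion = 0, n_train = 0L)
    pred <- predict(fit, envs, sampleMeta(study))
    obs <- exprMatrix(study)[g, ]
    keep <- obs > 0                       # clipped values cannot match
    expect_lt(mae(pred[keep], obs[keep]), 1e-9)
  }
  # reproducibility
  study2 <- simulateExpression(truth, envs, plan, seed = 32)
  expect_identical(exprMatrix(study), exprMatrix(study2))
})

test_that("a constant 'neither' gene simulates to its intercept", {
  env <- fix_env_12L
  samp <- data.frame(time_h = c(90, 96, 102), age_days = 17)
  coefs <- setNames(c(5, 0, 0, 0, 0, 0, 0, 0),
                    c("intercept", "age", "clock_cos", "clock_sin",
                      "env", "env_age", "env_cos", "env_sin"))
  tg <- truthGene("g1", "neither", fix_nl, coefs, noise_sd = 0)
  st <- simulateExpression(list(tg), env, samp, seed = 1)
  expect_equal(unname(exprMatrix(st)[1, ]), c(5, 5, 5))
})

test_that("temperature-driven genes differ between conditions differing only in temperature", {
  conds <- fix_conditions
  pair <- conds[conds$light_hours == 12 & !is.na(conds$light_temp) &
                  conds$dark_temp %in% c(15) & conds$light_temp %in% c(20, 40), ]
  envs <- lapply(seq_len(nrow(pair)), function(i) gcEnvSeries(pair[i, ]))
  names(envs) <- pair$condition_id
  plan <- makeStudySamples(pair, cultivars = 1)
  truth <- makeTruthSet(1, "temperature", seed = 33, noise_sd = 0,
                        age_effect = FALSE)
  st <- simulateExpression(truth, envs, plan, seed = 34)
  meta <- sampleMeta(st)
  a <- exprMatrix(st)[1, meta$condition_id == pair$condition_id[1]]
  b <- exprMatrix(st)[1, meta$condition_id == pair$condition_id[2]]
  expect_gt(max(abs(a - b)), 0.1)
})

test_that("plate swaps exchange annotations but not data, and are involutions", {
  fx <- makeSwapFixture(n_plates = 4, n_genes = 6, seed = 35)
  st <- fx$study
  swapped <- injectPlateSwap(st, "P1", "P2")
  # matrix untouched, metadata moved
  expect_identical(unname(exprMatrix(swapped)), unname(exprMatrix(st)))
  m0 <- sampleMeta(st); m1 <- sampleMeta(swapped)
  expect_false(identical(m0$condition_id, m1$condition_id))
  # the nominal condition of a swapped column now lies about its data
  p1_cols <- which(m0$plate_id == "P1")
  expect_true(all(m1$condition_id[p1_cols] != m0$condition_id[p1_cols]))
  # involution and self-swap identity
  back <- injectPlateSwap(swapped, "P1", "P2")
  expect_identical(unname(exprMatrix(back)), unname(exprMatrix(st)))
  expect_equal(sampleMeta(back)[, names(m0)], m0)
  self <- injectPlateSwap(st, "P3", "P3")
  expect_equal(sampleMeta(self), m0)
  expect_error(injectPlateSwap(st, "P1", "nope"), "unknown plate")
})

test_that("SNP fixtures reproduce the designed error structure", {
  clean <- makeSnpFixture(200, 3, c("A", "B", "A"), error_rate = 0,
                          dropout_rate = 0, seed = 36)
  rep1 <- genotypeConcordance(clean, setNames(c("A", "B", "A"),
                                              unique(clean$sample_id)))
  expect_equal(rep1$prop_match_nominal, rep(1, 3))
  expect_equal(rep1$verdict, rep("pass", 3))

  all_drop <- makeSnpFixture(50, 1, "A", error_rate = 0, dropout_rate = 1,
                             seed = 37)
  expect_true(all(all_drop$call == "none"))

  mix <- makeSnpFixture(2000, 1, "mix", error_rate = 0, dropout_rate = 0.2,
                        seed = 38)
  prop <- genotypeConcordance(mix, c(S001 = "A"))$prop_match_nominal
  expect_equal(prop, 0.5, tolerance = 0.1)   # binomial expectation

  # determinism
  expect_identical(makeSnpFixture(50, 2, "A", seed = 39),
                   makeSnpFixture(50, 2, "A", seed = 39))
})
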