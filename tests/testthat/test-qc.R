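# Plate-swap detection and genotype concordance on synthetic fixtures.

test_that("leave-one-plate-out temperature prediction is accurate on clean data", {
  fx <- makeSwapFixture(n_plates = 8, n_genes = 40, seed = 61)
  pred <- looPlateTemperature(fx$study)
  expect_equal(nrow(pred$plates), 8)
  expect_true(all(pred$plates$mae < 3))
  # clean study: nothing to flag, empty proposal
  prop <- inferSwaps(pred)
  expect_equal(length(prop$pairs), 0)
})

test_that("constant nominal temperature gives exact constant predictions", {
  fx <- makeSwapFixture(n_plates = 4, n_genes = 10, seed = 62)
  st <- fx$study
  SummarizedExperiment::colData(st)$nominal_temp_C <- 25
  pred <- looPlateTemperature(st)
  expect_true(all(pred$predictions$predicted == 25))
  expect_true(all(pred$plates$mae == 0))
})

test_that("an injected plate-swap pair is flagged, paired and corrected", {
  fx <- makeSwapFixture(n_plates = 12, n_genes = 40,
                        swaps = list(c("P1", "P3")), seed = 63)
  pred <- looPlateTemperature(fx$study)
  prop <- inferSwaps(pred)
  expect_setequal(prop$flagged, c("P1", "P3"))
  expect_equal(length(prop$pairs), 1)
  expect_setequal(prop$pairs[[1]], c("P1", "P3"))
  expect_true(all(prop$pair_mae$post < prop$pair_mae$pre))
  ver <- verifyCorrection(fx$study, prop)
  expect_true(ver$accepted)
  expect_equal(length(ver$flagged), 0)
})

test_that("two independent swap pairs are both recovered", {
  fx <- makeSwapFixture(n_plates = 16, n_genes = 40,
                        swaps = list(c("P1", "P4"), c("P2", "P6")), seed = 64)
  pred <- looPlateTemperature(fx$study)
  prop <- inferSwaps(pred)
  got <- lapply(prop$pairs, sort)
  expect_equal(length(got), 2)
  expect_true(list(c("P1", "P4")) %in% got || any(vapply(got, identical,
                                                         logical(1), c("P1", "P4"))))
  expect_true(any(vapply(got, identical, logical(1), c("P2", "P6"))))
  expect_true(verifyCorrection(fx$study, prop)$accepted)
})

test_that("a wrong proposal does not pass the second prediction round", {
  fx <- makeSwapFixture(n_plates = 12, n_genes = 40,
                        swaps = list(c("P1", "P3")), seed = 65)
  pred <- looPlateTemperature(fx$study)
  thr <- inferSwaps(pred)$threshold
  wrong <- list(pairs = list(c("P2", "P5")), threshold = thr)
  ver <- verifyCorrection(fx$study, wrong)
  expect_false(ver$accepted)
  expect_gt(length(ver$flagged), 0)
})

test_that("an empty proposal leaves a clean study unchanged", {
  fx <- makeSwapFixture(n_plates = 6, n_genes = 30, seed = 66)
  pred <- looPlateTemperature(fx$study)
  prop <- inferSwaps(pred)
  ver <- verifyCorrection(fx$study, prop)
  expect_true(ver$accepted)
  expect_equal(ver$predictions$plates$mae, pred$plates$mae, tolerance = 1e-9)
})

test_that("plate predictions are invariant to sample and plate ordering", {
  fx <- makeSwapFixture(n_plates = 6, n_genes = 30, seed = 67)
  st <- fx$study
  withr::with_seed(68, perm <- sample(ncol(st)))
  pred1 <- looPlateTemperature(st)
  pred2 <- looPlateTemperature(st[, perm])
  o1 <- order(pred1$plates$plate_id)
  o2 <- order(pred2$plates$plate_id)
  expect_equal(pred1$plates$mae[o1], pred2$plates$mae[o2], tolerance = 1e-8)
})

test_that("genotype concordance implements the pass / swap / discard bands", {
  calls <- makeSnpFixture(400, 4, c("A", "B", "A", "mix"),
                          error_rate = 0.02, dropout_rate = 0.3, seed = 69)
  nominal <- setNames(c("A", "B", "B", "A"), unique(calls$sample_id))
  rep <- genotypeConcordance(calls, nominal)
  expect_equal(rep$verdict, c("pass", "pass", "swap_candidate", "discard"))
  # proportions are computed over called loci only: brute-force check
  for (i in seq_len(nrow(rep))) {
    cc <- calls[calls$sample_id == rep$sample_id[i], "call"]
    called <- cc %in% c("A", "B")
    expect_equal(rep$n_called[i], sum(called))
    expect_equal(rep$prop_match_nominal[i],
                 mean(cc[called] == nominal[[rep$sample_id[i]]]))
  }
  # zero called loci
  none <- data.frame(sample_id = "S1", locus_id = paste0("L", 1:5),
                     call = "none")
  expect_equal(genotypeConcordance(none, c(S1 = "A"))$verdict, "discard")
  expect_error(genotypeConcordance(
    data.frame(sample_id = "S1", locus_id = "L1", call = "weird"),
    c(S1 = "A")), "categories")
})
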