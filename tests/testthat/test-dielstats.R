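make_two_cultivar_study <- function(mat_a, mat_b, condition = "c1",
                                    times = seq(1.5, 22.5, by = 3)) {
  k <- length(times)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * k)),
    cultivar = rep(c("A", "B"), each = k),
    condition_id = condition, plate_id = "P1",
    clock_time_h = rep(times, 2), age_days = 17,
    sampling_time_index = rep(seq_len(k), 2))
  ExpressionStudy(cbind(mat_a, mat_b), meta)
}

test_that("the expression filter keeps strictly above-threshold genes", {
  m <- rbind(g1 = rep(1, 6), g2 = rep(1.01, 6), g3 = c(0, 0, 0, 0, 0, 6.5))
  meta <- data.frame(sample_id = paste0("s", 1:6), cultivar = "A",
                     condition_id = "c", plate_id = "P1",
                     clock_time_h = 1:6, age_days = 17)
  st <- ExpressionStudy(m, meta)
  expect_equal(filterExpressed(st), c("g2", "g3"))
  # brute force on a random study
  withr::with_seed(51, mr <- matrix(runif(200, 0, 2), 20,
                                    dimnames = list(sprintf("g%02d", 1:20), NULL)))
  str <- ExpressionStudy(mr, data.frame(sample_id = paste0("r", 1:10),
                                        cultivar = "A", condition_id = "c",
                                        plate_id = "P1", clock_time_h = 1:10,
                                        age_days = 17))
  expect_equal(filterExpressed(str),
               rownames(mr)[apply(mr, 1, mean) > 1])
})

test_that("spline amplitudes behave like the diel oscillation range", {
  times <- seq(1.5, 22.5, by = 3)
  expect_equal(dielAmplitude(times, rep(3, 8))$amplitude, 0)
  # noiseless cosine of amplitude A: fitted range in [1.8A, 2A]
  for (A in c(1, 2.5)) {
    y <- A * cos(2 * pi * times / 24) + 4
    amp <- dielAmplitude(times, y)$amplitude
    expect_gte(amp, 1.8 * A)
    expect_lte(amp, 2.0 * A)
    # translation invariance
    expect_equal(dielAmplitude(times, y + 7)$amplitude, amp,
                 tolerance = 1e-9)
  }
  # time-origin shift of a periodic input
  y1 <- cos(2 * pi * times / 24)
  y2 <- cos(2 * pi * (times + 6) / 24)
  expect_equal(dielAmplitude(times, y1)$amplitude,
               dielAmplitude(times, y2)$amplitude, tolerance = 0.02)
  expect_error(dielAmplitude(c(0, 3, 6), c(1, 2, 3)), "4 time points")
  expect_error(dielAmplitude(c(0, 3, 6, 9), c(1, 2, 3, 4)), "21 h")
})

test_that("the oscillation filter requires amplitude > 2 in both cultivars", {
  amp <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    cultivar = rep(c("A", "B"), 3),
    condition_id = "c1",
    amplitude = c(2.5, 2.5, 2.5, 1.9, 2.0, 3.0))
  expect_equal(filterOscillating(amp), "g1")
  expect_error(filterOscillating(amp[amp$cultivar == "A", ]), "both cultivars")
})

test_that("cultivar-specific genes satisfy both the gap and low-expression clauses", {
  cases <- rbind(
    c(3, 0.4, TRUE),     # A-specific
    c(3, 0.9, FALSE),    # lower mean not < 0.5
    c(2.3, 0.4, FALSE))  # difference not > 2
  k <- 8
  for (i in seq_len(nrow(cases))) {
    st <- make_two_cultivar_study(matrix(cases[i, 1], 1, k,
                                         dimnames = list("g1", NULL)),
                                  matrix(cases[i, 2], 1, k))
    got <- cultivarSpecificGenes(st)
    expect_equal("g1" %in% got$A, as.logical(cases[i, 3]), info = paste(i))
    expect_equal(length(got$B), 0L)
  }
})

test_that("paired-t differential expression matches t.test and controls FDR", {
  k <- 8
  withr::with_seed(52, {
    base <- matrix(rnorm(20 * k, 5), 20, k,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
    shift <- matrix(rnorm(20 * k, 5), 20, k)
    shift[1, ] <- base[1, ] + 4 + rnorm(k, 0, 0.1)   # one strong DEG
  })
  st <- make_two_cultivar_study(abs(base), abs(shift))
  res <- degPairedT(st, "c1")
  # p-values equal stats::t.test paired
  for (g in c("g01", "g05", "g13")) {
    a <- exprMatrix(st)[g, 1:k]; b <- exprMatrix(st)[g, (k + 1):(2 * k)]
    expect_equal(res$p[res$gene_id == g],
                 t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_true(res$deg[res$gene_id == "g01"])
  expect_equal(res$direction[res$gene_id == "g01"], "higher_B")
  # identical cultivar columns: no DEGs, zero-variance differences handled
  same <- make_two_cultivar_study(abs(base), abs(base))
  expect_equal(sum(degPairedT(same, "c1")$deg), 0)
})

test_that("BH adjustment matches an independent step-up implementation", {
  withr::with_seed(53, {
    for (k in 1:5) {
      p <- runif(200)^sample(1:3, 1)
      expect_equal(p.adjust(p, "BH"), bh_stepup(p))
    }
  })
  # null simulation: with no true cultivar effect every discovery is
  # false, so the FDR equals the probability of any rejection, which BH
  # keeps at most q; allow a Monte-Carlo margin on 20 replicates
  k <- 8
  any_fd <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      a <- matrix(rnorm(2000 * k, 5), 2000, k,
                  dimnames = list(sprintf("g%04d", 1:2000), NULL))
      b <- matrix(rnorm(2000 * k, 5), 2000, k)
    })
    res <- degPairedT(make_two_cultivar_study(abs(a), abs(b)), "c1")
    sum(res$deg) > 0
  }, logical(1))
  expect_lte(mean(any_fd), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("the temperature-correlation screen uses strict +/-0.5 cutoffs", {
  k <- 40
  withr::with_seed(54, temp <- runif(k, 15, 40))
  m <- rbind(up = 0.1 * temp + 1,                      # r = 1
             flat = rep(2, k),                          # zero variance
             noise = withr::with_seed(55, abs(rnorm(k, 3))))
  meta <- data.frame(sample_id = paste0("s", 1:k), cultivar = "A",
                     condition_id = "c", plate_id = "P1",
                     clock_time_h = rep(1:8, 5), age_days = 17)
  st <- ExpressionStudy(m, meta)
  expect_message(scr <- tempCorrelationScreen(st, temp), "zero-variance")
  expect_equal(unname(scr$r[["up"]]), 1)
  expect_true("up" %in% scr$positive)
  expect_equal(scr$excluded, "flat")
  expect_false("noise" %in% c(scr$positive, scr$negative))
  # boundary: r exactly at the threshold is excluded
  expect_equal(length(tempCorrelationScreen(st, temp, threshold = 1)$positive), 0)
})
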