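test_that("MAE matches a brute-force loop and rejects bad input", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(0, 0), c(1, 3)), 2)
  withr::with_seed(41, {
    p <- rnorm(50); o <- rnorm(50)
    acc <- 0
    for (i in 1:50) acc <- acc + abs(p[i] - o[i])
    expect_equal(mae(p, o), acc / 50)
  })
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:2), "differ")
})

test_that("poor predictions are flagged at an inclusive threshold of 5", {
  expect_true(classifyPoor(5))
  expect_false(classifyPoor(4.999))
  expect_false(classifyPoor(0))
  expect_equal(classifyPoor(c(0, 5, 7)), c(FALSE, TRUE, TRUE))
})

test_that("consistency classification uses an inclusive 80% rule", {
  expect_equal(consistencyClass(c(temperature = 80, radiation = 20, neither = 0)),
               "temperature")
  expect_equal(consistencyClass(c(temperature = 79, radiation = 21, neither = 0)),
               "inconsistent")
  expect_equal(consistencyClass(c(temperature = 0, radiation = 0, neither = 1)),
               "neither")
  # invariant to the order of the tally entries
  expect_equal(consistencyClass(c(neither = 0, radiation = 85, temperature = 15)),
               "radiation")
  expect_error(consistencyClass(c(temperature = 0, radiation = 0, neither = 0)),
               "replicate")
})

test_that("subsampling is without replacement, 50/50 for mixed pools, and seeded", {
  pool <- data.frame(sample_id = sprintf("s%03d", 1:100))
  idx <- subsamplePool(pool, 40, seed = 42)
  expect_equal(length(idx), 40)
  expect_equal(anyDuplicated(idx), 0L)
  expect_identical(idx, subsamplePool(pool, 40, seed = 42))
  expect_false(identical(idx, subsamplePool(pool, 40, seed = 43)))
  expect_error(subsamplePool(pool, 101, seed = 1), "exceeds")

  mixed <- data.frame(sample_id = sprintf("s%03d", 1:100),
                      source = rep(c("gc", "field"), each = 50))
  mi <- subsamplePool(mixed, 40, seed = 44)
  expect_equal(sum(mixed$source[mi] == "gc"), 20)
  expect_equal(sum(mixed$source[mi] == "field"), 20)
  mo <- subsamplePool(mixed, 41, seed = 44)     # odd n: ceiling to the first source
  expect_equal(sum(mixed$source[mo] == "gc"), 21)
})

test_that("genome-wide impact converts exemplar selections to member-gene percents", {
  # cluster sizes chosen so the arithmetic mirrors exemplar-based accounting
  sizes <- c(e1 = 120, e2 = 80, e3 = 300, e4 = 60)
  tab <- data.frame(
    exemplar_gene_id = rep(names(sizes), sizes),
    member_gene_id = sprintf("m%04d", seq_len(sum(sizes))))
  gi <- genomeWideImpact(c("e1", "e2"), tab)
  expect_equal(gi$count, 200)
  expect_equal(gi$percent, round(100 * 200 / 560, 1))
  expect_equal(genomeWideImpact(character(0), tab),
               list(count = 0, percent = 0))
  expect_equal(genomeWideImpact(names(sizes), tab),
               list(count = 560, percent = 100))
  expect_error(genomeWideImpact("e9", tab), "unknown exemplar")
})

test_that("MAE summaries match brute-force medians and counts", {
  withr::with_seed(45, {
    tab <- expand.grid(gene_id = c("g1", "g2", "g3"), pool = c("gc", "field"),
                       n = 64, rep = 1:7, stringsAsFactors = FALSE)
    tab$mae <- runif(nrow(tab), 0, 8)
  })
  pg <- summarizeMae(tab, "per_gene_median")
  for (i in seq_len(nrow(pg))) {
    sel <- tab$gene_id == pg$gene_id[i] & tab$pool == pg$pool[i]
    expect_equal(pg$median_mae[i], median(tab$mae[sel]))
  }
  pr <- summarizeMae(tab, "per_rep_median")
  for (i in seq_len(nrow(pr))) {
    sel <- tab$rep == pr$rep[i] & tab$pool == pr$pool[i]
    expect_equal(pr$median_mae[i], median(tab$mae[sel]))
  }
  pc <- summarizeMae(tab, "poor_counts")
  for (i in seq_len(nrow(pc))) {
    sel <- tab$rep == pc$rep[i] & tab$pool == pc$pool[i]
    expect_equal(pc$poor_count[i], sum(tab$mae[sel] >= 5))
  }
  # single gene, three reps
  one <- data.frame(gene_id = "g", pool = "gc", n = 64, rep = 1:3,
                    mae = c(1, 2, 3))
  expect_equal(summarizeMae(one, "per_gene_median")$median_mae, 2)
  all6 <- data.frame(gene_id = rep(c("a", "b"), 2), pool = "gc", n = 64,
                     rep = rep(1:2, each = 2), mae = 6)
  expect_equal(summarizeMae(all6, "poor_counts")$poor_count, c(2, 2))
  expect_error(summarizeMae(one[0, ], "per_gene_median"), "empty")
})

test_that("a tiny selection experiment tallies choices and excludes failures", {
  ds <- makeDiscriminationStudy(n_genes = 4, seed = 46, n_field_train = 120,
                                n_field_test = 40, field_days = 10)
  res <- runSelectionExperiment(
    list(gc = ds$gc_study, field = ds$field_study), ds$envs, ds$test_study,
    pools = "gc", sizes = 64, reps = 1, seed = 47, nm_maxit = 10)
  s <- res$summary
  expect_equal(nrow(s), 4)
  expect_true(all(s$n_temperature + s$n_radiation + s$n_neither == 1))
  expect_true(all(res$mae$mae >= 0, na.rm = TRUE))
})
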