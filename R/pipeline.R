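#' Default pipeline configuration
#'
#' All thresholds of the analysis appear here with their standard values:
#' the 72-h meteorological look-back, the poor-prediction MAE cutoff (5),
#' the consistency fraction (0.8), the oscillation amplitude cutoff (2),
#' the mean-expression cutoff (1), the correlation screen cutoff (0.5) and
#' the cultivar-specificity rule (difference > 2, lower mean < 0.5).
#' Module blocks size the synthetic study and the selection experiment.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @return A nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    thresholds = list(lookback_h = 72, poor_mae = 5, consistency = 0.8,
                      amplitude = 2, mean_expression = 1, correlation = 0.5,
                      cultivar_diff = 2, cultivar_low = 0.5),
    simulate = list(n_genes = 12, drivers = c("temperature", "radiation",
                                              "neither"),
                    snr = 5, field_days = 30, gc_days = 5, dt = 0.5),
    experiment = list(pools = c("gc", "field", "mixed"), sizes = c(64),
                      reps = 3, n_test = 60),
    qc = list(n_loci = 200, error_rate = 0.02, dropout_rate = 0.3))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in order - synthetic data generation, QC (genotype
#' concordance), diel statistics (amplitudes, expression filter) and the
#' training-set-composition experiment - and writes every table, a JSON
#' manifest (seed, parameters, stage outputs) and a JSON-lines log to the
#' output directory. Rerunning with the same configuration reproduces the
#' outputs.
#'
#' @param config configuration list ([defaultRunConfig()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir = tempfile("run")) {
  stopifnot(is.numeric(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log_stage <- function(stage, ...) {
    writeLines(jsonlite::toJSON(c(list(stage = stage, seed = config$seed),
                                  list(...)), auto_unbox = TRUE), log_con)
  }

  # --- synthetic data ------------------------------------------------------
  conds <- enumerateConditions()
  writeConditionTable(conds, file.path(out_dir, "conditions.csv"))
  sim <- config$simulate
  envs <- lapply(seq_len(nrow(conds)), function(i)
    gcEnvSeries(conds[i, ], days = sim$gc_days, dt = sim$dt))
  names(envs) <- conds$condition_id
  envs$field <- fieldEnvSeries(days = sim$field_days, dt = sim$dt,
                               seed = config$seed)
  plan <- makeStudySamples(conds)
  truth <- makeTruthSet(sim$n_genes, sim$drivers, seed = config$seed)
  truth <- calibrateNoise(truth, envs, plan, snr = sim$snr)
  gc_study <- simulateExpression(truth, envs, plan, seed = config$seed + 1)
  field_samples <- fieldSamplePlan(sim$field_days, n = 240,
                                   seed = config$seed + 2)
  field_study <- simulateExpression(truth, envs$field, field_samples,
                                    seed = config$seed + 3)
  n_test <- config$experiment$n_test
  test_idx <- seq_len(n_test)
  test_study <- field_study[, test_idx]
  train_field <- field_study[, -test_idx]
  writeExpressionStudy(gc_study, file.path(out_dir, "gc_matrix.tsv"),
                       file.path(out_dir, "gc_meta.tsv"))
  writeExpressionStudy(field_study, file.path(out_dir, "field_matrix.tsv"),
                       file.path(out_dir, "field_meta.tsv"))
  log_stage("synthdata", n_conditions = nrow(conds),
            n_gc_samples = ncol(gc_study),
            n_field_samples = ncol(field_study))

  # --- qc ------------------------------------------------------------------
  qc_cfg <- config$qc
  cultivars <- sampleMeta(gc_study)$cultivar[seq_len(20)]
  snp <- makeSnpFixture(qc_cfg$n_loci, 20, cultivars,
                        error_rate = qc_cfg$error_rate,
                        dropout_rate = qc_cfg$dropout_rate,
                        seed = config$seed + 4)
  nominal <- setNames(cultivars, unique(snp$sample_id))
  geno <- genotypeConcordance(snp, nominal)
  writeGenotypeCalls(snp, file.path(out_dir, "genotype_calls.tsv"))
  jsonlite::write_json(geno, file.path(out_dir, "genotype_report.json"),
                       dataframe = "rows")
  log_stage("qc", n_pass = sum(geno$verdict == "pass"))

  # --- dielstats -----------------------------------------------------------
  expressed <- filterExpressed(gc_study, config$thresholds$mean_expression)
  amp_conds <- conds$condition_id[seq_len(3)]
  amp_study <- gc_study[, sampleMeta(gc_study)$condition_id %in% amp_conds]
  amp <- amplitudeTable(amp_study)
  write.table(amp, file.path(out_dir, "amplitudes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("dielstats", n_expressed = length(expressed))

  # --- experiment ----------------------------------------------------------
  ex <- config$experiment
  res <- runSelectionExperiment(
    list(gc = gc_study, field = train_field), envs, test_study,
    pools = ex$pools, sizes = ex$sizes, reps = ex$reps,
    seed = config$seed + 5)
  write.table(res$summary, file.path(out_dir, "selection_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(res$mae, file.path(out_dir, "selection_mae.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("experiment", n_rows = nrow(res$summary),
            n_excluded = length(res$excluded))

  manifest <- list(seed = config$seed, config = config,
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = out_dir, conditions = conds, truth = truth,
                 gc_study = gc_study, field_study = field_study,
                 genotype = geno, amplitudes = amp, experiment = res))
}

#' Random field sampling plan
#'
#' Draws sampling times (clock times of day across a span of field days,
#' past the 72-h look-back) and plant ages for synthetic field samples.
#'
#' @param days span of the field environmental trace (days).
#' @param n number of samples.
#' @param seed integer seed.
#' @param age_range plant age range (days) sampled uniformly.
#' @return A sample table suitable for [simulateExpression()], with
#'   `condition_id` set to `"field"`.
#' @export
fieldSamplePlan <- function(days, n, seed = 1, age_range = c(20, 110)) {
  withRNG(seed, {
    day <- sample(3:(days - 1), n, replace = TRUE)
    clock <- runif(n, 0, 24)
    time_h <- day * 24 + clock
    age <- runif(n, age_range[1], age_range[2])
  })
  data.frame(sample_id = sprintf("F%04d", seq_len(n)),
             cultivar = "A", condition_id = "field",
             plate_id = paste0("FP", (seq_len(n) - 1) %/% 96 + 1),
             clock_time_h = time_h %% 24, age_days = age, time_h = time_h)
}
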