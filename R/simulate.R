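#' Construct a ground-truth gene
#'
#' @param gene_id gene identifier.
#' @param driver `"temperature"`, `"radiation"` or `"neither"`; a
#'   `"neither"` gene must have zero environmental coefficients.
#' @param nl nonlinear parameters ([nlParams()]).
#' @param coefs named linear coefficients (length 8, see [designRow()]).
#' @param noise_sd log2-scale Gaussian noise standard deviation.
#' @return A [TruthGene-class].
#' @export
truthGene <- function(gene_id, driver, nl, coefs, noise_sd = 0) {
  new("TruthGene", gene_id = gene_id, driver = driver, nl = nl[NL_NAMES],
      coefs = coefs[COEF_NAMES], noise_sd = noise_sd)
}

setMethod("show", "TruthGene", function(object) {
  cat("TruthGene", object@gene_id, "- driver:", object@driver,
      sprintf("(noise_sd %.3g)\n", object@noise_sd))
})

#' Random set of ground-truth genes
#'
#' Draws diel genes with known drivers for recovery and discrimination
#' experiments. Every gene carries an intercept, a clock component with
#' random phase, and (for environment-driven genes) a gated environmental
#' response whose coefficient scale is matched to the dynamic range of the
#' driving variable so temperature- and radiation-driven genes have
#' comparable signal on the log2 scale. `age_effect` adds a linear age
#' trend, which matters when training data cover a narrower age range than
#' the prediction target.
#'
#' @param n_genes number of genes.
#' @param drivers vector recycled to `n_genes` with values
#'   `"temperature"`, `"radiation"`, `"neither"`.
#' @param seed integer seed.
#' @param noise_sd initial log2-scale noise SD per gene (see
#'   [calibrateNoise()] to set it from a target signal-to-noise ratio).
#' @param age_effect if TRUE, genes get a small linear age coefficient.
#' @param on_grid if TRUE, window/lag/peak are drawn from the default
#'   grid values (convenient for parameter-recovery checks); otherwise
#'   they are drawn continuously.
#' @return A list of [TruthGene-class] objects.
#' @export
makeTruthSet <- function(n_genes, drivers = c("temperature", "radiation"),
                         seed = 1, noise_sd = 0.3, age_effect = TRUE,
                         on_grid = TRUE) {
  drivers <- rep_len(drivers, n_genes)
  withRNG(seed, {
    lapply(seq_len(n_genes), function(i) {
      driver <- drivers[i]
      window <- if (on_grid) sample(c(3, 6, 12, 24), 1) else exp(runif(1, log(2), log(36)))
      lag <- if (on_grid) sample(c(0, 3), 1) else runif(1, 0, 6)
      peak <- if (on_grid) sample(seq(0, 21, by = 3), 1) else runif(1, 0, 24)
      depth <- sample(c(0.8, 1), 1)
      sharp <- sample(c(1, 4), 1)
      if (driver == "temperature") {
        clip <- c(-50, 60); b_env <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.35)
      } else {
        clip <- c(-10, 10); b_env <- sample(c(-1, 1), 1) * runif(1, 2, 4)
      }
      if (driver == "neither") b_env <- 0
      clock_amp <- runif(1, 0.8, 2)
      clock_phase <- runif(1, 0, 2 * pi)
      coefs <- c(intercept = runif(1, 4, 8),
                 age = if (age_effect) sample(c(-1, 1), 1) * runif(1, 0.01, 0.03) else 0,
                 clock_cos = clock_amp * cos(clock_phase),
                 clock_sin = clock_amp * sin(clock_phase),
                 env = b_env,
                 env_age = 0,
                 env_cos = if (driver == "neither") 0 else b_env * runif(1, -0.15, 0.15),
                 env_sin = if (driver == "neither") 0 else b_env * runif(1, -0.15, 0.15))
      truthGene(sprintf("g%03d", i), driver,
                nlParams(window, lag, peak, depth, sharp, clip[1], clip[2]),
                coefs, noise_sd)
    })
  })
}

truth_to_fit <- function(truth) {
  new("GeneModelFit", gene_id = truth@gene_id, predictor = truth@driver,
      nl = truth@nl, coefs = truth@coefs, criterion = NA_real_,
      n_train = 0L)
}

truth_signal <- function(truth, envs, samples) {
  predict(truth_to_fit(truth), envs, samples)
}

#' Set per-gene noise from a target signal-to-noise ratio
#'
#' Replaces each truth gene's `noise_sd` by `sd(signal)/sqrt(snr)`, where
#' the signal is the noiseless model prediction over a reference sample set
#' (SNR is defined as the ratio of signal to noise variances).
#'
#' @param truth list of [TruthGene-class].
#' @param envs,samples reference environment and samples over which the
#'   signal SD is measured.
#' @param snr target signal-to-noise ratio (>= 0); `Inf` gives noiseless
#'   genes.
#' @return The updated list of truth genes.
#' @export
calibrateNoise <- function(truth, envs, samples, snr = 5) {
  lapply(truth, function(tg) {
    s <- sd(truth_signal(tg, envs, samples))
    tg@noise_sd <- if (is.finite(snr) && snr > 0) s / sqrt(snr) else 0
    tg
  })
}

#' Simulate an expression study from ground-truth genes
#'
#' Forward model: each gene's column values are the noiseless model
#' prediction of its [TruthGene-class] plus Gaussian log2-scale noise,
#' clipped at 0 to stay in the observable log2(rpm+1) range.
#'
#' @param truth list of [TruthGene-class].
#' @param envs environmental traces (single [EnvSeries-class] or named list
#'   keyed by `condition_id`); must cover 72 h before every sample.
#' @param samples sample table (as from [makeStudySamples()]); missing
#'   `cultivar` or `plate_id` columns are filled with defaults.
#' @param seed integer seed for the noise draws.
#' @return An [ExpressionStudy-class]. The truth list and the generator
#'   seed are stored in its metadata under `truth` and `seed`.
#' @export
simulateExpression <- function(truth, envs, samples, seed = 1) {
  samples <- as.data.frame(samples)
  if (is.null(samples$sample_id))
    samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  if (is.null(samples$cultivar)) samples$cultivar <- "A"
  if (is.null(samples$condition_id)) samples$condition_id <- "env"
  if (is.null(samples$plate_id)) samples$plate_id <- "P1"
  if (is.null(samples$clock_time_h)) samples$clock_time_h <- samples$time_h %% 24
  if (is.null(samples$age_days)) samples$age_days <- 17
  envs <- as_env_list(envs, samples)
  mu <- vapply(truth, truth_signal, numeric(nrow(samples)),
               envs = envs, samples = samples)
  withRNG(seed, {
    noise <- vapply(truth, function(tg) rnorm(nrow(samples), 0, tg@noise_sd),
                    numeric(nrow(samples)))
  })
  m <- t(pmax(mu + noise, 0))
  rownames(m) <- vapply(truth, function(tg) tg@gene_id, character(1))
  colnames(m) <- samples$sample_id
  study <- ExpressionStudy(m, samples)
  S4Vectors::metadata(study)$truth <- truth
  S4Vectors::metadata(study)$seed <- seed
  study
}

#' Exchange the metadata annotations of two plates
#'
#' Emulates a plate-level sample swap during library processing: the
#' per-sample metadata (including plate, condition and time annotations) of
#' the two plates are exchanged sample-by-sample (matched by within-plate
#' order) while the expression matrix columns stay where they are, so the
#' annotations now lie about the data. Applying the same swap twice
#' restores the original study. The ground-truth swap is appended to the
#' study metadata under `swap_log`.
#'
#' @param study an [ExpressionStudy-class].
#' @param plate_a,plate_b plate identifiers; must exist and hold equally
#'   many samples.
#' @return The modified `ExpressionStudy`.
#' @export
injectPlateSwap <- function(study, plate_a, plate_b) {
  cd <- SummarizedExperiment::colData(study)
  ia <- which(cd$plate_id == plate_a)
  ib <- which(cd$plate_id == plate_b)
  if (!length(ia)) stop("unknown plate: ", plate_a)
  if (!length(ib)) stop("unknown plate: ", plate_b)
  if (length(ia) != length(ib))
    stop("plates have different sample counts (", length(ia), " vs ",
         length(ib), ")")
  if (identical(plate_a, plate_b)) return(study)
  new_cd <- cd
  new_cd[ia, ] <- cd[ib, ]
  new_cd[ib, ] <- cd[ia, ]
  rownames(new_cd) <- new_cd$sample_id
  SummarizedExperiment::colData(study) <- new_cd
  colnames(study) <- new_cd$sample_id
  S4Vectors::metadata(study)$swap_log <-
    c(S4Vectors::metadata(study)$swap_log, list(c(plate_a, plate_b)))
  study
}

#' Synthetic cultivar-specific SNP call table
#'
#' Per sample and locus, emits the sample's true allele with probability
#' `1 - error_rate - dropout_rate`, an erroneous call (the other cultivar's
#' allele or `"unknown"`, equally likely) with probability `error_rate`,
#' and `"none"` (no sequence) with probability `dropout_rate`. A true
#' cultivar of `"mix"` draws either allele with probability 1/2, emulating
#' a sample whose sequenced loci match neither cultivar consistently.
#'
#' @param n_loci,n_samples table dimensions.
#' @param true_cultivars character vector (length `n_samples`) of `"A"`,
#'   `"B"` or `"mix"`.
#' @param error_rate,dropout_rate per-call probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return A data.frame with columns `sample_id`, `locus_id`, `call`
#'   (`"A"`, `"B"`, `"unknown"`, `"none"`).
#' @export
makeSnpFixture <- function(n_loci, n_samples, true_cultivars,
                           error_rate = 0.02, dropout_rate = 0.3, seed = 1) {
  stopifnot(error_rate >= 0, dropout_rate >= 0,
            error_rate + dropout_rate <= 1)
  true_cultivars <- rep_len(true_cultivars, n_samples)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  locus_ids <- sprintf("L%05d", seq_len(n_loci))
  withRNG(seed, {
    calls <- lapply(seq_len(n_samples), function(i) {
      tc <- true_cultivars[i]
      true_allele <- if (tc == "mix")
        sample(c("A", "B"), n_loci, replace = TRUE) else rep(tc, n_loci)
      other <- ifelse(true_allele == "A", "B", "A")
      u <- runif(n_loci)
      call <- true_allele
      err <- u < error_rate
      call[err] <- ifelse(runif(sum(err)) < 0.5, other[err], "unknown")
      call[u >= error_rate & u < error_rate + dropout_rate] <- "none"
      data.frame(sample_id = sample_ids[i], locus_id = locus_ids,
                 call = call)
    })
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Assemble the predictor-discrimination study
#'
#' Builds the complete synthetic setting of the training-set-composition
#' experiment: the 73-condition chamber grid with its square-wave traces, a
#' field trace for training and an independent field trace (different
#' weather realization) for held-out testing, ground-truth genes split
#' between temperature- and radiation-driven (noise calibrated to a target
#' SNR over the pooled samples), and the three expression studies.
#'
#' @param n_genes number of truth genes (drivers alternate temperature /
#'   radiation).
#' @param seed master seed.
#' @param snr signal-to-noise variance ratio for [calibrateNoise()].
#' @param n_field_train,n_field_test field sample counts.
#' @param field_days,gc_days trace lengths in days.
#' @return A list: `envs`, `truth`, `drivers` (named by gene),
#'   `gc_study`, `field_study` (training pool), `test_study`.
#' @export
makeDiscriminationStudy <- function(n_genes = 30, seed = 1, snr = 5,
                                    n_field_train = 500, n_field_test = 200,
                                    field_days = 40, gc_days = 5) {
  conds <- enumerateConditions()
  envs <- lapply(seq_len(nrow(conds)), function(i)
    gcEnvSeries(conds[i, ], days = gc_days))
  names(envs) <- conds$condition_id
  envs$field <- fieldEnvSeries(days = field_days, seed = seed + 11)
  envs$field_test <- fieldEnvSeries(days = field_days, seed = seed + 12)
  plan <- makeStudySamples(conds)
  plan <- plan[plan$cultivar == "A", ]
  truth <- makeTruthSet(n_genes, c("temperature", "radiation"),
                        seed = seed + 13)
  f_train <- fieldSamplePlan(field_days, n_field_train, seed = seed + 14)
  f_test <- fieldSamplePlan(field_days, n_field_test, seed = seed + 15)
  f_test$condition_id <- "field_test"
  f_test$sample_id <- sub("^F", "T", f_test$sample_id)
  calib <- rbind(plan[, c("sample_id", "condition_id", "clock_time_h",
                          "age_days", "time_h")],
                 f_train[, c("sample_id", "condition_id", "clock_time_h",
                             "age_days", "time_h")])
  truth <- calibrateNoise(truth, envs, calib, snr = snr)
  drivers <- vapply(truth, function(tg) tg@driver, character(1))
  names(drivers) <- vapply(truth, function(tg) tg@gene_id, character(1))
  list(envs = envs,
       truth = truth,
       drivers = drivers,
       gc_study = simulateExpression(truth, envs, plan, seed = seed + 16),
       field_study = simulateExpression(truth, envs, f_train, seed = seed + 17),
       test_study = simulateExpression(truth, envs, f_test, seed = seed + 18))
}

#' Selection accuracy against ground truth
#'
#' Fraction of genes whose majority predictor choice over the subsampling
#' replicates equals the gene's true driver.
#'
#' @param summary the `summary` table of [runSelectionExperiment()].
#' @param drivers named character vector of true drivers per gene.
#' @param pool pool name to evaluate.
#' @return Accuracy in `[0, 1]`.
#' @export
selectionAccuracy <- function(summary, drivers, pool) {
  s <- summary[summary$pool == pool, ]
  tal <- cbind(temperature = s$n_temperature, radiation = s$n_radiation,
               neither = s$n_neither)
  chosen <- colnames(tal)[max.col(tal, ties.method = "first")]
  mean(chosen == drivers[s$gene_id])
}

#' Synthetic plate-swap QC fixture
#'
#' Builds a small chamber study whose genes respond strongly to
#' temperature (so the transcriptome encodes growth temperature, the
#' signal that plate-level swap detection exploits), one plate per
#' condition, annotates the nominal sampling temperature, and then
#' exchanges the annotations of the requested plate pairs. The true swaps
#' are in the study metadata under `swap_log`.
#'
#' @param n_plates number of plates (>= 3); each plate holds
#'   `conditions_per_plate` chamber conditions, as 96-well plates hold
#'   several conditions' worth of samples, so the temperatures of a
#'   held-out plate stay inside the training range.
#' @param conditions_per_plate chamber conditions per plate.
#' @param n_genes number of genes (half temperature-driven, half clock).
#' @param swaps list of plate-id pairs to swap (possibly empty).
#' @param seed integer seed.
#' @param snr signal-to-noise variance ratio.
#' @return A list: `study` (with `nominal_temp_C` metadata column),
#'   `envs`, `truth`.
#' @export
makeSwapFixture <- function(n_plates = 8, conditions_per_plate = 2,
                            n_genes = 40, swaps = list(), seed = 1,
                            snr = 10) {
  n_conditions <- n_plates * conditions_per_plate
  conds <- enumerateConditions()
  conds <- conds[conds$light_hours %in% c(8, 12, 16), ]
  # evenly spaced picks along the time-weighted mean temperature
  mean_temp <- (conds$light_hours * conds$light_temp +
                  (24 - conds$light_hours) * conds$dark_temp) / 24
  conds <- conds[order(mean_temp), ]
  conds <- conds[round(seq(1, nrow(conds), length.out = n_conditions)), ]
  envs <- lapply(seq_len(nrow(conds)), function(i) gcEnvSeries(conds[i, ]))
  names(envs) <- conds$condition_id
  plan <- makeStudySamples(conds)
  # Stratified plate assignment: conditions are dealt into strata of
  # consecutive mean temperature and each plate receives one condition per
  # stratum, so a held-out plate's temperatures are always spanned by the
  # training plates. Within strata the assignment is a seeded permutation,
  # redrawn until every requested swap pair has clearly different
  # light/dark temperature profiles (otherwise a swap would be
  # undetectable by construction).
  strata <- matrix(seq_len(n_conditions), nrow = n_plates)
  pair_dist <- function(assign, a, b) {
    ca <- match(paste0("P", a), assign)        # per stratum
    sum(vapply(seq_len(conditions_per_plate), function(k) {
      i <- strata[which(assign[strata[, k]] == paste0("P", a)), k]
      j <- strata[which(assign[strata[, k]] == paste0("P", b)), k]
      abs(conds$light_temp[i] - conds$light_temp[j]) +
        abs(conds$dark_temp[i] - conds$dark_temp[j])
    }, numeric(1)))
  }
  assign <- withRNG(seed + 91, {
    for (try in 1:100) {
      a <- character(n_conditions)
      for (k in seq_len(conditions_per_plate))
        a[strata[, k]] <- paste0("P", sample(n_plates))
      ok <- all(vapply(swaps, function(p)
        pair_dist(a, sub("^P", "", p[1]), sub("^P", "", p[2])) >= 10,
        logical(1)))
      if (ok || !length(swaps)) break
    }
    a
  })
  plate_of <- setNames(assign, conds$condition_id)
  plan$plate_id <- unname(plate_of[plan$condition_id])
  # temperature reporters with short, ungated windows: their expression
  # tracks the chamber temperature at sampling, which is the signal the
  # swap detector relies on; the rest are clock-only genes
  truth <- withRNG(seed, lapply(seq_len(n_genes), function(i) {
    base <- c(intercept = runif(1, 4, 8), age = 0,
              clock_cos = runif(1, -1, 1), clock_sin = runif(1, -1, 1),
              env = 0, env_age = 0, env_cos = 0, env_sin = 0)
    if (i %% 2 == 1) {
      base["env"] <- sample(c(-1, 1), 1) * runif(1, 0.1, 0.3)
      truthGene(sprintf("q%03d", i), "temperature",
                nlParams(sample(c(1, 2), 1), 0, 0, 0, 1, -50, 60), base)
    } else {
      truthGene(sprintf("q%03d", i), "neither",
                nlParams(3, 0, 0, 0, 1, -50, 60), base)
    }
  }))
  truth <- calibrateNoise(truth, envs, plan, snr = snr)
  study <- simulateExpression(truth, envs, plan, seed = seed + 1)
  meta <- sampleMeta(study)
  ci <- match(meta$condition_id, conds$condition_id)
  light <- meta$clock_time_h < conds$light_hours[ci]
  nominal <- ifelse(light, conds$light_temp[ci], conds$dark_temp[ci])
  SummarizedExperiment::colData(study)$nominal_temp_C <- nominal
  for (p in swaps) study <- injectPlateSwap(study, p[1], p[2])
  list(study = study, envs = envs, truth = truth)
}
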