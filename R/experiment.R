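#' Mean absolute error
#'
#' @param pred,obs equal-length numeric vectors on the log2(rpm+1) scale.
#' @return Mean of `|pred - obs|`.
#' @export
mae <- function(pred, obs) {
  if (!length(pred) || !length(obs)) stop("empty vectors")
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  mean(abs(pred - obs))
}

#' Flag poor predictions
#'
#' A gene model is considered a poor predictor when its held-out MAE is at
#' least `threshold` (inclusive) on the log2(rpm+1) scale.
#'
#' @param mae_value non-negative MAE value(s).
#' @param threshold poor-prediction cutoff (default 5).
#' @return Logical vector.
#' @export
classifyPoor <- function(mae_value, threshold = 5) {
  mae_value >= threshold
}

#' Consistency classification of predictor choices
#'
#' A gene is consistently classified when one choice accounts for at least
#' `threshold` of the subsampling replicates (inclusive); otherwise it is
#' `"inconsistent"`.
#'
#' @param tally named counts of choices over replicates, with names among
#'   `temperature`, `radiation`, `neither`.
#' @param threshold consistency fraction (default 0.8).
#' @return One of `"temperature"`, `"radiation"`, `"neither"`,
#'   `"inconsistent"`.
#' @export
consistencyClass <- function(tally, threshold = 0.8) {
  reps <- sum(tally)
  if (reps <= 0) stop("tally must cover at least one replicate")
  hit <- names(tally)[tally >= threshold * reps]
  if (length(hit)) hit[1] else "inconsistent"
}

#' Subsample a training pool without replacement
#'
#' For a single-source pool, draws `n` distinct samples. For a mixed pool
#' (rows labelled by a `source` column with two levels), draws half of the
#' subsample from each source (`ceiling(n/2)` from the first level when `n`
#' is odd).
#'
#' @param samples pool sample table; a `source` column with two levels
#'   marks a mixed pool.
#' @param n subsample size.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return Integer row indices into `samples`.
#' @export
subsamplePool <- function(samples, n, seed) {
  src <- if (!is.null(samples$source)) as.character(samples$source)
         else rep("pool", nrow(samples))
  levels <- unique(src)
  withRNG(seed, {
    if (length(levels) <= 1) {
      if (n > nrow(samples))
        stop("subsample size ", n, " exceeds pool size ", nrow(samples))
      idx <- sample(nrow(samples), n)
    } else {
      take <- c(ceiling(n / 2), floor(n / 2))
      idx <- unlist(lapply(seq_along(levels[1:2]), function(k) {
        rows <- which(src == levels[k])
        if (take[k] > length(rows))
          stop("subsample size ", take[k], " exceeds ", levels[k],
               " source size ", length(rows))
        rows[sample(length(rows), take[k])]
      }))
    }
    sort(idx)
  })
}

#' Training-set-composition experiment: per-gene predictor choice and MAE
#'
#' For every combination of gene, training pool (growth chamber, field, or
#' a 50/50 mixture), subsample size and replicate: draws a subsample
#' without replacement, fits the gene model once with temperature and once
#' with irradiance as the candidate predictor, records which was chosen by
#' the selection criterion (or `"neither"` when the winning fit drops the
#' environmental group), and evaluates the chosen model's MAE on a held-out
#' test set. Genes whose fitting fails in any replicate are flagged
#' excluded. The subsample of a given (pool, size, replicate) is shared by
#' all genes, mirroring a design where one data subsample trains every
#' gene's model.
#'
#' @param studies named list with elements `gc` and `field`, each an
#'   [ExpressionStudy-class] whose metadata includes `time_h`.
#' @param envs named list of [EnvSeries-class] traces covering every
#'   `condition_id` in the studies and the test set.
#' @param test_study held-out [ExpressionStudy-class] (disjoint from the
#'   pools) on which MAE is computed.
#' @param genes gene ids to fit (default: all genes of the `gc` study).
#' @param pools subset of `c("gc", "field", "mixed")`.
#' @param sizes subsample sizes.
#' @param reps replicates per size.
#' @param seed integer master seed; replicate subsamples derive from it.
#' @param paired if TRUE, the same replicate seeds (hence comparable
#'   subsample draws) are reused across pools.
#' @param nm_maxit,nlambda,pilot_ridge tuning knobs passed to the fitter.
#' @return A list with `summary` (one row per gene x pool x size: choice
#'   tallies, median MAE, exclusion flag) and `mae` (long table with one
#'   row per gene x pool x size x replicate: the choice and held-out MAE).
#' @export
runSelectionExperiment <- function(studies, envs, test_study,
                                   genes = NULL,
                                   pools = c("gc", "field", "mixed"),
                                   sizes = c(64, 256), reps = 20,
                                   seed = 1, paired = FALSE,
                                   nm_maxit = 50, nlambda = 25,
                                   pilot_ridge = 1e-2) {
  pools <- match.arg(pools, several.ok = TRUE)
  if (is.null(genes)) genes <- rownames(studies$gc)
  test_meta <- sampleMeta(test_study)
  test_mat <- exprMatrix(test_study)

  fit_cols <- c("sample_id", "condition_id", "clock_time_h", "age_days",
                "time_h")
  pool_tables <- list()
  if (any(c("gc", "mixed") %in% pools))
    pool_tables$gc <- cbind(sampleMeta(studies$gc)[, fit_cols], source = "gc")
  if (any(c("field", "mixed") %in% pools))
    pool_tables$field <- cbind(sampleMeta(studies$field)[, fit_cols],
                               source = "field")
  pool_samples <- function(pool) {
    switch(pool,
           gc = pool_tables$gc,
           field = pool_tables$field,
           mixed = rbind(pool_tables$gc, pool_tables$field))
  }
  pool_matrix <- function(pool) {
    switch(pool,
           gc = exprMatrix(studies$gc)[genes, , drop = FALSE],
           field = exprMatrix(studies$field)[genes, , drop = FALSE],
           mixed = cbind(exprMatrix(studies$gc)[genes, , drop = FALSE],
                         exprMatrix(studies$field)[genes, , drop = FALSE]))
  }

  variables <- c("temperature", "radiation")
  summary_rows <- list()
  mae_rows <- list()
  excluded <- character(0)

  traces <- lapply(setNames(variables, variables), function(v)
    envPackTraces(envs, v))
  test_age <- test_meta$age_days
  test_cc <- cos(2 * pi * test_meta$clock_time_h / 24)
  test_ss <- sin(2 * pi * test_meta$clock_time_h / 24)
  test_pack <- lapply(traces, function(tr) envPack(test_meta, envs,
                                                   traces = tr))
  predict_fast <- function(fit) {
    x <- if (fitPredictor(fit) == "neither") rep(0, nrow(test_meta)) else {
      p <- test_pack[[fitPredictor(fit)]]
      as.numeric(cpp_env_input_pack(p$t0s, p$dt, p$vals, p$clocks, p$offsets,
                                    p$trace_idx, p$times,
                                    unname(fitNlParams(fit)[NL_NAMES])))
    }
    if (anyNA(x)) return(NULL)
    b <- fitCoefs(fit)
    b[["intercept"]] + b[["age"]] * test_age + b[["clock_cos"]] * test_cc +
      b[["clock_sin"]] * test_ss +
      x * (b[["env"]] + b[["env_age"]] * test_age +
             b[["env_cos"]] * test_cc + b[["env_sin"]] * test_ss)
  }

  for (pool in pools) {
    ps <- pool_samples(pool)
    pm <- pool_matrix(pool)
    grids <- xg <- list()
    for (v in variables) {
      ev <- unlist(lapply(unique(as.character(ps$condition_id)),
                          function(k) envVariable(envs[[k]], v)))
      grids[[v]] <- defaultNonlinearGrid(ev)
      xg[[v]] <- envInputMatrix(ps, envs, grids[[v]], v)
    }
    for (n in sizes) {
      choices <- array(NA_character_, c(length(genes), reps),
                       dimnames = list(genes, NULL))
      maes <- array(NA_real_, c(length(genes), reps),
                    dimnames = list(genes, NULL))
      for (r in seq_len(reps)) {
        rep_seed <- if (paired) seed * 1000L + r
                    else seed * 1000L + r + 7919L * match(pool, c("gc", "field", "mixed"))
        idx <- subsamplePool(ps, n, rep_seed)
        sub <- ps[idx, , drop = FALSE]
        age <- sub$age_days
        cc <- cos(2 * pi * sub$clock_time_h / 24)
        ss <- sin(2 * pi * sub$clock_time_h / 24)
        Y <- t(pm[, idx, drop = FALSE])
        crit_mat <- lapply(variables, function(v)
          cpp_grid_search_multi(xg[[v]][idx, , drop = FALSE], age, cc, ss,
                                Y, numeric(0), pilot_ridge, nlambda))
        names(crit_mat) <- variables
        packs <- lapply(traces, function(tr) envPack(sub, envs, traces = tr))
        for (gi in seq_along(genes)) {
          g <- genes[gi]
          fit <- tryCatch(
            fitGeneModel(Y[, gi], sub, envs, gene_id = g,
                         grids = grids, packs = packs,
                         grid_criteria = lapply(crit_mat, function(m)
                           as.numeric(m[, gi])),
                         nm_maxit = nm_maxit, nlambda = nlambda,
                         pilot_ridge = pilot_ridge),
            error = function(e) NULL)
          if (is.null(fit)) { excluded <- union(excluded, g); next }
          choices[gi, r] <- fitPredictor(fit)
          pr <- predict_fast(fit)
          if (is.null(pr)) { excluded <- union(excluded, g); next }
          maes[gi, r] <- mae(pr, test_mat[g, ])
        }
      }
      for (gi in seq_along(genes)) {
        g <- genes[gi]
        tal <- c(temperature = sum(choices[gi, ] == "temperature", na.rm = TRUE),
                 radiation = sum(choices[gi, ] == "radiation", na.rm = TRUE),
                 neither = sum(choices[gi, ] == "neither", na.rm = TRUE))
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          gene_id = g, pool = pool, n = n, rep_count = reps,
          n_temperature = tal[["temperature"]],
          n_radiation = tal[["radiation"]],
          n_neither = tal[["neither"]],
          median_mae = median(maes[gi, ], na.rm = TRUE),
          excluded = g %in% excluded)
        mae_rows[[length(mae_rows) + 1]] <- data.frame(
          gene_id = g, pool = pool, n = n, rep = seq_len(reps),
          choice = choices[gi, ], mae = maes[gi, ])
      }
    }
  }
  list(summary = do.call(rbind, summary_rows),
       mae = do.call(rbind, mae_rows),
       excluded = excluded)
}

#' Genome-wide impact of a selected exemplar set
#'
#' Exemplar (representative) genes stand for co-expression clusters of
#' different sizes; the genome-wide impact of a selection of exemplars is
#' the total number of member genes of their clusters, and that count as a
#' percentage of all member genes, reported to one decimal.
#'
#' @param selected_exemplars character vector of selected exemplar ids.
#' @param cluster_table data.frame with columns `exemplar_gene_id`,
#'   `member_gene_id`.
#' @return A list with `count` and `percent`.
#' @export
genomeWideImpact <- function(selected_exemplars, cluster_table) {
  unknown <- setdiff(selected_exemplars, cluster_table$exemplar_gene_id)
  if (length(unknown))
    stop("unknown exemplar(s): ", paste(head(unknown, 5), collapse = ", "))
  total <- nrow(cluster_table)
  count <- sum(cluster_table$exemplar_gene_id %in% selected_exemplars)
  list(count = count,
       percent = round(100 * count / total, 1))
}

#' Summaries of held-out MAE tables
#'
#' @param mae_table long MAE table as returned in
#'   [runSelectionExperiment()]`$mae`.
#' @param axis `"per_gene_median"` (median over replicates for each gene),
#'   `"per_rep_median"` (median over genes for each replicate) or
#'   `"poor_counts"` (per replicate, the number of genes whose MAE in that
#'   replicate is at least the poor-prediction threshold).
#' @param poor_threshold poor-prediction cutoff used by `"poor_counts"`.
#' @return A data.frame keyed by pool and size.
#' @export
summarizeMae <- function(mae_table,
                         axis = c("per_gene_median", "per_rep_median",
                                  "poor_counts"),
                         poor_threshold = 5) {
  axis <- match.arg(axis)
  if (!nrow(mae_table)) stop("empty MAE table")
  if (axis == "per_gene_median") {
    out <- stats::aggregate(list(median_mae = mae_table$mae),
                            by = mae_table[, c("pool", "n", "gene_id")],
                            FUN = median, na.rm = TRUE)
  } else if (axis == "per_rep_median") {
    out <- stats::aggregate(list(median_mae = mae_table$mae),
                            by = mae_table[, c("pool", "n", "rep")],
                            FUN = median, na.rm = TRUE)
  } else {
    out <- stats::aggregate(
      list(poor_count = classifyPoor(mae_table$mae, poor_threshold)),
      by = mae_table[, c("pool", "n", "rep")],
      FUN = function(z) sum(z, na.rm = TRUE))
  }
  out
}
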