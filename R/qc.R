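#' Leave-one-plate-out temperature prediction from the transcriptome
#'
#' Because expression encodes growth temperature, regressing the nominal
#' sampling temperature on the transcriptome and predicting each 96-well
#' plate from a model trained on all other plates exposes plate-level
#' annotation swaps: a swapped plate's predictions disagree systematically
#' with its nominal labels. The regression is an L1-penalized (lasso)
#' Gaussian model; the penalty is chosen by 5-fold cross-validated MAE
#' within the training plates, with a deterministic, order-invariant fold
#' assignment (folds follow the sample-id sort order).
#'
#' @param study an [ExpressionStudy-class] with at least 3 plates.
#' @param temperatures optional per-sample nominal temperature (degC, in
#'   column order); defaults to the `nominal_temp_C` metadata column.
#' @return A list with `plates` (data.frame: `plate_id`, `mae`, `lambda`)
#'   and `predictions` (data.frame: `sample_id`, `plate_id`, `predicted`,
#'   `nominal`).
#' @export
looPlateTemperature <- function(study, temperatures = NULL) {
  meta <- sampleMeta(study)
  if (is.null(temperatures)) temperatures <- meta$nominal_temp_C
  if (is.null(temperatures) || length(temperatures) != ncol(study))
    stop("nominal temperature must be annotated for every sample")
  plates <- unique(meta$plate_id)
  if (length(plates) < 3) stop("at least 3 plates are required")
  X <- t(exprMatrix(study))
  preds <- numeric(ncol(study))
  plate_rows <- split(seq_len(ncol(study)), meta$plate_id)
  plate_df <- data.frame(plate_id = names(plate_rows), mae = NA_real_,
                         lambda = NA_real_)
  if (sd(temperatures) == 0) {
    # nothing to learn: constant predictor, zero error by construction
    preds[] <- temperatures[1]
    plate_df$mae <- 0; plate_df$lambda <- 0
  } else {
    for (k in seq_along(plate_rows)) {
      test <- plate_rows[[k]]
      train <- setdiff(seq_len(ncol(study)), test)
      if (!length(train)) stop("a plate contains all samples")
      ord <- order(meta$sample_id[train])
      foldid <- integer(length(train))
      foldid[ord] <- rep_len(1:5, length(train))
      cv <- glmnet::cv.glmnet(X[train, , drop = FALSE], temperatures[train],
                              alpha = 1, type.measure = "mae",
                              foldid = foldid)
      preds[test] <- as.numeric(predict(cv, X[test, , drop = FALSE],
                                        s = "lambda.min"))
      plate_df$lambda[k] <- cv$lambda.min
      plate_df$mae[k] <- mae(preds[test], temperatures[test])
    }
    if (any(is.na(plate_df$mae)))
      plate_df$mae <- vapply(plate_rows, function(rw)
        mae(preds[rw], temperatures[rw]), numeric(1))
  }
  list(plates = plate_df,
       predictions = data.frame(sample_id = meta$sample_id,
                                plate_id = meta$plate_id,
                                predicted = preds,
                                nominal = temperatures))
}

#' Infer plate-swap pairs from leave-one-plate-out predictions
#'
#' Flags plates whose MAE meets the threshold (default: 3 times the median
#' plate MAE) and searches exhaustively over pairings of the flagged plates
#' for the one that minimizes the total MAE after exchanging the nominal
#' annotations within each proposed pair. With an odd number of flagged
#' plates the best partial pairing is returned together with the unpaired
#' plate.
#'
#' @param predictions result of [looPlateTemperature()].
#' @param flag_threshold MAE flag cutoff (degC); default
#'   `3 * median(plate MAE)`.
#' @return A list: `pairs` (list of plate-id pairs), `unpaired`, `flagged`,
#'   `threshold`, and `pair_mae` (data.frame of pre- and post-exchange MAE
#'   per proposed pair).
#' @export
inferSwaps <- function(predictions, flag_threshold = NULL) {
  pl <- predictions$plates
  pr <- predictions$predictions
  if (is.null(flag_threshold)) flag_threshold <- 3 * median(pl$mae)
  flagged <- pl$plate_id[pl$mae >= flag_threshold]
  if (length(flagged) < 2)
    return(list(pairs = list(), unpaired = flagged, flagged = flagged,
                threshold = flag_threshold,
                pair_mae = data.frame(plate_a = character(0),
                                      plate_b = character(0),
                                      pre = numeric(0), post = numeric(0))))
  rows <- split(seq_len(nrow(pr)), pr$plate_id)
  # MAE of plate a's predictions against plate b's nominal labels
  # (samples matched by within-plate order)
  cross_mae <- function(a, b) {
    ia <- rows[[a]]; ib <- rows[[b]]
    n <- min(length(ia), length(ib))
    mae(pr$predicted[ia[seq_len(n)]], pr$nominal[ib[seq_len(n)]])
  }
  own_mae <- setNames(pl$mae, pl$plate_id)
  pair_cost <- function(a, b) cross_mae(a, b) + cross_mae(b, a)
  matchings <- function(items) {
    if (length(items) <= 1)
      return(list(list(pairs = list(), unpaired = items)))
    a <- items[1]
    out <- list()
    for (j in seq_along(items)[-1]) {
      rest <- items[-c(1, j)]
      for (m in matchings(rest))
        out[[length(out) + 1]] <-
          list(pairs = c(list(c(a, items[j])), m$pairs), unpaired = m$unpaired)
    }
    if (length(items) %% 2 == 1)        # allow leaving `a` unpaired
      for (m in matchings(items[-1]))
        out[[length(out) + 1]] <-
          list(pairs = m$pairs, unpaired = c(a, m$unpaired))
    out
  }
  best <- NULL; best_cost <- Inf
  for (m in matchings(flagged)) {
    cost <- sum(vapply(m$pairs, function(p) pair_cost(p[1], p[2]), numeric(1))) +
      sum(own_mae[m$unpaired])
    if (cost < best_cost) { best_cost <- cost; best <- m }
  }
  pair_mae <- do.call(rbind, lapply(best$pairs, function(p) {
    data.frame(plate_a = p[1], plate_b = p[2],
               pre = own_mae[p[1]] + own_mae[p[2]],
               post = pair_cost(p[1], p[2]))
  }))
  if (is.null(pair_mae))
    pair_mae <- data.frame(plate_a = character(0), plate_b = character(0),
                           pre = numeric(0), post = numeric(0))
  rownames(pair_mae) <- NULL
  list(pairs = best$pairs, unpaired = best$unpaired, flagged = flagged,
       threshold = flag_threshold, pair_mae = pair_mae)
}

#' Apply a swap proposal to a study
#'
#' Re-annotates the study by exchanging the metadata of each proposed plate
#' pair (the inverse of the presumed lab-work swap).
#'
#' @param study an [ExpressionStudy-class].
#' @param proposal result of [inferSwaps()] (or a list of plate-id pairs).
#' @return The re-annotated `ExpressionStudy`.
#' @export
applySwapProposal <- function(study, proposal) {
  pairs <- if (is.list(proposal) && !is.null(proposal$pairs))
    proposal$pairs else proposal
  for (p in pairs) study <- injectPlateSwap(study, p[1], p[2])
  study
}

#' Verify a swap correction by a second prediction round
#'
#' Applies the proposal, reruns [looPlateTemperature()] and accepts the
#' correction iff no plate remains flagged at the first round's threshold.
#'
#' @param study the original (uncorrected) [ExpressionStudy-class].
#' @param proposal result of [inferSwaps()].
#' @param flag_threshold MAE flag cutoff; default the proposal's threshold.
#' @return A list: `predictions` (second-round [looPlateTemperature()]),
#'   `flagged` (plates still flagged), `accepted`.
#' @export
verifyCorrection <- function(study, proposal, flag_threshold = NULL) {
  if (is.null(flag_threshold)) flag_threshold <- proposal$threshold
  corrected <- applySwapProposal(study, proposal)
  second <- looPlateTemperature(corrected)
  flagged <- second$plates$plate_id[second$plates$mae >= flag_threshold]
  list(predictions = second, flagged = flagged,
       accepted = length(flagged) == 0)
}

#' Cultivar genotype concordance per sample
#'
#' For each sample, the proportion of called loci (`"A"`/`"B"`; `"unknown"`
#' and `"none"` are excluded) whose allele matches the sample's nominal
#' cultivar. Samples pass above the upper band edge, are swap candidates
#' below the lower edge (labels likely exchanged between cultivars), and
#' are discarded inside the band - including the mixed-genotype case where
#' about half the loci match either cultivar.
#'
#' @param calls data.frame with `sample_id`, `locus_id`, `call` in
#'   `{"A", "B", "unknown", "none"}`.
#' @param nominal named character vector mapping sample id to nominal
#'   cultivar (`"A"` or `"B"`).
#' @param discard_band open interval of match proportions leading to
#'   discard (default `(0.3, 0.7)`).
#' @return A data.frame: `sample_id`, `n_called`, `prop_match_nominal`,
#'   `verdict` in `{"pass", "swap_candidate", "discard"}`.
#' @export
genotypeConcordance <- function(calls, nominal, discard_band = c(0.3, 0.7)) {
  bad <- setdiff(unique(calls$call), c("A", "B", "unknown", "none"))
  if (length(bad)) stop("unexpected call categories: ",
                        paste(bad, collapse = ", "))
  ids <- unique(calls$sample_id)
  missing <- setdiff(ids, names(nominal))
  if (length(missing)) stop("no nominal cultivar for: ",
                            paste(head(missing, 5), collapse = ", "))
  rows <- lapply(ids, function(s) {
    cc <- calls$call[calls$sample_id == s]
    called <- cc %in% c("A", "B")
    n_called <- sum(called)
    if (n_called == 0)
      return(data.frame(sample_id = s, n_called = 0L,
                        prop_match_nominal = NA_real_, verdict = "discard"))
    prop <- mean(cc[called] == nominal[[s]])
    verdict <- if (prop >= discard_band[2]) "pass"
               else if (prop <= discard_band[1]) "swap_candidate"
               else "discard"
    data.frame(sample_id = s, n_called = n_called,
               prop_match_nominal = prop, verdict = verdict)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
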