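#' Expression filter
#'
#' Keeps genes whose grand mean log2(rpm+1) across all samples is strictly
#' greater than `threshold`.
#'
#' @param study an [ExpressionStudy-class].
#' @param threshold mean-expression cutoff (default 1).
#' @return Character vector of retained gene ids.
#' @export
filterExpressed <- function(study, threshold = 1) {
  m <- exprMatrix(study)
  rownames(m)[rowMeans(m) > threshold]
}

#' Diel amplitude by smoothing spline
#'
#' Fits a cubic smoothing spline (`spar = 0.3` by default) to one gene's
#' expression over a sampling day, evaluates it on a regular grid (1.5-h
#' spacing) over the observed span, and returns the difference between the
#' maximum and minimum of the fitted curve.
#'
#' @param times sampling times (h); at least 4 points spanning >= 21 h.
#' @param values expression values (log2(rpm+1)).
#' @param spar smoothing parameter of [stats::smooth.spline()].
#' @param grid_step evaluation grid spacing (h).
#' @return A list with `amplitude`, `grid` (evaluation times), `fitted`
#'   (spline values on the grid) and `spar`.
#' @export
dielAmplitude <- function(times, values, spar = 0.3, grid_step = 1.5) {
  if (length(times) < 4) stop("at least 4 time points are required")
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (diff(range(times)) < 21)
    stop("time points must span at least 21 h")
  fit <- smooth.spline(times, values, spar = spar)
  grid <- seq(min(times), max(times), by = grid_step)
  f <- predict(fit, grid)$y
  list(amplitude = max(f) - min(f), grid = grid, fitted = f, spar = spar)
}

#' Per-gene diel amplitudes across cultivars and conditions
#'
#' @param study an [ExpressionStudy-class]; each (cultivar, condition)
#'   cell must contain one diel series of samples.
#' @param genes gene ids (default all).
#' @param spar,grid_step passed to [dielAmplitude()].
#' @return A data.frame: `gene_id`, `cultivar`, `condition_id`, `amplitude`.
#' @export
amplitudeTable <- function(study, genes = NULL, spar = 0.3, grid_step = 1.5) {
  if (is.null(genes)) genes <- rownames(study)
  meta <- sampleMeta(study)
  m <- exprMatrix(study)[genes, , drop = FALSE]
  cells <- split(seq_len(nrow(meta)),
                 list(meta$cultivar, meta$condition_id), drop = TRUE)
  rows <- lapply(names(cells), function(key) {
    idx <- cells[[key]]
    tt <- meta$clock_time_h[idx]
    data.frame(gene_id = genes,
               cultivar = meta$cultivar[idx[1]],
               condition_id = meta$condition_id[idx[1]],
               amplitude = vapply(genes, function(g)
                 dielAmplitude(tt, m[g, idx], spar, grid_step)$amplitude,
                 numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Oscillating-gene filter
#'
#' Keeps genes whose mean amplitude exceeds `threshold` (strictly) in every
#' cultivar.
#'
#' @param amplitudes data.frame as from [amplitudeTable()].
#' @param threshold amplitude cutoff (default 2, log2(rpm+1) units).
#' @return Character vector of retained gene ids.
#' @export
filterOscillating <- function(amplitudes, threshold = 2) {
  cultivars <- unique(amplitudes$cultivar)
  if (length(cultivars) < 2)
    stop("amplitudes for both cultivars are required")
  avg <- stats::aggregate(list(amp = amplitudes$amplitude),
                          by = amplitudes[, c("gene_id", "cultivar")],
                          FUN = mean)
  keep <- tapply(avg$amp > threshold, avg$gene_id, all)
  names(keep)[keep]
}

#' Cultivar-specific genes
#'
#' A gene is specific to the higher-expressing cultivar when the difference
#' of the two cultivar grand means exceeds `diff_threshold` and the lower
#' cultivar mean is below `low_threshold`.
#'
#' @param study an [ExpressionStudy-class] with two cultivars.
#' @param diff_threshold between-cultivar mean difference cutoff (strict).
#' @param low_threshold upper bound (strict) on the lower cultivar's mean.
#' @return A list with one character vector of gene ids per cultivar.
#' @export
cultivarSpecificGenes <- function(study, diff_threshold = 2,
                                  low_threshold = 0.5) {
  meta <- sampleMeta(study)
  cultivars <- sort(unique(meta$cultivar))
  if (length(cultivars) != 2) stop("exactly two cultivars are required")
  m <- exprMatrix(study)
  a <- rowMeans(m[, meta$cultivar == cultivars[1], drop = FALSE])
  b <- rowMeans(m[, meta$cultivar == cultivars[2], drop = FALSE])
  out <- list(rownames(m)[a - b > diff_threshold & b < low_threshold],
              rownames(m)[b - a > diff_threshold & a < low_threshold])
  names(out) <- cultivars
  out
}

#' Paired-t differential expression between cultivars in one condition
#'
#' Per gene, a two-sided paired t-test on the cultivar pair of samples at
#' each time point of the condition, with Benjamini-Hochberg control of the
#' FDR across genes. Cultivar-specific genes should be excluded upstream.
#'
#' @param study an [ExpressionStudy-class].
#' @param condition condition id to test.
#' @param q_threshold DEG cutoff on the BH-adjusted value.
#' @return A data.frame: `gene_id`, `condition_id`, `direction`
#'   (`"higher_A"`/`"higher_B"` by the cultivar sort order), `p`, `q`,
#'   `deg` (TRUE iff `q < q_threshold`). Genes with zero-variance
#'   differences get `p = NA` and are never DEGs.
#' @export
degPairedT <- function(study, condition, q_threshold = 0.05) {
  meta <- sampleMeta(study)
  sel <- meta$condition_id == condition
  if (!any(sel)) stop("unknown condition: ", condition)
  meta <- meta[sel, , drop = FALSE]
  m <- exprMatrix(study)[, sel, drop = FALSE]
  cultivars <- sort(unique(meta$cultivar))
  if (length(cultivars) != 2) stop("exactly two cultivars are required")
  ia <- which(meta$cultivar == cultivars[1])
  ib <- which(meta$cultivar == cultivars[2])
  ta <- meta$sampling_time_index %||% meta$clock_time_h
  ia <- ia[order(ta[ia])]
  ib <- ib[order(ta[ib])]
  if (length(ia) != length(ib) || !all(ta[ia] == ta[ib]))
    stop("cultivars are not sampled at identical time points in ", condition)
  k <- length(ia)
  if (k < 2) stop("at least 2 paired time points are required")
  d <- m[, ia, drop = FALSE] - m[, ib, drop = FALSE]
  dbar <- rowMeans(d)
  dsd <- apply(d, 1, sd)
  tstat <- dbar / (dsd / sqrt(k))
  p <- 2 * pt(abs(tstat), df = k - 1, lower.tail = FALSE)
  p[dsd == 0] <- NA
  q <- p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(m), condition_id = condition,
             direction = ifelse(dbar > 0, paste0("higher_", cultivars[1]),
                                paste0("higher_", cultivars[2])),
             p = p, q = q, deg = !is.na(q) & q < q_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temperature-correlation screen
#'
#' Per gene, the Pearson correlation of expression with the air temperature
#' at sampling, across all samples pooled. Genes exceeding the threshold
#' (strictly) form the positive and negative sets; zero-variance genes are
#' excluded and reported.
#'
#' @param study an [ExpressionStudy-class].
#' @param temperature per-sample temperature (degC), in column order.
#' @param threshold correlation cutoff (default 0.5, strict).
#' @return A list with `r` (named per-gene correlations), `positive`,
#'   `negative` (gene id vectors) and `excluded` (zero-variance genes).
#' @export
tempCorrelationScreen <- function(study, temperature, threshold = 0.5) {
  m <- exprMatrix(study)
  if (length(temperature) != ncol(m))
    stop("temperature must be annotated for every sample")
  sds <- apply(m, 1, sd)
  excluded <- rownames(m)[sds == 0]
  r <- rep(NA_real_, nrow(m))
  names(r) <- rownames(m)
  ok <- sds > 0
  r[ok] <- as.numeric(cor(t(m[ok, , drop = FALSE]), temperature))
  if (length(excluded))
    message(length(excluded), " zero-variance gene(s) excluded from the screen")
  list(r = r,
       positive = names(r)[!is.na(r) & r > threshold],
       negative = names(r)[!is.na(r) & r < -threshold],
       excluded = excluded)
}
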