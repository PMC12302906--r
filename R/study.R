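#' Construct an expression study
#'
#' @param matrix genes x samples matrix of log2(rpm+1) values.
#' @param meta data.frame of per-sample metadata with columns `sample_id`,
#'   `cultivar`, `condition_id`, `plate_id`, `clock_time_h`, `age_days` and
#'   optionally `time_h` (absolute time within the sample's environmental
#'   trace, required for model fitting) and `sampling_time_index`.
#' @return An [ExpressionStudy-class].
#' @export
ExpressionStudy <- function(matrix, meta) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) colnames(matrix) <- meta$sample_id
  missing_meta <- setdiff(colnames(matrix), meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(head(missing_meta, 5), collapse = ", "))
  if (ncol(matrix) != nrow(meta))
    stop("matrix has ", ncol(matrix), " columns but metadata describes ",
         nrow(meta), " samples")
  meta <- meta[match(colnames(matrix), meta$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2rpm = matrix), colData = cd)
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy the log2(rpm+1) matrix
#' @param x an `ExpressionStudy`.
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "log2rpm")

#' @describeIn ExpressionStudy per-sample metadata as a plain data.frame
#' @export
sampleMeta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  cultivars :", paste(sort(unique(cd$cultivar)), collapse = ", "), "\n")
  cat("  conditions:", length(unique(cd$condition_id)),
      " plates:", length(unique(cd$plate_id)), "\n")
})

#' Subset an expression study to a set of samples
#'
#' @param study an [ExpressionStudy-class].
#' @param samples sample ids or column indices.
#' @return The subsetted `ExpressionStudy`.
#' @export
subsetSamples <- function(study, samples) {
  study[, samples]
}
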