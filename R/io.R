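#' Read and write the package's table formats
#'
#' Validating loaders for the plain-text formats used throughout: TSV for
#' expression matrices, sample metadata, cluster membership and genotype
#' calls; CSV for environmental time series and condition tables. Writing
#' then reading any table is the identity.
#'
#' @name fieldfit-io
NULL

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' @rdname fieldfit-io
#' @param path file path.
#' @return `readConditionTable`: a data.frame as from
#'   [enumerateConditions()].
#' @export
readConditionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("condition_id", "light_hours", "light_temp", "dark_temp"),
               "condition table")
  if (anyDuplicated(df$condition_id))
    stop("duplicate condition_id in ", path)
  df
}

#' @rdname fieldfit-io
#' @param conditions condition data.frame.
#' @export
writeConditionTable <- function(conditions, path) {
  write.csv(conditions, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname fieldfit-io
#' @param env an [EnvSeries-class].
#' @export
writeEnvSeries <- function(env, path) {
  write.csv(as.data.frame(env), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fieldfit-io
#' @return `readEnvSeries`: an [EnvSeries-class].
#' @export
readEnvSeries <- function(path) {
  df <- read.csv(path)
  require_cols(df, c("time_h", "clock_time_h", "temperature_C", "irradiance"),
               "environmental series")
  EnvSeries(df$time_h, df$temperature_C, df$irradiance, df$clock_time_h)
}

#' @rdname fieldfit-io
#' @param study an [ExpressionStudy-class].
#' @param matrix_path,meta_path paths of the expression matrix TSV (first
#'   column `gene_id`) and the sample metadata TSV.
#' @export
writeExpressionStudy <- function(study, matrix_path, meta_path) {
  m <- exprMatrix(study)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(sampleMeta(study), meta_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(matrix_path)
}

#' @rdname fieldfit-io
#' @return `readExpressionStudy`: an [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(matrix_path, meta_path) {
  df <- read.delim(matrix_path, check.names = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("expression matrix must have gene_id as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric expression values in column ", colnames(df)[bad + 1])
  }
  rownames(m) <- df$gene_id
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  require_cols(meta, STUDY_META_COLS, "sample metadata")
  ExpressionStudy(m, meta)
}

#' @rdname fieldfit-io
#' @return `readClusterTable`: a data.frame with `exemplar_gene_id`,
#'   `member_gene_id`.
#' @export
readClusterTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  require_cols(df, c("exemplar_gene_id", "member_gene_id"), "cluster table")
  df
}

#' @rdname fieldfit-io
#' @param cluster_table cluster membership data.frame.
#' @export
writeClusterTable <- function(cluster_table, path) {
  write.table(cluster_table, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname fieldfit-io
#' @return `readGenotypeCalls`: a data.frame with `sample_id`, `locus_id`,
#'   `call`.
#' @export
readGenotypeCalls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  require_cols(df, c("sample_id", "locus_id", "call"), "genotype call table")
  bad <- setdiff(unique(df$call), c("A", "B", "unknown", "none"))
  if (length(bad))
    stop("invalid genotype call(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname fieldfit-io
#' @param calls genotype call data.frame.
#' @export
writeGenotypeCalls <- function(calls, path) {
  write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted gene models as JSON lines
#'
#' One JSON object per gene: id, predictor, the seven nonlinear parameters,
#' the eight coefficients, the criterion value and the training size.
#'
#' @param fits list of [GeneModelFit-class].
#' @param path output file.
#' @export
writeGeneModelFits <- function(fits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in fits) {
    writeLines(jsonlite::toJSON(list(
      gene_id = f@gene_id, predictor = f@predictor,
      nl = as.list(f@nl), coefs = as.list(f@coefs),
      criterion = f@criterion, n_train = f@n_train),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
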