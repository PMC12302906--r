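#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<-
#' @importFrom stats approx coef cor mad median optim p.adjust predict pt
#'   quantile rbinom rlnorm rnorm runif sd setNames smooth.spline var
#' @importFrom utils read.csv read.delim write.csv write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib fieldfit, .registration = TRUE
NULL

NL_NAMES <- c("window_h", "lag_h", "gate_peak_h", "gate_depth",
              "gate_sharp", "clip_lo", "clip_hi")
COEF_NAMES <- c("intercept", "age", "clock_cos", "clock_sin",
                "env", "env_age", "env_cos", "env_sin")
# Penalization groups over the non-intercept coefficients:
# G1 = age, G2 = clock pair, G3 = environmental response + interactions.
COEF_GROUPS <- c(age = 1L, clock_cos = 2L, clock_sin = 2L,
                 env = 3L, env_age = 3L, env_cos = 3L, env_sin = 3L)
STUDY_META_COLS <- c("sample_id", "cultivar", "condition_id", "plate_id",
                     "clock_time_h", "age_days")

#' Regularly sampled environmental trace
#'
#' Holds temperature and irradiance on a strictly uniform time grid, together
#' with the clock time (hours of day) of every grid point. This is the
#' covariate source for the gene-expression model, which averages a gated,
#' clipped transform of one of the two variables over a look-back window of
#' up to 72 h.
#'
#' @slot time hours since series start (uniform grid).
#' @slot clock_time hours-of-day in `[0, 24)` per grid point.
#' @slot temperature air temperature, degrees Celsius.
#' @slot irradiance irradiance in arbitrary flux units, non-negative.
#' @exportClass EnvSeries
setClass("EnvSeries",
  representation(time = "numeric", clock_time = "numeric",
                 temperature = "numeric", irradiance = "numeric"))

setValidity("EnvSeries", function(object) {
  n <- length(object@time)
  if (length(object@temperature) != n || length(object@irradiance) != n ||
      length(object@clock_time) != n)
    return("time, clock_time, temperature and irradiance must have equal length")
  if (n >= 2) {
    d <- diff(object@time)
    if (any(d <= 0)) return("time grid must be strictly increasing")
    if (max(d) - min(d) > 1e-8) return("time grid must be uniform")
  }
  if (any(!is.finite(object@temperature))) return("non-finite temperature")
  if (any(!is.finite(object@irradiance))) return("non-finite irradiance")
  if (any(object@irradiance < 0)) return("irradiance must be >= 0")
  if (any(object@clock_time < 0 | object@clock_time >= 24))
    return("clock_time must lie in [0, 24)")
  TRUE
})

#' Expression study: log2(rpm+1) matrix with per-sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] carrying
#' one assay `"log2rpm"` (genes x samples, values finite and non-negative)
#' and per-sample metadata columns `sample_id`, `cultivar`, `condition_id`,
#' `plate_id`, `clock_time_h` and `age_days`. An optional `time_h` column
#' gives the absolute time of each sample within its environmental trace and
#' is required for model fitting.
#'
#' @exportClass ExpressionStudy
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  if (!"log2rpm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2rpm' is required")
  m <- SummarizedExperiment::assay(object, "log2rpm")
  if (any(!is.finite(m))) return("expression values must be finite")
  if (any(m < 0)) return("log2(rpm+1) values must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(STUDY_META_COLS, colnames(cd))
  if (length(missing))
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(cd$sample_id)) return("sample_id values must be unique")
  if (!identical(colnames(object), as.character(cd$sample_id)))
    return("column names must equal sample_id")
  TRUE
})

#' Ground-truth gene for the forward simulator
#'
#' Describes one synthetic gene: its driving environmental variable
#' (`"temperature"`, `"radiation"` or `"neither"`), the seven nonlinear gate
#' and window parameters, the eight linear coefficients and the log2-scale
#' noise standard deviation. A `"neither"` gene must have all environmental
#' coefficients exactly zero.
#'
#' @exportClass TruthGene
setClass("TruthGene",
  representation(gene_id = "character", driver = "character",
                 nl = "numeric", coefs = "numeric", noise_sd = "numeric"))

setValidity("TruthGene", function(object) {
  if (!object@driver %in% c("temperature", "radiation", "neither"))
    return("driver must be temperature, radiation or neither")
  if (!identical(names(object@nl), NL_NAMES))
    return(paste("nl must be named", paste(NL_NAMES, collapse = ", ")))
  if (!identical(names(object@coefs), COEF_NAMES))
    return(paste("coefs must be named", paste(COEF_NAMES, collapse = ", ")))
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  env_cols <- c("env", "env_age", "env_cos", "env_sin")
  if (object@driver == "neither" && any(object@coefs[env_cols] != 0))
    return("a 'neither' gene must have zero environmental coefficients")
  ok <- validateNlParams(object@nl)
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' Fitted per-gene expression model
#'
#' The result of fitting the age + clock + gated-environment model to one
#' gene: the chosen environmental predictor, the seven nonlinear parameters,
#' the eight linear coefficients, the selection-criterion (BIC) value and
#' the training-set size.
#'
#' @exportClass GeneModelFit
setClass("GeneModelFit",
  representation(gene_id = "character", predictor = "character",
                 nl = "numeric", coefs = "numeric", criterion = "numeric",
                 n_train = "integer"))

setValidity("GeneModelFit", function(object) {
  if (!object@predictor %in% c("temperature", "radiation", "neither"))
    return("predictor must be temperature, radiation or neither")
  if (!identical(names(object@nl), NL_NAMES))
    return(paste("nl must be named", paste(NL_NAMES, collapse = ", ")))
  if (!identical(names(object@coefs), COEF_NAMES))
    return(paste("coefs must be named", paste(COEF_NAMES, collapse = ", ")))
  if (any(!is.finite(object@coefs))) return("coefficients must be finite")
  env_cols <- c("env", "env_age", "env_cos", "env_sin")
  if (object@predictor == "neither" && any(object@coefs[env_cols] != 0))
    return("a 'neither' fit must have zero environmental coefficients")
  TRUE
})

validateNlParams <- function(nl) {
  if (any(is.na(nl))) return("nonlinear parameters must not be NA")
  finite_req <- setdiff(NL_NAMES, c("clip_lo", "clip_hi"))
  if (any(!is.finite(nl[finite_req])))
    return("nonlinear parameters must be finite")
  if (nl["window_h"] <= 0) return("window_h must be > 0")
  if (nl["lag_h"] < 0) return("lag_h must be >= 0")
  if (nl["window_h"] + nl["lag_h"] > 72 + 1e-9)
    return("window_h + lag_h must be <= 72 (look-back limit)")
  if (nl["gate_peak_h"] < 0 || nl["gate_peak_h"] >= 24)
    return("gate_peak_h must lie in [0, 24)")
  if (nl["gate_depth"] < 0 || nl["gate_depth"] > 1)
    return("gate_depth must lie in [0, 1]")
  if (nl["gate_sharp"] <= 0) return("gate_sharp must be > 0")
  if (nl["clip_lo"] >= nl["clip_hi"]) return("clip_lo must be < clip_hi")
  TRUE
}
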