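#' Diel gate function
#'
#' Time-of-day weighting of environmental responsiveness:
#' `(1 - depth) + depth * ((1 + cos(2*pi*(clock - peak)/24)) / 2)^sharp`.
#' The gate is 24-h periodic, maximal (= 1) at the peak clock time, and its
#' minimum is `1 - depth`; `depth = 0` removes the gating entirely and
#' larger `sharp` concentrates responsiveness around the peak.
#'
#' @param clock_time hours of day (vectorized).
#' @param nl named nonlinear parameter vector (see [nlParams()]).
#' @return Gate weights in `[1 - depth, 1]`.
#' @export
gateWeight <- function(clock_time, nl) {
  (1 - nl[["gate_depth"]]) + nl[["gate_depth"]] *
    ((1 + cos(2 * pi * (clock_time - nl[["gate_peak_h"]]) / 24)) / 2) ^
    nl[["gate_sharp"]]
}

#' Named nonlinear parameter vector
#'
#' The seven parameters of the environmental-response sub-model that cannot
#' be optimized by the group LASSO: the look-back averaging `window_h` and
#' the `lag_h` between the window's end and the sample; the gate peak clock
#' time, depth and sharpness; and the input clipping bounds.
#'
#' @param window_h window length (h, > 0).
#' @param lag_h lag before the window end (h, >= 0); `window_h + lag_h <= 72`.
#' @param gate_peak_h clock time of maximal responsiveness, in `[0, 24)`.
#' @param gate_depth gate depth in `[0, 1]` (0 = ungated).
#' @param gate_sharp gate sharpness exponent (> 0).
#' @param clip_lo,clip_hi clipping bounds on the environmental variable.
#' @return A named numeric vector of length 7.
#' @export
nlParams <- function(window_h, lag_h = 0, gate_peak_h = 0, gate_depth = 0,
                     gate_sharp = 1, clip_lo = -Inf, clip_hi = Inf) {
  nl <- c(window_h = window_h, lag_h = lag_h, gate_peak_h = gate_peak_h,
          gate_depth = gate_depth, gate_sharp = gate_sharp,
          clip_lo = clip_lo, clip_hi = clip_hi)
  ok <- validateNlParams(nl)
  if (!isTRUE(ok)) stop(ok)
  nl
}

#' Gated environmental input
#'
#' The scalar covariate of the environmental-response sub-model: the mean,
#' over the trace grid points `s` in `[t - lag - window, t - lag)`, of
#' `gate(clock(s)) * clip(E(s); clip_lo, clip_hi)`, where `E` is the
#' temperature or irradiance trace.
#'
#' @param env an [EnvSeries-class].
#' @param times absolute times (h into the trace) of the samples.
#' @param nl named nonlinear parameter vector ([nlParams()]).
#' @param variable `"temperature"` or `"radiation"`.
#' @return Numeric vector, one value per sample time.
#' @export
envInput <- function(env, times, nl, variable = c("temperature", "radiation")) {
  variable <- match.arg(variable)
  nl <- nl[NL_NAMES]
  out <- cpp_env_input(env@time, env@clock_time, envVariable(env, variable),
                       times, unname(nl))
  if (anyNA(out)) {
    earliest <- env@time[1] + nl[["lag_h"]] + nl[["window_h"]]
    stop("environmental history does not cover the look-back window for ",
         sum(is.na(out)), " sample(s); earliest valid time is ",
         format(earliest), " h into the trace")
  }
  out
}

#' Model design matrix
#'
#' One row per sample: intercept, age, the clock cos/sin pair (24-h period),
#' the gated environmental input `x`, and the interactions of `x` with age
#' and the clock pair. Representing the clock phase by the cos/sin pair lets
#' the group LASSO optimize the phase implicitly (phase = atan2 of the pair).
#'
#' @param clock_time hours of day per sample.
#' @param age plant age (days) per sample.
#' @param x_env gated environmental input per sample (scalar or vector).
#' @return Numeric matrix with columns `intercept`, `age`, `clock_cos`,
#'   `clock_sin`, `env`, `env_age`, `env_cos`, `env_sin`.
#' @export
designRow <- function(clock_time, age, x_env) {
  n <- max(length(clock_time), length(age), length(x_env))
  clock_time <- rep_len(clock_time, n)
  age <- rep_len(age, n)
  x <- rep_len(x_env, n)
  cc <- cos(2 * pi * clock_time / 24)
  ss <- sin(2 * pi * clock_time / 24)
  m <- cbind(1, age, cc, ss, x, age * x, cc * x, ss * x)
  colnames(m) <- COEF_NAMES
  m
}

#' Adaptive group LASSO fit of the linear coefficients
#'
#' Two-stage estimator: a lightly ridge-penalized pilot fit defines
#' group-specific penalty weights `1/||pilot_g||`, then a group LASSO path
#' is solved by block coordinate descent on a groupwise-orthonormalized
#' design and the solution minimizing `BIC = n*log(RSS/n) + df*log(n)`
#' (df = 1 + number of nonzero coefficients) is returned. The penalty
#' groups are G1 = age, G2 = clock pair, G3 = the four environmental terms;
#' whole groups can be zeroed exactly. A `lambda` of 0 gives the exact
#' least-squares fit.
#'
#' @param X design matrix as from [designRow()] (the intercept column is
#'   detected and left unpenalized).
#' @param y expression values (log2(rpm+1)); at least 16 observations.
#' @param lambdas optional penalty grid; by default a 25-point log-spaced
#'   path from the smallest fully-sparsifying value downward.
#' @param nlambda path length when `lambdas` is NULL.
#' @param pilot_ridge relative ridge penalty of the pilot fit.
#' @return A list: `coefs` (named, length 8), `criterion` (best BIC),
#'   `lambda`, `df`, `bic_path`, `lambda_path`, `env_selected` (TRUE if any
#'   G3 coefficient is nonzero), `degenerate`.
#' @export
fitLinearAGL <- function(X, y, lambdas = NULL, nlambda = 25,
                         pilot_ridge = 1e-2) {
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (length(y) < 16) stop("at least 16 observations are required")
  has_int <- identical(colnames(X)[1], "intercept") ||
    all(X[, 1] == 1)
  Xp <- if (has_int) X[, -1, drop = FALSE] else X
  if (ncol(Xp) != 7)
    stop("expected the 7 non-intercept model columns, got ", ncol(Xp))
  fit <- cpp_agl_fit(Xp, y, unname(COEF_GROUPS) - 1L,
                     if (is.null(lambdas)) numeric(0) else lambdas,
                     pilot_ridge, nlambda)
  if (isTRUE(fit$degenerate))
    warning("degenerate design or constant response; returning intercept-only fit")
  coefs <- c(fit$b0, as.numeric(fit$beta))
  names(coefs) <- COEF_NAMES
  env_cols <- c("env", "env_age", "env_cos", "env_sin")
  list(coefs = coefs, criterion = fit$bic, lambda = fit$lambda, df = fit$df,
       bic_path = as.numeric(fit$bic_path),
       lambda_path = as.numeric(fit$lambda_path),
       env_selected = any(coefs[env_cols] != 0),
       degenerate = isTRUE(fit$degenerate))
}

#' Default nonlinear parameter grid
#'
#' The grid-search stage of the nonlinear optimization evaluates the model
#' criterion at every combination of window length (1-48 h), lag (0-12 h),
#' gate peak (0-18 h), gate depth (0 or 1), gate sharpness (1 or 4) and two
#' clipping options (the full observed range of the training environmental
#' values, or their central 80%): 768 settings.
#'
#' @param env_values environmental values observed in training (used for
#'   the clipping quantiles).
#' @return A data.frame with one row per grid point, columns [nlParams()].
#' @export
defaultNonlinearGrid <- function(env_values) {
  rng <- range(env_values)
  if (rng[2] - rng[1] < 1e-9) rng[2] <- rng[1] + 1e-6
  q <- quantile(env_values, c(0.1, 0.9), names = FALSE)
  if (q[2] - q[1] < 1e-9) { q <- rng }
  clips <- unique(rbind(rng, q))
  g <- expand.grid(window_h = c(1, 3, 6, 12, 24, 48),
                   lag_h = c(0, 3, 6, 12),
                   gate_peak_h = c(0, 6, 12, 18),
                   gate_depth = c(0, 1),
                   gate_sharp = c(1, 4),
                   clip = seq_len(2),
                   KEEP.OUT.ATTRS = FALSE)
  if (nrow(clips) == 1) g <- g[g$clip == 1, ]
  g$clip_lo <- clips[g$clip, 1]
  g$clip_hi <- clips[g$clip, 2]
  g$clip <- NULL
  g
}

#' Environmental inputs for every sample at every grid point
#'
#' Precomputes the gated environmental input for a set of samples (possibly
#' spanning several environmental traces) at each row of a nonlinear
#' parameter grid. Fitting many genes or subsampling replicates over the
#' same pool can then reuse one cache.
#'
#' @param samples data.frame with `time_h` and `condition_id` columns.
#' @param envs a named list of [EnvSeries-class] traces keyed by
#'   `condition_id`, or a single `EnvSeries` shared by all samples.
#' @param grid data.frame of nonlinear parameters ([defaultNonlinearGrid()]).
#' @param variable `"temperature"` or `"radiation"`.
#' @return Matrix of dim `nrow(samples)` x `nrow(grid)`.
#' @export
envInputMatrix <- function(samples, envs, grid,
                           variable = c("temperature", "radiation")) {
  variable <- match.arg(variable)
  envs <- as_env_list(envs, samples)
  pack <- envPack(samples, envs, variable)
  out <- cpp_env_input_grid(pack$t0s, pack$dt, pack$vals, pack$clocks,
                            pack$offsets, pack$trace_idx, pack$times,
                            as.matrix(grid[, NL_NAMES]))
  if (anyNA(out))
    stop("environmental history does not cover the look-back window for ",
         "some samples at some grid points")
  out
}

as_env_list <- function(envs, samples) {
  if (is(envs, "EnvSeries")) {
    keys <- unique(as.character(samples$condition_id))
    envs <- setNames(rep(list(envs), length(keys)), keys)
  }
  envs
}

nl_to_par <- function(nl) {
  c(log(nl[["window_h"]]),
    log(nl[["lag_h"]] + 0.25),
    nl[["gate_peak_h"]],
    stats::qlogis(min(max(nl[["gate_depth"]], 1e-4), 1 - 1e-4)),
    log(nl[["gate_sharp"]]),
    nl[["clip_lo"]],
    log(max(nl[["clip_hi"]] - nl[["clip_lo"]], 1e-9)))
}

par_to_nl <- function(u) {
  c(window_h = exp(u[1]),
    lag_h = max(0, exp(u[2]) - 0.25),
    gate_peak_h = u[3] %% 24,
    gate_depth = stats::plogis(u[4]),
    gate_sharp = exp(u[5]),
    clip_lo = u[6],
    clip_hi = u[6] + exp(u[7]))
}

#' Optimize the nonlinear parameters of the environmental sub-model
#'
#' Two-tier search: the model criterion (BIC of the adaptive group LASSO
#' fit) is evaluated at every grid point, then a Nelder-Mead refinement is
#' started from the best grid point using bound-respecting transforms (log
#' for the window, lag offset, and sharpness; logit for the gate depth; the
#' gate peak wraps modulo 24; the clipping bounds are kept ordered through a
#' log-width parameter). The better of the grid optimum and the refined
#' solution is returned, so the refinement can only improve the criterion.
#'
#' @param y expression values of one gene over the training samples.
#' @param samples training sample table (`time_h`, `clock_time_h`,
#'   `age_days`, `condition_id`).
#' @param envs environmental traces (see [envInputMatrix()]).
#' @param variable `"temperature"` or `"radiation"`.
#' @param grid nonlinear grid; default [defaultNonlinearGrid()] on the
#'   training environmental values.
#' @param xgrid optional precomputed [envInputMatrix()] for `samples` over
#'   `grid` (cache for repeated fits on the same pool).
#' @param grid_criterion optional precomputed criterion vector over the
#'   grid rows (as from the multi-gene grid search); skips the grid stage.
#' @param pack optional precomputed trace pack for `samples` (internal
#'   cache used by the experiment driver).
#' @param lambdas,nlambda,pilot_ridge passed to [fitLinearAGL()].
#' @param nm_maxit Nelder-Mead iteration budget (0 disables refinement).
#' @return A list: `nl`, `coefs`, `criterion`, `df`, `env_selected`,
#'   `grid_criterion` (criterion at every grid point), `n_train`.
#' @export
optimizeNonlinear <- function(y, samples, envs,
                              variable = c("temperature", "radiation"),
                              grid = NULL, xgrid = NULL,
                              grid_criterion = NULL,
                              lambdas = NULL, nlambda = 25,
                              pilot_ridge = 1e-2, nm_maxit = 150,
                              pack = NULL) {
  variable <- match.arg(variable)
  if (!nrow(samples)) stop("training set is empty")
  envs <- as_env_list(envs, samples)
  if (is.null(grid)) {
    ev <- unlist(lapply(names(envs), function(k) envVariable(envs[[k]], variable)))
    grid <- defaultNonlinearGrid(ev)
  }
  if (!nrow(grid)) stop("nonlinear parameter grid is empty")
  age <- samples$age_days
  cc <- cos(2 * pi * samples$clock_time_h / 24)
  ss <- sin(2 * pi * samples$clock_time_h / 24)
  lam <- if (is.null(lambdas)) numeric(0) else lambdas
  if (is.null(grid_criterion)) {
    if (is.null(xgrid)) xgrid <- envInputMatrix(samples, envs, grid, variable)
    gs <- cpp_grid_search(xgrid, age, cc, ss, y, lam, pilot_ridge, nlambda)
    crit <- as.numeric(gs$criterion)
    best <- gs$best
  } else {
    crit <- grid_criterion
    best <- which.min(crit)
  }
  if (all(!is.finite(crit)))
    stop("model criterion is non-finite at every grid point (",
         nrow(grid), " points tried)")
  nl_best <- as_nl(grid[best, ])

  if (is.null(pack)) pack <- envPack(samples, envs, variable)
  eval_nl <- function(nl) {
    x <- cpp_env_input_pack(pack$t0s, pack$dt, pack$vals, pack$clocks,
                            pack$offsets, pack$trace_idx, pack$times,
                            unname(nl[NL_NAMES]))
    if (anyNA(x)) return(NULL)
    X <- cbind(age, cc, ss, x, age * x, cc * x, ss * x)
    cpp_agl_fit(X, y, unname(COEF_GROUPS) - 1L, lam, pilot_ridge, nlambda)
  }

  nl_opt <- nl_best
  crit_opt <- crit[best]
  if (nm_maxit > 0) {
    obj <- function(u) {
      nl <- par_to_nl(u)
      if (!isTRUE(validateNlParams(nl))) return(1e10)
      cpp_nl_criterion(pack$t0s, pack$dt, pack$vals, pack$clocks,
                       pack$offsets, pack$trace_idx, pack$times,
                       age, cc, ss, y, unname(nl[NL_NAMES]),
                       lam, pilot_ridge, nlambda)
    }
    nm <- optim(nl_to_par(nl_best), obj, method = "Nelder-Mead",
                control = list(maxit = nm_maxit, reltol = 1e-6))
    if (is.finite(nm$value) && nm$value < crit_opt) {
      nl_opt <- par_to_nl(nm$par)
      crit_opt <- nm$value
    }
  }
  f <- eval_nl(nl_opt)
  coefs <- c(f$b0, as.numeric(f$beta))
  names(coefs) <- COEF_NAMES
  env_cols <- c("env", "env_age", "env_cos", "env_sin")
  list(nl = nl_opt, coefs = coefs, criterion = f$bic, df = f$df,
       env_selected = any(coefs[env_cols] != 0),
       grid_criterion = crit, n_train = length(y))
}

as_nl <- function(row) {
  nl <- as.numeric(row[NL_NAMES])
  names(nl) <- NL_NAMES
  nl
}

# Concatenated traces for the packed C++ env-input evaluator; build once
# per pool and reuse across replicates and genes.
envPackTraces <- function(envs, variable, keys = names(envs)) {
  dt <- envStep(envs[[keys[1]]])
  t0s <- numeric(length(keys))
  offs <- integer(length(keys) + 1)
  vals <- clks <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    e <- envs[[keys[k]]]
    if (is.null(e)) stop("no environmental trace for condition ", keys[k])
    if (abs(envStep(e) - dt) > 1e-9)
      stop("environmental traces must share one grid step")
    t0s[k] <- e@time[1]
    vals[[k]] <- envVariable(e, variable)
    clks[[k]] <- e@clock_time
    offs[k + 1] <- offs[k] + length(e@time)
  }
  list(t0s = t0s, dt = dt, vals = unlist(vals), clocks = unlist(clks),
       offsets = as.integer(offs), keys = keys)
}

# Attach per-sample indexing to a trace pack.
envPack <- function(samples, envs, variable, traces = NULL) {
  if (is.null(traces))
    traces <- envPackTraces(envs, variable,
                            keys = unique(as.character(samples$condition_id)))
  idx <- match(as.character(samples$condition_id), traces$keys)
  if (anyNA(idx))
    stop("no environmental trace for condition ",
         samples$condition_id[which(is.na(idx))[1]])
  c(traces, list(trace_idx = as.integer(idx - 1L), times = samples$time_h))
}

env_input_multi <- function(samples, envs, nl, variable) {
  x <- numeric(nrow(samples))
  by_env <- split(seq_len(nrow(samples)), samples$condition_id)
  for (key in names(by_env)) {
    idx <- by_env[[key]]
    env <- envs[[key]]
    x[idx] <- cpp_env_input(env@time, env@clock_time,
                            envVariable(env, variable),
                            samples$time_h[idx], unname(nl[NL_NAMES]))
  }
  x
}

#' Fit the per-gene model and choose the environmental predictor
#'
#' Runs [optimizeNonlinear()] once with temperature and once with
#' irradiance as the candidate environmental variable and keeps the fit
#' with the lower criterion. If the winning fit zeroes the whole
#' environmental coefficient group the gene is classified as driven by
#' `"neither"` variable. Criterion ties (difference below `1e-8`) resolve
#' to `"neither"` when both fits drop the environmental group, otherwise to
#' the fit with fewer nonzero coefficients, otherwise to temperature.
#'
#' @inheritParams optimizeNonlinear
#' @param gene_id gene identifier stored in the returned fit.
#' @param grids optional named list of grids (`temperature`, `radiation`).
#' @param xgrids optional named list of cached [envInputMatrix()] results.
#' @param grid_criteria optional named list (per variable) of precomputed
#'   grid criterion vectors.
#' @param packs optional named list (per variable) of precomputed trace
#'   packs.
#' @param ... passed to [optimizeNonlinear()].
#' @return A [GeneModelFit-class].
#' @export
fitGeneModel <- function(y, samples, envs, gene_id = "gene",
                         grids = NULL, xgrids = NULL,
                         grid_criteria = NULL, packs = NULL, ...) {
  fits <- lapply(c("temperature", "radiation"), function(v) {
    optimizeNonlinear(y, samples, envs, variable = v,
                      grid = grids[[v]], xgrid = xgrids[[v]],
                      grid_criterion = grid_criteria[[v]],
                      pack = packs[[v]], ...)
  })
  names(fits) <- c("temperature", "radiation")
  d <- fits$temperature$criterion - fits$radiation$criterion
  if (abs(d) < 1e-8) {
    if (!fits$temperature$env_selected && !fits$radiation$env_selected) {
      pick <- "temperature"; predictor <- "neither"
    } else {
      nz <- vapply(fits, function(f) sum(f$coefs != 0), numeric(1))
      pick <- if (nz["radiation"] < nz["temperature"]) "radiation" else "temperature"
      predictor <- if (fits[[pick]]$env_selected) pick else "neither"
    }
  } else {
    pick <- if (d < 0) "temperature" else "radiation"
    predictor <- if (fits[[pick]]$env_selected) pick else "neither"
  }
  f <- fits[[pick]]
  coefs <- f$coefs
  if (predictor == "neither")
    coefs[c("env", "env_age", "env_cos", "env_sin")] <- 0
  new("GeneModelFit", gene_id = gene_id, predictor = predictor,
      nl = f$nl, coefs = coefs, criterion = f$criterion,
      n_train = as.integer(f$n_train))
}

#' @describeIn GeneModelFit chosen environmental predictor
#' @param x,object a `GeneModelFit`.
#' @export
fitPredictor <- function(x) x@predictor

#' @describeIn GeneModelFit linear coefficients (named, length 8)
#' @export
fitCoefs <- function(x) x@coefs

#' @describeIn GeneModelFit nonlinear parameters (named, length 7)
#' @export
fitNlParams <- function(x) x@nl

#' @describeIn GeneModelFit selection-criterion (BIC) value
#' @export
fitCriterion <- function(x) x@criterion

setMethod("show", "GeneModelFit", function(object) {
  cat("GeneModelFit", object@gene_id, "- predictor:", object@predictor,
      sprintf("(criterion %.2f, n = %d)\n", object@criterion, object@n_train))
  cat("  nl:", paste(sprintf("%s=%.3g", names(object@nl), object@nl),
                     collapse = " "), "\n")
  cat("  coefs:", paste(sprintf("%s=%.3g", names(object@coefs), object@coefs),
                        collapse = " "), "\n")
})

#' Predict expression from a fitted gene model
#'
#' @param object a [GeneModelFit-class].
#' @param env environmental traces (single [EnvSeries-class] or named list
#'   keyed by `condition_id`); each sample needs 72 h of history.
#' @param samples sample table with `time_h`, `clock_time_h`, `age_days`
#'   and `condition_id`.
#' @return Predicted log2(rpm+1) vector. Fits with predictor `"neither"`
#'   are independent of the environmental traces.
#' @export
setMethod("predict", "GeneModelFit", function(object, env, samples, ...) {
  envs <- as_env_list(env, samples)
  if (object@predictor == "neither") {
    x <- rep(0, nrow(samples))
  } else {
    x <- env_input_multi(samples, envs, object@nl,
                         if (object@predictor == "radiation") "radiation"
                         else "temperature")
    if (anyNA(x)) {
      earliest <- max(vapply(envs, function(e)
        e@time[1] + object@nl[["lag_h"]] + object@nl[["window_h"]],
        numeric(1)))
      stop("environmental history does not cover the look-back window for ",
           sum(is.na(x)), " sample(s); earliest valid time is ",
           format(earliest), " h into the trace")
    }
  }
  X <- designRow(samples$clock_time_h, samples$age_days, x)
  as.numeric(X %*% object@coefs)
})
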