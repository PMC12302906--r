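#' Construct an environmental series
#'
#' @param time numeric vector of hours since series start (uniform grid).
#' @param temperature temperature in degrees Celsius.
#' @param irradiance irradiance (arbitrary flux units, >= 0).
#' @param clock_time hours-of-day per point; defaults to `time %% 24`,
#'   i.e. the series is assumed to start at local midnight.
#' @return An [EnvSeries-class] object.
#' @export
EnvSeries <- function(time, temperature, irradiance, clock_time = time %% 24) {
  new("EnvSeries", time = as.numeric(time), clock_time = as.numeric(clock_time),
      temperature = as.numeric(temperature), irradiance = as.numeric(irradiance))
}

#' @describeIn EnvSeries time grid (hours since start)
#' @param x,object an `EnvSeries`.
#' @export
envTime <- function(x) x@time

#' @describeIn EnvSeries temperature trace
#' @export
envTemperature <- function(x) x@temperature

#' @describeIn EnvSeries irradiance trace
#' @export
envIrradiance <- function(x) x@irradiance

#' @describeIn EnvSeries clock time (hours of day) per grid point
#' @export
envClock <- function(x) x@clock_time

#' @describeIn EnvSeries grid step in hours
#' @export
envStep <- function(x) {
  if (length(x@time) < 2) return(NA_real_)
  x@time[2] - x@time[1]
}

#' @describeIn EnvSeries pick one variable by name
#' @param variable `"temperature"` or `"radiation"`.
#' @export
envVariable <- function(x, variable = c("temperature", "radiation")) {
  variable <- match.arg(variable)
  if (variable == "temperature") x@temperature else x@irradiance
}

setMethod("length", "EnvSeries", function(x) length(x@time))

setMethod("show", "EnvSeries", function(object) {
  n <- length(object@time)
  cat("EnvSeries with", n, "points,",
      if (n > 1) sprintf("dt = %.3g h, span %.1f h", envStep(object),
                         diff(range(object@time))) else "", "\n")
  cat("  temperature:", sprintf("%.1f-%.1f degC", min(object@temperature),
                                max(object@temperature)), "\n")
  cat("  irradiance :", sprintf("%.3g-%.3g", min(object@irradiance),
                                max(object@irradiance)), "\n")
})

setMethod("as.data.frame", "EnvSeries", function(x, ...) {
  data.frame(time_h = x@time, clock_time_h = x@clock_time,
             temperature_C = x@temperature, irradiance = x@irradiance)
})

#' Square-wave growth-chamber environment for one condition
#'
#' Generates the idealized chamber trace: irradiance is `light_irradiance`
#' during the light phase (clock time 0 to `light_hours`) and 0 otherwise;
#' temperature is the light-period temperature during the light phase and
#' the dark-period temperature otherwise. Constant conditions (0L/24D,
#' 24L/0D) give constant traces.
#'
#' @param condition one row of [enumerateConditions()] (or any list with
#'   `light_hours`, `light_temp`, `dark_temp`).
#' @param days series length in days; at least 4 so a 72-h look-back window
#'   fits before a sampling day.
#' @param dt grid step in hours; must divide 24.
#' @param light_irradiance irradiance during the light phase (normalized
#'   chamber flux; the chamber light level is a property of the chamber, not
#'   a per-sample covariate).
#' @return An [EnvSeries-class].
#' @export
gcEnvSeries <- function(condition, days = 5, dt = 0.5, light_irradiance = 1) {
  if (days < 4) stop("days must be >= 4 (acclimation plus look-back window)")
  if (dt <= 0 || abs(24 / dt - round(24 / dt)) > 1e-9)
    stop("dt must be a positive divisor of 24 (got ", dt, ")")
  lh <- condition$light_hours
  lt <- condition$light_temp
  dk <- condition$dark_temp
  time <- seq(0, days * 24 - dt, by = dt)
  clock <- time %% 24
  light <- clock < lh
  temperature <- ifelse(light, lt, dk)
  if (lh == 0) temperature <- rep(dk, length(time))
  if (lh == 24) temperature <- rep(lt, length(time))
  irradiance <- ifelse(light, light_irradiance, 0)
  EnvSeries(time, temperature, irradiance, clock)
}

#' Synthetic field meteorology with diel-correlated temperature and irradiance
#'
#' A phenomenological generator reproducing the statistical structure of
#' paddy-field weather that matters to the model: temperature is a seasonal
#' mean plus a diel sinusoid peaking in the early afternoon plus AR(1) noise;
#' irradiance is a half-sinusoid over the daylight hours scaled by a
#' log-normal day-to-day weather factor. At the defaults the Pearson
#' correlation between temperature and irradiance is positive and >= 0.3,
#' emulating the confounding that makes the two predictors hard to separate
#' in field training data.
#'
#' @param days series length in days (>= 4).
#' @param dt grid step in hours.
#' @param seed integer seed; the trace is reproducible given the seed.
#' @param mean_temp seasonal mean temperature (degC).
#' @param diel_amp semi-amplitude of the diel temperature cycle (degC).
#' @param peak_clock clock time of the temperature peak (h).
#' @param ar_coef,ar_sd AR(1) coefficient and innovation SD of the
#'   temperature noise (degC); the defaults give smooth within-day
#'   excursions with a correlation time of several hours, as real air
#'   temperature has.
#' @param sunrise,daylength daylight window (h); irradiance is zero outside.
#' @param irr_max clear-day peak irradiance (flux units).
#' @param weather_sdlog SD of the log day-to-day weather factor.
#' @param cloud_temp_coupling fraction in `[0, 1]` by which the day's
#'   weather factor also scales the diel temperature amplitude (cloudy
#'   days are cooler); this is what makes the two variables share
#'   day-to-day information the way field meteorology does.
#' @param radiative_flicker relative amplitude by which the smooth AR(1)
#'   excursions also modulate daytime irradiance (sunny spells are both
#'   brighter and warmer), so that within-day weather is shared between
#'   the variables rather than private to temperature.
#' @return An [EnvSeries-class].
#' @export
fieldEnvSeries <- function(days = 30, dt = 0.5, seed = 1,
                           mean_temp = 25, diel_amp = 5, peak_clock = 13,
                           ar_coef = 0.95, ar_sd = 0.5,
                           sunrise = 6, daylength = 12,
                           irr_max = 1, weather_sdlog = 0.4,
                           cloud_temp_coupling = 0.6,
                           radiative_flicker = 0.25) {
  if (days < 4) stop("days must be >= 4")
  time <- seq(0, days * 24 - dt, by = dt)
  clock <- time %% 24
  n <- length(time)
  withRNG(seed, {
    noise <- numeric(n)
    if (ar_sd > 0) {
      eps <- rnorm(n, 0, ar_sd)
      noise[1] <- eps[1] / sqrt(1 - ar_coef^2)
      for (i in seq_len(n - 1)) noise[i + 1] <- ar_coef * noise[i] + eps[i + 1]
    }
    day_index <- floor(time / 24) + 1
    weather <- if (weather_sdlog > 0)
      rlnorm(max(day_index), meanlog = -weather_sdlog^2 / 2,
             sdlog = weather_sdlog) else rep(1, max(day_index))
    day_amp <- diel_amp * (1 - cloud_temp_coupling +
                           cloud_temp_coupling * weather[day_index])
    temperature <- mean_temp +
      day_amp * cos(2 * pi * (clock - peak_clock) / 24) + noise
    frac <- (clock - sunrise) / daylength
    shape <- ifelse(frac > 0 & frac < 1, sin(pi * frac), 0)
    flick <- if (ar_sd > 0)
      pmax(0, 1 + radiative_flicker * noise /
             (ar_sd / sqrt(1 - ar_coef^2))) else 1
    irradiance <- pmax(0, irr_max * shape * weather[day_index] * flick)
  })
  EnvSeries(time, temperature, irradiance, clock)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
withRNG <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
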