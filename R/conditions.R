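#' Enumerate the 73-condition growth-chamber factorial design
#'
#' Builds every chamber condition implied by the factorial rule: for each of
#' the three light/dark photoperiods (8L/16D, 12L/12D, 16L/8D), all pairs of
#' light-period temperature (20, 25, 30, 35, 40 degC) and dark-period
#' temperature (15, 20, 25, 30, 35 degC) with unequal temperatures; plus one
#' continuous-dark condition per dark temperature (0L/24D) and one
#' continuous-light condition per light temperature (24L/0D). Rows are
#' ordered by photoperiod, then light temperature, then dark temperature.
#'
#' @param light_temps,dark_temps temperature levels (degC).
#' @return A data.frame with columns `condition_id`, `light_hours`,
#'   `light_temp`, `dark_temp` (temperature `NA` where the phase is absent).
#' @examples
#' nrow(enumerateConditions())  # 73
#' @export
enumerateConditions <- function(light_temps = c(20, 25, 30, 35, 40),
                                dark_temps = c(15, 20, 25, 30, 35)) {
  rows <- list()
  for (lh in c(0, 8, 12, 16, 24)) {
    if (lh == 0) {
      for (dk in dark_temps)
        rows[[length(rows) + 1]] <- list(lh, NA_real_, dk)
    } else if (lh == 24) {
      for (lt in light_temps)
        rows[[length(rows) + 1]] <- list(lh, lt, NA_real_)
    } else {
      for (lt in light_temps) for (dk in dark_temps)
        if (lt != dk) rows[[length(rows) + 1]] <- list(lh, lt, dk)
    }
  }
  out <- data.frame(
    light_hours = vapply(rows, `[[`, numeric(1), 1),
    light_temp = vapply(rows, `[[`, numeric(1), 2),
    dark_temp = vapply(rows, `[[`, numeric(1), 3))
  out <- cbind(condition_id = conditionId(out), out)
  rownames(out) <- NULL
  out
}

conditionId <- function(df) {
  sprintf("L%02d_T%s_D%s", as.integer(df$light_hours),
          ifelse(is.na(df$light_temp), "xx",
                 sprintf("%02d", as.integer(df$light_temp))),
          ifelse(is.na(df$dark_temp), "xx",
                 sprintf("%02d", as.integer(df$dark_temp))))
}

#' Full-factorial sample plan over conditions, time points and cultivars
#'
#' Mirrors the study layout of one sampling day per condition: by default
#' eight samplings at a 3-h cadence starting 1.5 h after lights-on, for each
#' of two cultivars, giving 8 x 2 x 73 = 1168 planned samples over the full
#' chamber grid.
#'
#' @param conditions data.frame as from [enumerateConditions()].
#' @param timepoints_per_condition number of samplings per condition.
#' @param cultivars number of cultivars (labelled `A`, `B`, ...).
#' @param sampling_offsets_h clock times of the samplings (h after the start
#'   of the day); default the 3-h cadence `1.5, 4.5, ..., 22.5`.
#' @param sampling_day_start_h absolute time (h into the environmental
#'   trace) at which the sampling day begins; the default 72 leaves a full
#'   look-back window of history before the first sample.
#' @param age_at_sampling_days plant age on the sampling day.
#' @return A data.frame with one row per planned sample: `sample_id`,
#'   `cultivar`, `condition_id`, `plate_id` (one plate per condition),
#'   `clock_time_h`, `age_days`, `time_h`, `sampling_time_index`.
#' @export
makeStudySamples <- function(conditions,
                             timepoints_per_condition = 8,
                             cultivars = 2,
                             sampling_offsets_h = NULL,
                             sampling_day_start_h = 72,
                             age_at_sampling_days = 17) {
  if (is.null(sampling_offsets_h))
    sampling_offsets_h <- 1.5 + 3 * (seq_len(timepoints_per_condition) - 1)
  if (length(sampling_offsets_h) != timepoints_per_condition)
    stop("sampling_offsets_h must have length timepoints_per_condition")
  cv <- LETTERS[seq_len(cultivars)]
  plan <- expand.grid(sampling_time_index = seq_len(timepoints_per_condition),
                      cultivar = cv,
                      condition_id = conditions$condition_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan$clock_time_h <- sampling_offsets_h[plan$sampling_time_index] %% 24
  plan$time_h <- sampling_day_start_h + sampling_offsets_h[plan$sampling_time_index]
  plan$age_days <- age_at_sampling_days
  plan$plate_id <- paste0("P", match(plan$condition_id, conditions$condition_id))
  plan$sample_id <- sprintf("%s_%s_t%02d", plan$condition_id, plan$cultivar,
                            plan$sampling_time_index)
  plan[, c("sample_id", "cultivar", "condition_id", "plate_id",
           "clock_time_h", "age_days", "time_h", "sampling_time_index")]
}
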