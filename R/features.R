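#' Intake pattern objects
#'
#' An `intake_pattern` holds one lactation time series of maternal
#' metabolizable energy intake (MEI, MJ/day) together with the covariates
#' used by the scaling analysis. Day 0 (parturition) may be present in the
#' input but is excluded from all analyses; a pattern needs at least three
#' analysable measurements (day >= 1).
#'
#' @param pattern_id character scalar identifying the pattern.
#' @param species Latin binomial (used to match phylogeny tips).
#' @param breed breed label within species; `""` if not applicable.
#' @param times days postpartum, strictly increasing.
#' @param mei maternal metabolizable energy intake, MJ/day, same length as
#'   `times`, non-negative.
#' @param diet_me_density metabolizable energy density of the diet,
#'   MJ/kg dry matter.
#' @param mass_peak_kg maternal body mass at the time of peak intake, kg.
#' @param mass_onset_kg maternal body mass at the onset of lactation, kg.
#'
#' @return An object of class `intake_pattern`.
#' @export
intake_pattern <- function(pattern_id, species, breed = "", times, mei,
                           diet_me_density, mass_peak_kg,
                           mass_onset_kg = mass_peak_kg) {
  times <- as.numeric(times)
  mei <- as.numeric(mei)
  if (length(times) != length(mei)) {
    stop("`times` and `mei` must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(mei < 0)) stop("`mei` must be non-negative", call. = FALSE)
  if (diet_me_density <= 0) stop("`diet_me_density` must be > 0", call. = FALSE)
  if (mass_peak_kg <= 0 || mass_onset_kg <= 0) {
    stop("body masses must be > 0", call. = FALSE)
  }
  if (sum(times >= 1) < 3) {
    stop("pattern `", pattern_id,
         "` has fewer than 3 analysable measurements (day >= 1)",
         call. = FALSE)
  }
  structure(
    list(pattern_id = as.character(pattern_id),
         species = as.character(species),
         breed = as.character(breed),
         times = times, mei = mei,
         diet_me_density = diet_me_density,
         mass_peak_kg = mass_peak_kg,
         mass_onset_kg = mass_onset_kg),
    class = "intake_pattern")
}

#' @export
print.intake_pattern <- function(x, ...) {
  cat("<intake_pattern>", x$pattern_id, "-", x$species,
      if (nzchar(x$breed)) paste0("(", x$breed, ")") else "", "\n")
  cat("  ", length(x$times), "measurements, days",
      min(x$times), "-", max(x$times),
      "; MEI", round(min(x$mei), 2), "-", round(max(x$mei), 2), "MJ/day\n")
  invisible(x)
}

# analysable part of the series: day 0 (parturition) excluded
analysable <- function(pattern) {
  keep <- pattern$times >= 1
  list(times = pattern$times[keep], mei = pattern$mei[keep])
}

# grid spacing of a (uniformly sampled) pattern; median diff is robust to
# the odd missing day
grid_spacing <- function(times) {
  if (length(times) < 2) return(1)
  stats::median(diff(times))
}

#' Initial rate of intake elevation
#'
#' The first MEI value after the day of parturition; measurements at day 0
#' are ignored.
#'
#' @param pattern an [intake_pattern].
#' @return MEI at the first analysable measurement, MJ/day.
#' @export
initial_rate <- function(pattern) {
  a <- analysable(pattern)
  if (length(a$times) == 0) stop("no measurements with day >= 1", call. = FALSE)
  a$mei[[1]]
}

#' Peak rate and time to peak
#'
#' By default the global maximum of the analysable series. With
#' `robust = TRUE` the maximum of a centred 3-point running-median smooth
#' (endpoints kept as observed) is used instead, so that a single-day spike
#' does not define the peak. Ties are broken by the earliest time. A peak
#' on the last measurement is flagged as possibly not reached.
#'
#' @param pattern an [intake_pattern].
#' @param robust use the 3-point median smooth before locating the maximum.
#' @return list with `peak_rate` (MJ/day), `time_to_peak` (days postpartum)
#'   and `peak_at_end` flag.
#' @export
peak_rate_and_time <- function(pattern, robust = FALSE) {
  a <- analysable(pattern)
  y <- a$mei
  if (robust && length(y) >= 3) {
    sm <- y
    for (i in 2:(length(y) - 1)) sm[i] <- stats::median(y[(i - 1):(i + 1)])
    y <- sm
  }
  i <- which.max(y)  # which.max takes the earliest of tied maxima
  list(peak_rate = y[[i]],
       time_to_peak = a$times[[i]],
       peak_at_end = i == length(y))
}

#' Average rate between initial and peak
#'
#' Arithmetic mean of all measurements from the initial-rate time through
#' the peak time, inclusive of both endpoints.
#'
#' @param pattern an [intake_pattern].
#' @param time_to_peak day of the peak, as returned by [peak_rate_and_time()].
#' @return MJ/day.
#' @export
average_rate <- function(pattern, time_to_peak) {
  a <- analysable(pattern)
  mean(a$mei[a$times <= time_to_peak])
}

#' Cumulative elevation of intake to the peak
#'
#' Rectangle-rule sum of the excess of each measurement over the initial
#' rate, from the initial measurement to the peak, multiplied by the grid
#' spacing (1 day for daily series, the measurement interval for weekly
#' series). Negative summands (dips below the initial rate) are kept.
#'
#' @param pattern an [intake_pattern].
#' @param time_to_peak day of the peak.
#' @return MJ.
#' @export
cumulative_elevation_to_peak <- function(pattern, time_to_peak) {
  a <- analysable(pattern)
  keep <- a$times <= time_to_peak
  dt <- grid_spacing(a$times)
  sum((a$mei[keep] - a$mei[[1]]) * dt)
}

#' MEI from dry-matter intake and diet energy density
#'
#' @param dm_intake_kg_per_day mass of food eaten, kg dry matter per day.
#' @param me_density_mj_per_kg metabolizable energy density, MJ/kg dry matter.
#' @return metabolizable energy intake, MJ/day.
#' @export
#' @examples
#' mei_from_mass_intake(2.65, 11.5) # 30.475 MJ/day
mei_from_mass_intake <- function(dm_intake_kg_per_day, me_density_mj_per_kg) {
  if (any(dm_intake_kg_per_day <= 0) || any(me_density_mj_per_kg <= 0)) {
    stop("intake and energy density must be > 0", call. = FALSE)
  }
  dm_intake_kg_per_day * me_density_mj_per_kg
}

#' Extract the six raw characteristics of an intake pattern
#'
#' @param pattern an [intake_pattern].
#' @param robust_peak use robust peak detection (see [peak_rate_and_time()]).
#' @return one-row data frame: pattern_id, species, breed, initial_rate,
#'   peak_rate, time_to_peak, average_rate, amplitude,
#'   cumulative_elevation_to_peak, diet_me_density, mass_peak_kg,
#'   mass_onset_kg, peak_at_end.
#' @export
pattern_characteristics <- function(pattern, robust_peak = FALSE) {
  init <- initial_rate(pattern)
  pk <- peak_rate_and_time(pattern, robust = robust_peak)
  data.frame(
    pattern_id = pattern$pattern_id,
    species = pattern$species,
    breed = pattern$breed,
    initial_rate = init,
    peak_rate = pk$peak_rate,
    time_to_peak = pk$time_to_peak,
    average_rate = average_rate(pattern, pk$time_to_peak),
    amplitude = pk$peak_rate - init,
    cumulative_elevation_to_peak =
      cumulative_elevation_to_peak(pattern, pk$time_to_peak),
    diet_me_density = pattern$diet_me_density,
    mass_peak_kg = pattern$mass_peak_kg,
    mass_onset_kg = pattern$mass_onset_kg,
    peak_at_end = pk$peak_at_end,
    stringsAsFactors = FALSE)
}

#' Characteristics table for a list of patterns
#'
#' @param patterns list of [intake_pattern] objects.
#' @param robust_peak passed to [pattern_characteristics()].
#' @return data frame, one row per pattern.
#' @export
characteristics_table <- function(patterns, robust_peak = FALSE) {
  do.call(rbind, lapply(patterns, pattern_characteristics,
                        robust_peak = robust_peak))
}
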