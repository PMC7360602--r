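# System configuration and mouse profiles.  All cage-level parameters carry
# their unit in the field name (_ul, _s, _g, _hz) and every default mirrors
# the published operating point of the device.

#' Cage-level system configuration
#'
#' Validated container for every tunable cage parameter.  Defaults reproduce
#' the published operating point: 10 uL drops, 50 ug/mL drug solution, 5 Hz
#' load-cell sampling, a 10 s post-drop lockout, a 30 s exit wait followed by
#' a 20-reading / 0.1 g tare stability test, day rollover at midnight, a
#' 12/12 light cycle with lights on at 06:00, and a 57-step pump calibration
#' for a 10 uL drop from a 30 mL syringe.
#'
#' @param drop_volume_ul nominal volume per drop (microlitre).
#' @param drug_conc_ug_per_ml drug concentration of the pump solution.
#' @param sampling_rate_hz load-cell sampling rate while a mouse is present.
#' @param lockout_s refractory period after a drop before the next can be
#'   triggered, ensuring the previous drop is fully ingested.
#' @param exit_wait_s wait after a mouse leaves before the tare check.
#' @param tare_sample_count readings collected for the tare stability test.
#' @param tare_tolerance_g maximum deviation from the sample mean (gram) for
#'   the load cell to be considered empty and stable.
#' @param day_rollover_hour clock hour at which the dosing day resets.
#' @param lights_on_hour,lights_off_hour light-cycle switch points (hour).
#' @param drug_interleave_n dispense a drug drop only on every n-th drop;
#'   1 front-loads the dose, 2-3 spreads it across the day.
#' @param max_failed_reads consecutive unreadable RFID reads tolerated before
#'   an automatic controller reboot.
#' @param pump_steps_per_drop stepper-motor steps per nominal drop.
#' @param weight_round_dp decimal places weights are rounded to before mode
#'   counting.
#' @param plausible_weight_g closed interval of admissible mouse weights;
#'   raw readings outside it are discarded by the estimator.
#' @return An object of class `dosing_config` (a validated named list).
#' @export
system_config <- function(drop_volume_ul = 10,
                          drug_conc_ug_per_ml = 50,
                          sampling_rate_hz = 5,
                          lockout_s = 10,
                          exit_wait_s = 30,
                          tare_sample_count = 20L,
                          tare_tolerance_g = 0.1,
                          day_rollover_hour = 0,
                          lights_on_hour = 6,
                          lights_off_hour = 18,
                          drug_interleave_n = 1L,
                          max_failed_reads = 10L,
                          pump_steps_per_drop = 57L,
                          weight_round_dp = 1L,
                          plausible_weight_g = c(10, 60)) {
  cfg <- list(drop_volume_ul = as.numeric(drop_volume_ul),
              drug_conc_ug_per_ml = as.numeric(drug_conc_ug_per_ml),
              sampling_rate_hz = as.numeric(sampling_rate_hz),
              lockout_s = as.numeric(lockout_s),
              exit_wait_s = as.numeric(exit_wait_s),
              tare_sample_count = as.integer(tare_sample_count),
              tare_tolerance_g = as.numeric(tare_tolerance_g),
              day_rollover_hour = as.numeric(day_rollover_hour),
              lights_on_hour = as.numeric(lights_on_hour),
              lights_off_hour = as.numeric(lights_off_hour),
              drug_interleave_n = as.integer(drug_interleave_n),
              max_failed_reads = as.integer(max_failed_reads),
              pump_steps_per_drop = as.integer(pump_steps_per_drop),
              weight_round_dp = as.integer(weight_round_dp),
              plausible_weight_g = as.numeric(plausible_weight_g))
  class(cfg) <- "dosing_config"
  validate_config(cfg)
  cfg
}

#' Validate a system configuration
#'
#' @param config a `dosing_config`.
#' @return The configuration, invisibly, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_config <- function(config) {
  pos <- c("drop_volume_ul", "drug_conc_ug_per_ml", "sampling_rate_hz",
           "lockout_s", "exit_wait_s", "tare_tolerance_g")
  for (f in pos) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("validation error: '%s' must be a single positive number", f),
           call. = FALSE)
  }
  if (config$tare_sample_count < 2L)
    stop("validation error: 'tare_sample_count' must be at least 2", call. = FALSE)
  if (config$drug_interleave_n < 1L)
    stop("validation error: 'drug_interleave_n' must be at least 1", call. = FALSE)
  if (config$max_failed_reads < 1L)
    stop("validation error: 'max_failed_reads' must be at least 1", call. = FALSE)
  if (config$pump_steps_per_drop < 1L)
    stop("validation error: 'pump_steps_per_drop' must be at least 1", call. = FALSE)
  if (config$weight_round_dp < 0L)
    stop("validation error: 'weight_round_dp' must be non-negative", call. = FALSE)
  for (f in c("day_rollover_hour", "lights_on_hour", "lights_off_hour")) {
    v <- config[[f]]
    if (v < 0 || v >= 24)
      stop(sprintf("validation error: '%s' must lie in [0, 24)", f), call. = FALSE)
  }
  if (config$lights_on_hour == config$lights_off_hour)
    stop("validation error: 'lights_on_hour' must differ from 'lights_off_hour'",
         call. = FALSE)
  pw <- config$plausible_weight_g
  if (length(pw) != 2L || any(!is.finite(pw)) || pw[1] <= 0 || pw[1] >= pw[2])
    stop("validation error: 'plausible_weight_g' must be a positive increasing interval",
         call. = FALSE)
  invisible(config)
}

#' Drug mass per drop
#'
#' The drop quantum: concentration (ug/mL) times drop volume (uL) gives
#' micrograms per drop after the 1000x unit conversion.  With the defaults
#' (50 ug/mL, 10 uL) one drop carries 0.5 ug.
#'
#' @param config a [system_config()].
#' @return Micrograms of drug in one nominal drop.
#' @export
ug_per_drop <- function(config) {
  config$drug_conc_ug_per_ml * config$drop_volume_ul / 1000
}

#' Per-mouse dosing profile
#'
#' @param rfid_tag non-empty identifier (letters, digits, `_`, `-`).
#' @param group `"treatment"` or `"control"`.  Control animals receive only
#'   water; a non-zero dose supplied for a control mouse is ignored with a
#'   warning.
#' @param dose_mg_per_kg target daily dose in mg per kg bodyweight; defaults
#'   to 1 for treatment mice and 0 for controls.
#' @param baseline_day_count initial days in the cage with no drug, used to
#'   establish a baseline weight estimate before dosing starts.
#' @return An object of class `mouse_profile`.
#' @export
mouse_profile <- function(rfid_tag, group = c("treatment", "control"),
                          dose_mg_per_kg = NULL, baseline_day_count = 1L) {
  group <- match.arg(group)
  if (is.null(dose_mg_per_kg))
    dose_mg_per_kg <- if (group == "control") 0 else 1
  if (!is.character(rfid_tag) || length(rfid_tag) != 1L || !nzchar(rfid_tag) ||
      !grepl("^[A-Za-z0-9_-]+$", rfid_tag))
    stop("validation error: 'rfid_tag' must be a non-empty alphanumeric string",
         call. = FALSE)
  dose_mg_per_kg <- as.numeric(dose_mg_per_kg)
  if (!is.finite(dose_mg_per_kg) || dose_mg_per_kg < 0)
    stop("validation error: 'dose_mg_per_kg' must be non-negative", call. = FALSE)
  if (group == "control" && dose_mg_per_kg > 0) {
    warning(sprintf("control mouse '%s': dose set to 0", rfid_tag), call. = FALSE)
    dose_mg_per_kg <- 0
  }
  baseline_day_count <- as.integer(baseline_day_count)
  if (baseline_day_count < 0L)
    stop("validation error: 'baseline_day_count' must be non-negative", call. = FALSE)
  structure(list(rfid_tag = rfid_tag, group = group,
                 dose_mg_per_kg = dose_mg_per_kg,
                 baseline_day_count = baseline_day_count),
            class = "mouse_profile")
}

#' Load a cage configuration file
#'
#' Reads a YAML document with an optional `cage:` mapping (any subset of the
#' [system_config()] fields) and a required non-empty `mice:` list, each entry
#' carrying at least `rfid_tag` and `group`.
#'
#' @param path path to the YAML configuration file.
#' @return List with elements `config` (a `dosing_config`) and `profiles`
#'   (named list of `mouse_profile`, keyed by tag).
#' @export
load_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf("parse error in '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  cage <- doc$cage
  if (is.null(cage)) cage <- list()
  known <- names(formals(system_config))
  bad <- setdiff(names(cage), known)
  if (length(bad))
    stop(sprintf("parse error: unknown cage field '%s'", bad[1]), call. = FALSE)
  config <- do.call(system_config, cage)
  if (is.null(doc$mice) || length(doc$mice) == 0L)
    stop("validation error: 'mice' must list at least one mouse", call. = FALSE)
  profiles <- lapply(doc$mice, function(m) {
    if (is.null(m$rfid_tag))
      stop("parse error: mouse entry missing 'rfid_tag'", call. = FALSE)
    if (is.null(m$group))
      stop(sprintf("parse error: mouse '%s' missing 'group'", m$rfid_tag),
           call. = FALSE)
    mouse_profile(rfid_tag = m$rfid_tag, group = m$group,
                  dose_mg_per_kg = if (is.null(m$dose_mg_per_kg)) {
                    if (m$group == "control") 0 else 1
                  } else m$dose_mg_per_kg,
                  baseline_day_count = if (is.null(m$baseline_day_count)) 1L
                                       else m$baseline_day_count)
  })
  tags <- vapply(profiles, `[[`, "", "rfid_tag")
  if (anyDuplicated(tags))
    stop(sprintf("validation error: duplicate rfid_tag '%s'",
                 tags[duplicated(tags)][1]), call. = FALSE)
  names(profiles) <- tags
  list(config = config, profiles = profiles)
}

#' Write a cage configuration file
#'
#' Inverse of [load_config()]; round-tripping a configuration through
#' `write_config()` then `load_config()` reproduces it exactly.
#'
#' @param config a [system_config()].
#' @param profiles list of [mouse_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, profiles, path) {
  doc <- list(cage = unclass(config),
              mice = lapply(unname(profiles), unclass))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.dosing_config <- function(x, ...) {
  cat("<dosing_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, paste(x[[f]], collapse = "..")))
  invisible(x)
}

#' @export
print.mouse_profile <- function(x, ...) {
  cat(sprintf("<mouse_profile> %s (%s, %g mg/kg, %d baseline day(s))\n",
              x$rfid_tag, x$group, x$dose_mg_per_kg, x$baseline_day_count))
  invisible(x)
}
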