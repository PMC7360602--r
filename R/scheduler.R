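# Daily drug-drop quota and lick-by-lick drop-type selection.
#
# The dose loop: the previous day's weight estimate fixes an integer quota of
# drug drops at day rollover; drug drops are dispensed from the start of the
# dosing day (optionally interleaved with water drops) until the quota is
# met, after which every drop is water.

#' Daily drug-drop quota for a bodyweight
#'
#' The exact drop count `dose * weight / quantum` is rounded to the nearest
#' integer with ties rounded up.  With the defaults (1 mg/kg, 50 ug/mL,
#' 10 uL) the quantum is 0.5 ug, the quota is `round(2 * weight)`, and each
#' 0.5 g of bodyweight gained adds exactly one drop.
#'
#' @param weight_g bodyweight estimate in grams.
#' @param dose_mg_per_kg target daily dose (0 for control animals).
#' @param config a [system_config()].
#' @return Integer number of drug drops for the day.
#' @export
required_drug_drops <- function(weight_g, dose_mg_per_kg, config) {
  if (dose_mg_per_kg == 0) return(0L)
  q <- ug_per_drop(config)
  if (q <= 0)
    stop("configuration error: non-positive drug mass per drop with a non-zero dose",
         call. = FALSE)
  # dose[mg/kg] * weight[g] = total micrograms for the day
  as.integer(floor(dose_mg_per_kg * weight_g / q + 0.5 + 1e-9))
}

#' Fresh per-day dosing state
#'
#' @param day integer day index.
#' @param quota_drug_drops scheduled drug drops for the day.
#' @return A list of class `daily_state` with zeroed counters.
#' @export
new_daily_state <- function(day = 0L, quota_drug_drops = 0L) {
  structure(list(day = as.integer(day),
                 quota_drug_drops = as.integer(quota_drug_drops),
                 drug_drops = 0L, water_drops = 0L, drop_counter = 0L),
            class = "daily_state")
}

#' Decide whether the next drop is drug or water
#'
#' A drug drop is dispensed iff the day's quota is not yet met, the mouse is
#' in the treatment group, and the day's running drop counter sits on an
#' interleave position (`drop_counter %% drug_interleave_n == 0`, so drug
#' drops occupy positions 0, n, 2n, ...).  Baseline days carry a zero quota
#' and therefore always yield water.
#'
#' @param state a `daily_state` (fields `quota_drug_drops`, `drug_drops`,
#'   `drop_counter`).
#' @param profile the mouse's [mouse_profile()].
#' @param config a [system_config()].
#' @return `"drug"` or `"water"`.
#' @export
next_drop_type <- function(state, profile, config) {
  if (profile$group == "control") return("water")
  if (state$drug_drops < state$quota_drug_drops &&
      state$drop_counter %% config$drug_interleave_n == 0L) "drug" else "water"
}

#' Roll a mouse's dosing state over to a new day
#'
#' Invoked once per mouse at each day boundary.  Counters reset; the quota
#' for the new day is computed from the fresh weight estimate or, if the day
#' produced none, from the carried-forward estimate.  Baseline days and
#' control animals get quota 0.  Quotas change only here: mid-day weight
#' updates never alter the active quota.
#'
#' @param previous_state the expiring `daily_state` (or `NULL` on first use).
#' @param new_weight_estimate_g the day's weight estimate in grams, or `NA`
#'   if the estimator produced none.
#' @param carry_weight_g the last known estimate to fall back on (`NA` if
#'   none exists yet).
#' @param profile the mouse's [mouse_profile()].
#' @param config a [system_config()].
#' @param day integer index of the new day (0-based since cage entry).
#' @return List with `state` (fresh `daily_state`) and `schedule` (a
#'   `dose_schedule`: tag, day, weight used, quota, drop quantum).
#' @export
rollover_day <- function(previous_state, new_weight_estimate_g, carry_weight_g,
                         profile, config, day) {
  weight_used <- if (!is.na(new_weight_estimate_g)) new_weight_estimate_g
                 else carry_weight_g
  baseline <- day < profile$baseline_day_count
  quota <- if (baseline || is.na(weight_used)) 0L
           else required_drug_drops(weight_used, profile$dose_mg_per_kg, config)
  schedule <- structure(list(mouse_tag = profile$rfid_tag, day = as.integer(day),
                             weight_used_g = weight_used,
                             quota_drug_drops = quota,
                             ug_per_drop = ug_per_drop(config),
                             baseline = baseline),
                        class = "dose_schedule")
  list(state = new_daily_state(day, quota), schedule = schedule)
}

#' Dose actually delivered, in mg per kg
#'
#' Closes the loop for accuracy accounting: drug drops delivered times the
#' drop quantum, per kilogram of bodyweight.  Micrograms per gram equal
#' milligrams per kilogram, so no further conversion is needed.
#'
#' @param drug_drops number of drug drops delivered.
#' @param weight_g bodyweight in grams (must be positive).
#' @param config a [system_config()].
#' @return Delivered dose in mg/kg.
#' @export
delivered_dose_mg_per_kg <- function(drug_drops, weight_g, config) {
  if (any(weight_g <= 0))
    stop("contract violation: 'weight_g' must be positive", call. = FALSE)
  drug_drops * ug_per_drop(config) / weight_g
}
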