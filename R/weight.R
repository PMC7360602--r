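# Robust daily bodyweight estimation from the 5 Hz load-cell stream, and the
# stability test that gates automatic taring.
#
# A mouse occupying the module produces thousands of readings per day that
# mix the true weight with sensor noise and large positive transients
# (climbing, partial entry, a second mouse at the entrance).  The daily
# estimate is the mode of the rounded readings after a two-stage filter:
# (a) discard readings outside the plausible weight interval, then
# (b) discard readings more than 3 MAD-scaled deviations from the median of
# the survivors.  Filtering operates on raw values; rounding (half away from
# zero, to `weight_round_dp` places) happens before mode counting.

#' Retain plausible, non-outlying weight readings
#'
#' Stage (a) drops readings outside `plausible_weight_g` (tare-adjacent
#' near-zero values, gross artifacts); stage (b) drops readings further than
#' 3 MAD-scaled deviations from the median of the survivors (movement
#' transients that still fall inside the plausible interval).
#'
#' @param grams numeric vector of raw readings.
#' @param config a [system_config()].
#' @return The retained raw readings (possibly empty).
#' @export
retain_weight_readings <- function(grams, config) {
  pw <- config$plausible_weight_g
  kept <- grams[is.finite(grams) & grams >= pw[1] & grams <= pw[2]]
  if (length(kept) == 0L) return(kept)
  med <- stats::median(kept)
  madv <- stats::mad(kept)
  if (madv > 0) kept <- kept[abs(kept - med) <= 3 * madv]
  else kept <- kept[kept == med]
  kept
}

#' Daily bodyweight estimate: mode of rounded, filtered readings
#'
#' Rounds all retained readings from one dosing day to `weight_round_dp`
#' decimal places (half away from zero) and returns the most frequent value.
#' A tie between equally frequent values is broken in favour of the value
#' nearest the median of the retained rounded readings, and the smaller value
#' if still equidistant, so the estimate is deterministic and favours the
#' bulk of the distribution.
#'
#' @param samples numeric vector of raw readings collected over one dosing
#'   day for one mouse (a `data.frame` with a `grams` column is also
#'   accepted).
#' @param config a [system_config()].
#' @return A list of class `weight_estimate` with fields `grams`,
#'   `n_readings` and `n_retained`, or `NULL` when no reading survives
#'   filtering (callers fall back to the previous day's estimate).
#' @export
daily_weight_estimate <- function(samples, config) {
  if (is.data.frame(samples)) samples <- samples$grams
  n <- length(samples)
  kept <- retain_weight_readings(samples, config)
  if (length(kept) == 0L) return(NULL)
  rounded <- round_half_away(kept, config$weight_round_dp)
  vals <- sort(unique(rounded))
  counts <- tabulate(match(rounded, vals))
  cand <- vals[counts == max(counts)]
  if (length(cand) > 1L) {
    med <- stats::median(rounded)
    d <- abs(cand - med)
    cand <- cand[d == min(d)]
    cand <- min(cand)
  }
  structure(list(grams = cand, n_readings = n, n_retained = length(rounded)),
            class = "weight_estimate")
}

#' Tare stability test
#'
#' After the exit wait, a fixed-size sample of readings is taken from the
#' load cell; the cell is tared only if every reading lies within
#' `tare_tolerance_g` of the sample mean, i.e. the module is empty and the
#' signal is stable.
#'
#' @param readings exactly `tare_sample_count` readings in grams.
#' @param config a [system_config()].
#' @return `TRUE` if the cell should be tared.
#' @export
should_tare <- function(readings, config) {
  if (length(readings) != config$tare_sample_count)
    stop(sprintf("contract violation: expected %d readings, got %d",
                 config$tare_sample_count, length(readings)), call. = FALSE)
  max(abs(readings - mean(readings))) <= config$tare_tolerance_g
}

#' Module occupancy implied by a reading count
#'
#' Readings accumulate only while a mouse occupies the module, so the count
#' divided by the sampling rate measures daily occupancy.  8,820 readings at
#' 5 Hz correspond to 29.4 minutes.
#'
#' @param n_readings number of load-cell readings.
#' @param config a [system_config()].
#' @return Minutes of occupancy.
#' @export
occupancy_minutes <- function(n_readings, config) {
  stopifnot(n_readings >= 0)
  n_readings / config$sampling_rate_hz / 60
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("<weight_estimate> %.*f g (%d of %d readings retained)\n",
              1L, x$grams, x$n_retained, x$n_readings))
  invisible(x)
}
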