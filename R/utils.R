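# Small shared helpers: rounding convention, reproducible RNG streams,
# clock arithmetic and the closed event-code vocabulary.

#' Event codes recognised throughout the package
#'
#' The closed vocabulary used in event logs: cage entry/exit, licks, the two
#' drop types, automatic tares, failed RFID reads, controller reboots and the
#' post-drop validation image.
#'
#' @format Character vector of the nine recognised codes.
#' @export
EVENT_CODES <- c("ENTRY", "EXIT", "LICK", "DROP_WATER", "DROP_DRUG",
                 "TARE", "RFID_FAIL", "REBOOT", "IMAGE")

#' Tag used for cage-level events that belong to no single mouse
#' @export
CAGE_TAG <- "CAGE"

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimal places, used when weight
#' readings are quantised before mode counting.  base R's `round()` rounds
#' half to even, which would systematically split counts at the .x5 boundary.
#'
#' @param x numeric vector.
#' @param dp decimal places.
#' @return `x` rounded with halves moving away from zero.
#' @export
round_half_away <- function(x, dp = 1L) {
  p <- 10^dp
  # the 1e-9 guard absorbs binary representation error at exact halves
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# ---- reproducible random streams -------------------------------------------
# Each stochastic component (behaviour, load cell, pump, valve, RFID) owns an
# independent stream so that re-seeding one never perturbs the others.  A
# stream snapshots and restores .Random.seed around every draw.

#' Create an independent random-number stream
#'
#' @param seed integer seed for this stream.
#' @return An object of class `rng_stream` usable with [stream_eval()].
#' @export
rng_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(seed)
  s$state <- get(".Random.seed", globalenv())
  .restore_global_seed(old)
  class(s) <- "rng_stream"
  s
}

#' Evaluate a draw on a given random stream
#'
#' Runs `fn()` with the global RNG state swapped to the stream's state,
#' advances the stream, and restores whatever state was active before.
#'
#' @param stream an [rng_stream()].
#' @param fn zero-argument function performing random draws.
#' @return The value of `fn()`.
#' @export
stream_eval <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    .restore_global_seed(old)
  })
  fn()
}

#' Fan a master seed out into named component streams
#'
#' @param master_seed integer master seed.
#' @param names character vector naming the streams.
#' @return Named list of [rng_stream()] objects.
#' @export
fanout_streams <- function(master_seed, names) {
  root <- rng_stream(master_seed)
  seeds <- stream_eval(root, function() sample.int(2147483646L, length(names)))
  stats::setNames(lapply(seeds, rng_stream), names)
}

.save_global_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_global_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

# ---- clock arithmetic ------------------------------------------------------
# Simulation time is numeric seconds with t = 0 at local midnight of day 0.

#' Dosing-day index of a simulation time
#'
#' Days roll over at `day_rollover_hour` on the cage clock; with the default
#' (midnight) day `d` covers `[d*86400, (d+1)*86400)`.
#'
#' @param t numeric seconds since midnight of day 0.
#' @param config a [system_config()].
#' @return Integer day index (vectorised).
#' @export
day_of <- function(t, config) {
  as.integer(floor((t - config$day_rollover_hour * 3600) / 86400))
}

#' Clock hour-of-day for a simulation time
#' @inheritParams day_of
#' @return Fractional hour in `[0, 24)`.
#' @export
hour_of <- function(t, config) {
  (t %% 86400) / 3600
}

#' Is a clock hour in the dark phase?
#'
#' Dark is the half-open complement of `[lights_on, lights_off)`; schedules
#' with lights-on spanning midnight are handled explicitly.
#'
#' @param h fractional hour in `[0, 24)`.
#' @param config a [system_config()].
#' @return Logical vector.
#' @export
is_dark_hour <- function(h, config) {
  on <- config$lights_on_hour; off <- config$lights_off_hour
  if (on < off) h < on | h >= off else h >= off & h < on
}
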