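# Virtual transducers and actuators with calibrated error models: stepper
# syringe pump, gravity-fed water valve, and load cell.  Models are mutable
# environments so dispensing and taring update state in place; every random
# draw goes through an explicit rng_stream for reproducibility.

#' Stepper-driven syringe pump model
#'
#' Calibrated so `steps_per_drop` motor steps displace one nominal 10 uL
#' drop from a 30 mL syringe; per-drop volume noise is Gaussian.
#'
#' @param steps_per_drop calibration (steps per nominal drop).
#' @param volume_error_sd_ul standard deviation of per-drop volume error.
#' @param syringe_volume_ul initial syringe fill.
#' @param nominal_drop_ul drop volume the calibration refers to.
#' @return A mutable object of class `pump_model`.
#' @export
pump_model <- function(steps_per_drop = 57L, volume_error_sd_ul = 0.12,
                       syringe_volume_ul = 30000, nominal_drop_ul = 10) {
  p <- new.env(parent = emptyenv())
  p$steps_per_drop <- as.integer(steps_per_drop)
  p$volume_error_sd_ul <- volume_error_sd_ul
  p$nominal_drop_ul <- nominal_drop_ul
  p$syringe_capacity_ul <- syringe_volume_ul
  p$syringe_remaining_ul <- syringe_volume_ul
  p$dispensed_ul <- 0
  p$n_drops <- 0L
  class(p) <- "pump_model"
  p
}

#' Dispense from the syringe pump
#'
#' Realised volume is linear in the commanded steps
#' (`nominal * steps / steps_per_drop`) plus Gaussian noise, and is drawn
#' down from the syringe so total dispensed volume is conserved.
#'
#' @param pump a [pump_model()].
#' @param steps positive step command.
#' @param stream optional [rng_stream()]; `NULL` means no noise.
#' @return Realised volume in uL.
#' @export
pump_dispense <- function(pump, steps, stream = NULL) {
  stopifnot(steps > 0)
  vol <- pump$nominal_drop_ul * steps / pump$steps_per_drop
  if (!is.null(stream))
    vol <- vol + stream_eval(stream, function()
      stats::rnorm(1, 0, pump$volume_error_sd_ul))
  vol <- max(vol, 1e-6)
  if (pump$syringe_remaining_ul < vol)
    stop("hardware fault: syringe empty", call. = FALSE)
  pump$syringe_remaining_ul <- pump$syringe_remaining_ul - vol
  pump$dispensed_ul <- pump$dispensed_ul + vol
  pump$n_drops <- pump$n_drops + 1L
  vol
}

#' Refill the syringe
#' @param pump a [pump_model()].
#' @param volume_ul fill volume; defaults to the syringe capacity.
#' @return The pump, invisibly.
#' @export
pump_refill <- function(pump, volume_ul = pump$syringe_capacity_ul) {
  pump$syringe_remaining_ul <- volume_ul
  invisible(pump)
}

#' Gravity-fed water valve model
#'
#' Valve drops are cheap but imprecise: per-drop volume has a relative
#' spread `size_cv` and the mean drifts multiplicatively as the reservoir
#' level and line resistance change, at `drift_rate` per day (signed), until
#' the valve is recalibrated.
#'
#' @param nominal_drop_ul calibrated drop volume.
#' @param size_cv per-drop coefficient of variation.
#' @param drift_rate signed fractional drift per day since recalibration.
#' @param last_recalibration_t time (s) of the last recalibration.
#' @return A mutable object of class `valve_model`.
#' @export
valve_model <- function(nominal_drop_ul = 10, size_cv = 0.04,
                        drift_rate = 0.02, last_recalibration_t = 0) {
  v <- new.env(parent = emptyenv())
  v$nominal_drop_ul <- nominal_drop_ul
  v$size_cv <- size_cv
  v$drift_rate <- drift_rate
  v$last_recalibration_t <- last_recalibration_t
  v$dispensed_ul <- 0
  v$n_drops <- 0L
  class(v) <- "valve_model"
  v
}

#' Dispense from the water valve
#'
#' @param valve a [valve_model()].
#' @param t current time in seconds (drives the drift term).
#' @param stream optional [rng_stream()]; `NULL` means no noise.
#' @return Realised volume in uL.
#' @export
valve_dispense <- function(valve, t, stream = NULL) {
  days <- (t - valve$last_recalibration_t) / 86400
  vol <- valve$nominal_drop_ul * (1 + valve$drift_rate * days)
  if (!is.null(stream))
    vol <- vol * (1 + stream_eval(stream, function()
      stats::rnorm(1, 0, valve$size_cv)))
  vol <- max(vol, 1e-6)
  valve$dispensed_ul <- valve$dispensed_ul + vol
  valve$n_drops <- valve$n_drops + 1L
  vol
}

#' Recalibrate the water valve
#'
#' Resets the drift term so the next noise-free drop is nominal again;
#' routine maintenance performed every few days.
#'
#' @param valve a [valve_model()].
#' @param t recalibration time in seconds.
#' @return The valve, invisibly.
#' @export
recalibrate_valve <- function(valve, t) {
  valve$last_recalibration_t <- t
  invisible(valve)
}

#' Load-cell model
#'
#' Readings are the true mass plus the current zero offset plus noise.
#' Noise has two regimes: with an animal on the cell, movement wobble of
#' scale `noise_sd_g` and, with probability `transient_prob`, a large
#' positive movement artifact (climbing, partial entry) -- the regime the
#' downstream outlier removal is built for.  An empty cell shows only small
#' electronic noise (`empty_noise_sd_g`), which is what lets the tare
#' stability test distinguish a truly empty module from a lingering mouse.
#' Readings clip at the cell capacity.
#'
#' @param noise_sd_g movement-noise standard deviation while a mass is on
#'   the cell.
#' @param empty_noise_sd_g electronic noise of the unloaded cell.
#' @param transient_prob probability an occupied reading is a movement
#'   artifact.
#' @param transient_mean_g,transient_sd_g artifact offset distribution
#'   (offsets are truncated at zero so artifacts bias positive).
#' @param zero_offset_g initial zero-point drift.
#' @param capacity_g cell capacity (module included).
#' @return A mutable object of class `load_cell_model`.
#' @export
load_cell_model <- function(noise_sd_g = 0.2, empty_noise_sd_g = 0.02,
                            transient_prob = 0.05,
                            transient_mean_g = 15, transient_sd_g = 5,
                            zero_offset_g = 0, capacity_g = 780) {
  m <- new.env(parent = emptyenv())
  m$noise_sd_g <- noise_sd_g
  m$empty_noise_sd_g <- empty_noise_sd_g
  m$transient_prob <- transient_prob
  m$transient_mean_g <- transient_mean_g
  m$transient_sd_g <- transient_sd_g
  m$zero_offset_g <- zero_offset_g
  m$capacity_g <- capacity_g
  class(m) <- "load_cell_model"
  m
}

#' Read the load cell
#'
#' @param true_mass_g true mass on the cell (vectorised; one reading per
#'   element).  Elements with positive mass get movement noise and possible
#'   transients; zero-mass elements get only electronic noise.
#' @param model a [load_cell_model()].
#' @param stream optional [rng_stream()]; `NULL` means noise-free.
#' @return Readings in grams, clipped at the cell capacity.
#' @export
load_cell_read <- function(true_mass_g, model, stream = NULL) {
  stopifnot(all(true_mass_g >= 0))
  n <- length(true_mass_g)
  r <- true_mass_g + model$zero_offset_g
  if (!is.null(stream)) {
    occupied <- true_mass_g > 0
    r <- r + stream_eval(stream, function() {
      noise <- stats::rnorm(n, 0, ifelse(occupied, model$noise_sd_g,
                                         model$empty_noise_sd_g))
      hit <- occupied & stats::runif(n) < model$transient_prob
      if (any(hit))
        noise[hit] <- noise[hit] +
          pmax(stats::rnorm(sum(hit), model$transient_mean_g,
                            model$transient_sd_g), 0)
      noise
    })
  }
  pmin(r, model$capacity_g)
}

#' Tare the load cell
#'
#' Zeroes the cell: the accumulated zero offset is absorbed so an empty
#' module reads 0 again.
#'
#' @param model a [load_cell_model()].
#' @return The model, invisibly.
#' @export
load_cell_tare <- function(model) {
  model$zero_offset_g <- 0
  invisible(model)
}
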