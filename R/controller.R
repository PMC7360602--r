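# The session state machine.  Event-driven and clock-agnostic: it consumes a
# time-ordered stream of sensor events (tag reads, tag-out transitions,
# licks, weight samples, exit-wait checks) and emits the coded event log,
# per-day weight estimates and dose schedules.  The same controller runs
# against the virtual cage here or, in principle, real transducers.
#
# Phases: IDLE (module empty), OCCUPIED (a confirmed tag present),
# EXIT_WAIT (tag gone, waiting before the tare check).  Only one mouse can
# be OCCUPIED at a time; a different confirmed tag closes the old session.
# The post-drop lockout is a property of the spout, not of the session, so
# it survives exits, re-entries and mouse switches.

#' Create a dosing controller
#'
#' @param config a [system_config()].
#' @param profiles named list of [mouse_profile()] (the cage registry).
#' @param dispense optional function `(type, t) -> volume_ul` resolving a
#'   drop command against actuator models; `NULL` dispenses the nominal
#'   drop volume.
#' @param on_tare optional zero-argument callback invoked when the
#'   controller tares the load cell.
#' @param origin_date calendar date of simulation day 0 (time 0 is local
#'   midnight of this date, taken as UTC).
#' @param keep_weight_buffers keep each day's raw weight samples after
#'   rollover (needed to write daily weight files; off by default to bound
#'   memory).
#' @return A mutable object of class `cage_controller`.
#' @export
controller_new <- function(config, profiles, dispense = NULL, on_tare = NULL,
                           origin_date = as.Date("2024-01-01"),
                           keep_weight_buffers = FALSE) {
  stopifnot(inherits(config, "dosing_config"), length(profiles) > 0)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    names(profiles) <- vapply(profiles, `[[`, "", "rfid_tag")
  ctrl <- new.env(parent = emptyenv())
  ctrl$cfg <- config
  ctrl$profiles <- profiles
  ctrl$dispense <- if (is.null(dispense))
    function(type, t) config$drop_volume_ul else dispense
  ctrl$on_tare <- on_tare
  ctrl$origin_date <- as.Date(origin_date)
  ctrl$keep_weight_buffers <- keep_weight_buffers

  ctrl$phase <- "IDLE"
  ctrl$current_tag <- NA_character_
  ctrl$lockout_until <- -Inf
  ctrl$failed_reads <- 0L
  ctrl$exit_deadline <- NA_real_
  ctrl$day <- 0L

  # event buffer: parallel vectors grown by doubling
  ev <- new.env(parent = emptyenv())
  ev$t <- numeric(1024); ev$tag <- character(1024)
  ev$code <- character(1024); ev$payload <- character(1024); ev$n <- 0L
  ctrl$ev <- ev

  ctrl$mouse <- new.env(parent = emptyenv())
  for (tag in names(profiles)) {
    st <- new.env(parent = emptyenv())
    st$quota <- 0L; st$drug <- 0L; st$water <- 0L; st$counter <- 0L
    st$carry_g <- NA_real_
    st$bufs <- new.env(parent = emptyenv())
    assign(tag, st, envir = ctrl$mouse)
  }

  ctrl$estimates <- list()   # one row per mouse per completed day
  ctrl$schedules <- list()   # one row per mouse per day quota was set
  for (tag in names(profiles))   # day 0: baseline and/or no weight yet
    ctrl$schedules[[length(ctrl$schedules) + 1L]] <-
      list(tag = tag, day = 0L, weight_used_g = NA_real_, quota = 0L,
           baseline = 0L < profiles[[tag]]$baseline_day_count)
  class(ctrl) <- "cage_controller"
  ctrl
}

.emit <- function(ctrl, t, tag, code, payload = "") {
  ev <- ctrl$ev
  n <- ev$n + 1L
  if (n > length(ev$t)) {
    grow <- function(x) { length(x) <- 2L * length(x); x }
    ev$t <- grow(ev$t); ev$tag <- grow(ev$tag)
    ev$code <- grow(ev$code); ev$payload <- grow(ev$payload)
  }
  ev$t[n] <- round(t * 1000) / 1000    # millisecond log resolution
  ev$tag[n] <- tag; ev$code[n] <- code
  ev$payload[n] <- payload
  ev$n <- n
  invisible(NULL)
}

.advance <- function(ctrl, t) {
  target <- day_of(t, ctrl$cfg)
  while (target > ctrl$day) .rollover(ctrl, ctrl$day + 1L)
  invisible(NULL)
}

# Day rollover: estimate each mouse's weight from the expiring day's buffer,
# record it, reset counters, and set the new day's quota from the fresh (or
# carried-forward) estimate.
.rollover <- function(ctrl, new_day) {
  cfg <- ctrl$cfg
  old <- new_day - 1L
  for (tag in names(ctrl$profiles)) {
    st <- get(tag, envir = ctrl$mouse)
    prof <- ctrl$profiles[[tag]]
    buf <- get0(as.character(old), envir = st$bufs)
    g <- if (is.null(buf)) numeric(0) else buf$g[seq_len(buf$n)]
    est <- daily_weight_estimate(g, cfg)
    carried <- is.null(est)
    est_g <- if (carried) NA_real_ else est$grams
    ctrl$estimates[[length(ctrl$estimates) + 1L]] <-
      list(tag = tag, day = old,
           grams = if (carried) st$carry_g else est_g,
           n_readings = length(g),
           n_retained = if (carried) 0L else est$n_retained,
           carried = carried)
    if (!carried) st$carry_g <- est_g

    ro <- rollover_day(NULL, est_g, st$carry_g, prof, cfg, new_day)
    st$quota <- ro$state$quota_drug_drops
    st$drug <- 0L; st$water <- 0L; st$counter <- 0L
    ctrl$schedules[[length(ctrl$schedules) + 1L]] <-
      list(tag = tag, day = new_day,
           weight_used_g = ro$schedule$weight_used_g,
           quota = ro$schedule$quota_drug_drops,
           baseline = ro$schedule$baseline)
    if (!ctrl$keep_weight_buffers && !is.null(buf))
      rm(list = as.character(old), envir = st$bufs)
  }
  ctrl$day <- new_day
  invisible(NULL)
}

#' Handle an RFID tag read
#'
#' Every tag-in-range transition triggers a read.  A readable, registered
#' tag opens (or silently confirms) a session; an unreadable or unregistered
#' tag logs a failed read, and too many consecutive failures trigger an
#' automatic reboot.  The reboot resets session state only -- per-day drop
#' counters persist, so a reboot can never double-dose.
#'
#' @param ctrl a [controller_new()] controller.
#' @param t event time in seconds.
#' @param tag the tag string, or `NA` for an unreadable read.
#' @return The controller, invisibly.
#' @export
on_tag_in_range <- function(ctrl, t, tag) {
  .advance(ctrl, t)
  if (is.na(tag) || !tag %in% names(ctrl$profiles)) {
    .emit(ctrl, t, CAGE_TAG, "RFID_FAIL",
          if (is.na(tag)) "" else paste0("unknown:", tag))
    ctrl$failed_reads <- ctrl$failed_reads + 1L
    if (ctrl$failed_reads >= ctrl$cfg$max_failed_reads) {
      .emit(ctrl, t, CAGE_TAG, "REBOOT", "")
      ctrl$phase <- "IDLE"
      ctrl$current_tag <- NA_character_
      ctrl$exit_deadline <- NA_real_
      ctrl$lockout_until <- -Inf
      ctrl$failed_reads <- 0L
    }
    return(invisible(ctrl))
  }
  ctrl$failed_reads <- 0L
  if (ctrl$phase == "OCCUPIED") {
    if (identical(ctrl$current_tag, tag)) return(invisible(ctrl))  # confirmation
    .emit(ctrl, t, ctrl$current_tag, "EXIT", "")   # implicit session close
  }
  ctrl$phase <- "OCCUPIED"
  ctrl$current_tag <- tag
  ctrl$exit_deadline <- NA_real_
  .emit(ctrl, t, tag, "ENTRY", "")
  invisible(ctrl)
}

#' Handle the tag leaving reader range
#'
#' Deactivates the lick trigger and weight collection and starts the exit
#' wait; ignored when no session is open.
#'
#' @inheritParams on_tag_in_range
#' @return The controller, invisibly.
#' @export
on_tag_out_of_range <- function(ctrl, t) {
  .advance(ctrl, t)
  if (ctrl$phase != "OCCUPIED") return(invisible(ctrl))
  .emit(ctrl, t, ctrl$current_tag, "EXIT", "")
  ctrl$phase <- "EXIT_WAIT"
  ctrl$current_tag <- NA_character_
  ctrl$exit_deadline <- t + ctrl$cfg$exit_wait_s
  invisible(ctrl)
}

#' Handle a lick at the spout
#'
#' With a session open and the lockout expired, the lick triggers delivery
#' of the drop type chosen by [next_drop_type()], a validation image, and a
#' fresh lockout.  Within the lockout only the lick itself is logged.  With
#' no confirmed tag nothing is logged and nothing is dispensed.
#'
#' @inheritParams on_tag_in_range
#' @return Invisibly, a list: `delivered` (logical), and when delivered also
#'   `type` (`"drug"`/`"water"`) and `volume_ul` (realised volume).
#' @export
on_lick <- function(ctrl, t) {
  .advance(ctrl, t)
  if (ctrl$phase != "OCCUPIED") return(invisible(list(delivered = FALSE)))
  tag <- ctrl$current_tag
  .emit(ctrl, t, tag, "LICK", "")
  if (t < ctrl$lockout_until) return(invisible(list(delivered = FALSE)))
  st <- get(tag, envir = ctrl$mouse)
  prof <- ctrl$profiles[[tag]]
  type <- next_drop_type(list(quota_drug_drops = st$quota, drug_drops = st$drug,
                              drop_counter = st$counter),
                         prof, ctrl$cfg)
  vol <- ctrl$dispense(type, t)
  code <- if (type == "drug") "DROP_DRUG" else "DROP_WATER"
  .emit(ctrl, t, tag, code, sprintf("%.3f", vol))
  .emit(ctrl, t, tag, "IMAGE", sprintf("img_%s_%010.0f", tag, round(t)))
  if (type == "drug") st$drug <- st$drug + 1L else st$water <- st$water + 1L
  st$counter <- st$counter + 1L
  ctrl$lockout_until <- t + ctrl$cfg$lockout_s
  invisible(list(delivered = TRUE, type = type, volume_ul = vol))
}

#' Handle one load-cell sample while a mouse is present
#'
#' Appends the reading to the occupying mouse's buffer for the sample's
#' dosing day; a tick with no session open is a no-op.
#'
#' @inheritParams on_tag_in_range
#' @param grams the reading.
#' @return The controller, invisibly.
#' @export
on_weight_tick <- function(ctrl, t, grams) {
  if (ctrl$phase != "OCCUPIED") return(invisible(ctrl))
  append_weight_samples(ctrl, ctrl$current_tag, t, grams)
  invisible(ctrl)
}

#' Append a block of weight samples for a mouse
#'
#' Vectorised buffer append used by the simulator: samples are keyed to the
#' dosing day each individual timestamp falls in, so occupancies spanning
#' midnight are split correctly.
#'
#' @param ctrl the controller.
#' @param tag mouse tag.
#' @param t numeric vector of sample times.
#' @param grams numeric vector of readings (same length).
#' @return The controller, invisibly.
#' @export
append_weight_samples <- function(ctrl, tag, t, grams) {
  stopifnot(length(t) == length(grams))
  if (length(t) == 0L) return(invisible(ctrl))
  st <- get(tag, envir = ctrl$mouse)
  days <- day_of(t, ctrl$cfg)
  for (d in unique(days)) {
    sel <- days == d
    key <- as.character(d)
    buf <- get0(key, envir = st$bufs)
    if (is.null(buf)) {
      buf <- new.env(parent = emptyenv())
      buf$t <- numeric(4096); buf$g <- numeric(4096); buf$n <- 0L
      assign(key, buf, envir = st$bufs)
    }
    k <- sum(sel)
    while (buf$n + k > length(buf$t)) {
      length(buf$t) <- 2L * length(buf$t); length(buf$g) <- 2L * length(buf$g)
    }
    idx <- buf$n + seq_len(k)
    buf$t[idx] <- t[sel]; buf$g[idx] <- grams[sel]
    buf$n <- buf$n + k
  }
  invisible(ctrl)
}

#' Handle the end of the exit wait
#'
#' Fires only if the controller is still in EXIT_WAIT and the deadline has
#' passed (a re-entry cancels the wait).  The supplied readings are put
#' through the tare stability test; on success a TARE event is logged and
#' the tare callback zeroes the (virtual) load cell.  Either way the module
#' returns to IDLE.
#'
#' @inheritParams on_tag_in_range
#' @param readings exactly `tare_sample_count` load-cell readings in grams.
#' @return The controller, invisibly.
#' @export
on_exit_wait_elapsed <- function(ctrl, t, readings) {
  .advance(ctrl, t)
  if (ctrl$phase != "EXIT_WAIT" || is.na(ctrl$exit_deadline) ||
      t < ctrl$exit_deadline)
    return(invisible(ctrl))
  if (should_tare(readings, ctrl$cfg)) {
    .emit(ctrl, t, CAGE_TAG, "TARE", sprintf("%.3f", mean(readings)))
    if (!is.null(ctrl$on_tare)) ctrl$on_tare()
  }
  ctrl$phase <- "IDLE"
  ctrl$exit_deadline <- NA_real_
  invisible(ctrl)
}

#' Events logged so far
#'
#' @param ctrl the controller.
#' @return `data.frame` with columns `time` (POSIXct, UTC, millisecond
#'   resolution), `tag`, `code`, `payload`.
#' @export
controller_events <- function(ctrl) {
  ev <- ctrl$ev
  n <- ev$n
  origin <- as.POSIXct(paste(ctrl$origin_date, "00:00:00"), tz = "UTC")
  data.frame(time = origin + ev$t[seq_len(n)],
             tag = ev$tag[seq_len(n)],
             code = ev$code[seq_len(n)],
             payload = ev$payload[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Close out a run
#'
#' Advances the controller to `t_end` (triggering any outstanding day
#' rollovers) and flushes the final partial day, then returns the run's
#' tables.
#'
#' @param ctrl the controller.
#' @param t_end end-of-run time in seconds.
#' @return List with `events`, `estimates` (one row per mouse per day:
#'   estimate in grams, reading counts, carried flag) and `schedules` (one
#'   row per mouse per day: weight used, quota, baseline flag), all
#'   `data.frame`s.
#' @export
controller_finalize <- function(ctrl, t_end) {
  .advance(ctrl, t_end)
  if (t_end > ctrl$day * 86400 + ctrl$cfg$day_rollover_hour * 3600)
    .rollover(ctrl, ctrl$day + 1L)
  est <- do.call(rbind, lapply(ctrl$estimates, function(r)
    data.frame(tag = r$tag, day = r$day, grams = r$grams,
               n_readings = r$n_readings, n_retained = r$n_retained,
               carried = r$carried, stringsAsFactors = FALSE)))
  sch <- do.call(rbind, lapply(ctrl$schedules, function(r)
    data.frame(tag = r$tag, day = r$day, weight_used_g = r$weight_used_g,
               quota = r$quota, baseline = r$baseline,
               stringsAsFactors = FALSE)))
  est$date <- ctrl$origin_date + est$day
  sch$date <- ctrl$origin_date + sch$day
  list(events = controller_events(ctrl), estimates = est, schedules = sch)
}

#' @export
print.cage_controller <- function(x, ...) {
  cat(sprintf("<cage_controller> phase=%s tag=%s day=%d events=%d\n",
              x$phase, x$current_tag, x$day, x$ev$n))
  invisible(x)
}
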