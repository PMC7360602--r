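# Simulated colony behaviour: circadian visit bouts, lick trains, paced
# daily intake and gradual weight gain.  Defaults emulate the empirical
# operating regime of the real system: mice drink essentially at the lockout
# rate while in the module, accumulating ~1.7 mL across ~30 min of occupancy
# per day, with ~74% of activity in the dark phase, 30-40% day-to-day
# variability in consumption (driven by a daily engagement factor plus an
# intake target), and a gain of ~5 g over two months from a ~25 g start.
# Per-visit lick-bout statistics are not empirically constrained; the bout
# defaults here are the package's own construction.

#' Behavioural parameters for one simulated mouse
#'
#' @param tag RFID tag string.
#' @param start_weight_g bodyweight at day 0.
#' @param growth_g_per_day deterministic growth rate (default 5 g over 60
#'   days).
#' @param weight_fluct_sd_g day-to-day fluctuation around the growth curve;
#'   the default gives a mean absolute day-to-day change of ~1-1.5% of
#'   bodyweight.
#' @param visit_rate_dark,visit_rate_light module visits per hour by light
#'   phase.  The defaults put ~74% of activity in the dark phase and yield
#'   ~40 visits (about 30 min occupancy) per day.
#' @param engagement_cv day-to-day coefficient of variation of a lognormal
#'   multiplier on both visit rates, modelling fluctuating task engagement.
#' @param mean_visit_s,min_visit_s,max_visit_s visit duration model
#'   (shifted, truncated exponential).
#' @param inter_lick_mean_s mean gap between effective licks within a visit.
#'   The default keeps the spout occupied, so drops arrive at close to the
#'   lockout rate while the mouse is present -- the regime observed on the
#'   real device.
#' @param intake_mean_ml,intake_cv daily fluid intake target: lognormal
#'   with this mean and day-to-day coefficient of variation.  Intake is
#'   paced across the day in proportion to the circadian visit profile, so
#'   drinking keeps its dark-phase bias even when the target binds.  The
#'   target mean sits above realised consumption because pacing, finite
#'   occupancy and the lockout truncate it; the default is calibrated so
#'   realised consumption averages ~1.7 mL/day.
#' @return An object of class `sim_mouse`.
#' @export
sim_mouse <- function(tag, start_weight_g = 25,
                      growth_g_per_day = 5 / 60,
                      weight_fluct_sd_g = 0.25,
                      visit_rate_dark = 2.5,
                      visit_rate_light = 0.883,
                      engagement_cv = 0.25,
                      mean_visit_s = 50, min_visit_s = 5, max_visit_s = 300,
                      inter_lick_mean_s = 0.7,
                      intake_mean_ml = 2.2, intake_cv = 0.35) {
  stopifnot(visit_rate_dark > visit_rate_light, visit_rate_light >= 0,
            start_weight_g > 0, intake_mean_ml > 0, intake_cv >= 0,
            engagement_cv >= 0)
  structure(list(tag = tag, start_weight_g = start_weight_g,
                 growth_g_per_day = growth_g_per_day,
                 weight_fluct_sd_g = weight_fluct_sd_g,
                 visit_rate_dark = visit_rate_dark,
                 visit_rate_light = visit_rate_light,
                 engagement_cv = engagement_cv,
                 mean_visit_s = mean_visit_s, min_visit_s = min_visit_s,
                 max_visit_s = max_visit_s,
                 inter_lick_mean_s = inter_lick_mean_s,
                 intake_mean_ml = intake_mean_ml, intake_cv = intake_cv),
            class = "sim_mouse")
}

#' True-weight trajectory for a simulated mouse
#'
#' Deterministic linear growth plus independent daily fluctuations; one
#' value per day (the day's true weight, constant within the day).
#'
#' @param mouse a [sim_mouse()].
#' @param days number of days.
#' @param stream an [rng_stream()] (`NULL` for the noise-free curve).
#' @return Numeric vector of length `days`.
#' @export
weight_trajectory <- function(mouse, days, stream = NULL) {
  base <- mouse$start_weight_g + mouse$growth_g_per_day * (seq_len(days) - 1L)
  if (!is.null(stream) && mouse$weight_fluct_sd_g > 0)
    base <- base + stream_eval(stream, function()
      stats::rnorm(days, 0, mouse$weight_fluct_sd_g))
  base
}

#' Daily intake targets for a simulated mouse
#'
#' Lognormal draws with the mouse's mean and day-to-day CV; drinking stops
#' for the day once the target is reached.
#'
#' @inheritParams weight_trajectory
#' @return Numeric vector of mL targets, length `days`.
#' @export
draw_daily_intake <- function(mouse, days, stream = NULL) {
  if (is.null(stream) || mouse$intake_cv == 0)
    return(rep(mouse$intake_mean_ml, days))
  sdlog <- sqrt(log(1 + mouse$intake_cv^2))
  meanlog <- log(mouse$intake_mean_ml) - sdlog^2 / 2
  stream_eval(stream, function() stats::rlnorm(days, meanlog, sdlog))
}

#' Daily engagement multipliers
#'
#' Mean-one lognormal factors scaling a mouse's visit rates day by day,
#' the main driver of day-to-day variability in occupancy and consumption.
#'
#' @inheritParams weight_trajectory
#' @return Numeric vector of multipliers, length `days`.
#' @export
draw_daily_engagement <- function(mouse, days, stream = NULL) {
  if (is.null(stream) || mouse$engagement_cv == 0) return(rep(1, days))
  sdlog <- sqrt(log(1 + mouse$engagement_cv^2))
  stream_eval(stream, function() stats::rlnorm(days, -sdlog^2 / 2, sdlog))
}

# Fraction of a mouse's daily activity budget accrued by clock hour h,
# proportional to the cumulative visit-rate profile.  Used to pace intake
# so that drinking follows the circadian structure instead of emptying the
# daily target in the first active hours.
.pacing_frac <- function(h, mouse, config) {
  w <- ifelse(is_dark_hour(0:23, config), mouse$visit_rate_dark,
              mouse$visit_rate_light)
  cum <- c(0, cumsum(w))
  hi <- pmin(floor(h), 23)
  (cum[hi + 1L] + (h - hi) * w[hi + 1L]) / cum[25L]
}

#' Generate one day of module visits for one mouse
#'
#' Inhomogeneous Poisson process with piecewise-constant hourly rate
#' (`visit_rate_dark` in the dark phase, `visit_rate_light` in the light
#' phase, both scaled by `rate_multiplier`); durations are shifted truncated
#' exponentials.  Overlaps between mice are resolved afterwards by
#' [resolve_single_occupancy()].
#'
#' @param mouse a [sim_mouse()].
#' @param day integer day index (visits fall in `[day*86400, (day+1)*86400)`).
#' @param config a [system_config()] (light schedule).
#' @param stream an [rng_stream()].
#' @param rate_multiplier day-level engagement factor.
#' @return `data.frame` with columns `tag`, `start`, `end` (seconds),
#'   ordered by start.
#' @export
generate_visits <- function(mouse, day, config, stream, rate_multiplier = 1) {
  hours <- 0:23
  rates <- rate_multiplier *
    ifelse(is_dark_hour(hours, config), mouse$visit_rate_dark,
           mouse$visit_rate_light)
  out <- stream_eval(stream, function() {
    n_h <- stats::rpois(24, rates)
    n <- sum(n_h)
    if (n == 0L) return(data.frame(tag = character(), start = numeric(),
                                   end = numeric(), stringsAsFactors = FALSE))
    starts <- day * 86400 + rep(hours, n_h) * 3600 + stats::runif(n) * 3600
    dur <- pmin(mouse$min_visit_s +
                  stats::rexp(n, 1 / (mouse$mean_visit_s - mouse$min_visit_s)),
                mouse$max_visit_s)
    data.frame(tag = rep(mouse$tag, n), start = starts, end = starts + dur,
               stringsAsFactors = FALSE)
  })
  out[order(out$start), , drop = FALSE]
}

#' Enforce single occupancy across mice
#'
#' The module physically admits one mouse at a time.  Visits are processed
#' in start order; a visit starting before the previous one ends is
#' truncated at the front (its start moves to the previous end plus a small
#' gap) and dropped entirely if too little remains.
#'
#' @param visits combined visit `data.frame` (`tag`, `start`, `end`).
#' @param min_gap_s minimum separation between consecutive occupancies.
#' @param min_visit_s visits shorter than this after truncation are dropped.
#' @return Non-overlapping visit `data.frame` ordered by start.
#' @export
resolve_single_occupancy <- function(visits, min_gap_s = 2, min_visit_s = 5) {
  visits <- visits[order(visits$start), , drop = FALSE]
  n <- nrow(visits)
  if (n == 0L) return(visits)
  start <- visits$start; end <- visits$end
  keep <- logical(n)
  cur_end <- -Inf
  for (i in seq_len(n)) {
    s <- max(start[i], cur_end + min_gap_s)
    if (end[i] - s >= min_visit_s) {
      start[i] <- s
      keep[i] <- TRUE
      cur_end <- end[i]
    }
  }
  out <- visits[keep, , drop = FALSE]
  out$start <- start[keep]
  rownames(out) <- NULL
  out
}

#' Generate lick times within one visit
#'
#' Coarse bout model: effective licks arrive with a 0.2 s floor plus an
#' exponential gap, so a present mouse keeps the spout engaged and drops
#' arrive at close to the lockout rate.  The train is empty when satiety is
#' exhausted and is truncated once it could already have yielded the drops
#' needed to satisfy the remaining intake (one drop per lockout window).
#'
#' @param start,end visit interval in seconds.
#' @param remaining_ml fluid still wanted at this point of the day.
#' @param mouse a [sim_mouse()].
#' @param config a [system_config()] (drop volume, lockout).
#' @param stream an [rng_stream()].
#' @return Numeric vector of lick times (possibly empty).
#' @export
generate_licks <- function(start, end, remaining_ml, mouse, config, stream) {
  if (remaining_ml <= 0 || end <= start) return(numeric(0))
  mean_gap <- mouse$inter_lick_mean_s
  drops_needed <- ceiling(remaining_ml * 1000 / config$drop_volume_ul) + 1L
  horizon <- min(end, start + drops_needed * config$lockout_s + mean_gap)
  n_guess <- ceiling((horizon - start) / mean_gap * 1.5) + 10L
  gaps <- stream_eval(stream, function()
    0.2 + stats::rexp(n_guess, 1 / max(mean_gap - 0.2, 0.05)))
  times <- start + cumsum(gaps)
  times[times < horizon]
}

#' Simulation-side options for a colony run
#'
#' @param rfid_fail_prob probability a visit's entry read is unreadable
#'   (the mouse is then never identified for that visit).
#' @param valve_recal_days maintenance interval for valve recalibration.
#' @param zero_drift_sd_g_per_h random-walk scale of the load-cell zero
#'   offset between tares.
#' @param keep_weight_buffers retain raw per-day weight samples on the
#'   controller (for writing daily weight files).
#' @return A list of class `sim_options`.
#' @export
sim_options <- function(rfid_fail_prob = 0.01, valve_recal_days = 3,
                        zero_drift_sd_g_per_h = 0.01,
                        keep_weight_buffers = FALSE) {
  structure(list(rfid_fail_prob = rfid_fail_prob,
                 valve_recal_days = valve_recal_days,
                 zero_drift_sd_g_per_h = zero_drift_sd_g_per_h,
                 keep_weight_buffers = keep_weight_buffers),
            class = "sim_options")
}

#' Run a virtual colony against the dosing controller
#'
#' The full desk-scale experiment: simulated mice visit the module, lick,
#' and receive drops dispensed by the virtual pump and valve; the load cell
#' streams noisy weight readings; the controller runs its session, dosing
#' and taring logic unmodified.  Ground truth (true weights, realised
#' intake) is recorded alongside the controller's own outputs.
#'
#' A master seed fans out into independent streams (behaviour, load cell,
#' pump, valve, RFID) so components can be varied without perturbing the
#' rest.  With all noise parameters zero the run is fully deterministic.
#'
#' @param config a [system_config()].
#' @param profiles named list of [mouse_profile()] (3-4 mice per cage is
#'   the intended regime).
#' @param days number of simulated days.
#' @param seed master seed.
#' @param mice optional named list of [sim_mouse()] matching `profiles`;
#'   defaults draw start weights uniformly from 20-30 g.
#' @param pump,valve,load_cell optional hardware models (defaults:
#'   [pump_model()], [valve_model()], [load_cell_model()]).
#' @param options a [sim_options()].
#' @param origin_date calendar date of day 0.
#' @return A list of class `colony_run`: `events`, `summary`, `estimates`,
#'   `schedules`, `truth` (`weights` and `intake` data frames),
#'   `controller`, hardware models, `config`, `profiles`, `seed`.
#' @export
run_colony <- function(config, profiles, days, seed,
                       mice = NULL, pump = NULL, valve = NULL,
                       load_cell = NULL, options = sim_options(),
                       origin_date = as.Date("2024-01-01")) {
  stopifnot(days >= 1, length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, "", "rfid_tag")
  tags <- names(profiles)
  streams <- fanout_streams(seed, c("behaviour", "loadcell", "pump", "valve",
                                    "rfid", "mice"))
  if (is.null(mice)) {
    starts <- stream_eval(streams$mice, function()
      stats::runif(length(tags), 20, 30))
    mice <- stats::setNames(
      lapply(seq_along(tags), function(i)
        sim_mouse(tags[i], start_weight_g = starts[i])), tags)
  }
  if (is.null(pump)) pump <- pump_model(steps_per_drop = config$pump_steps_per_drop,
                                        nominal_drop_ul = config$drop_volume_ul)
  if (is.null(valve)) valve <- valve_model(nominal_drop_ul = config$drop_volume_ul)
  if (is.null(load_cell)) load_cell <- load_cell_model()

  dispense <- function(type, t) {
    if (type == "drug") pump_dispense(pump, config$pump_steps_per_drop,
                                      streams$pump)
    else valve_dispense(valve, t, streams$valve)
  }
  ctrl <- controller_new(config, profiles, dispense = dispense,
                         on_tare = function() load_cell_tare(load_cell),
                         origin_date = origin_date,
                         keep_weight_buffers = options$keep_weight_buffers)

  # ground truth draws (fixed consumption order of the behaviour stream)
  true_w <- matrix(0, days, length(tags), dimnames = list(NULL, tags))
  target_ml <- matrix(0, days, length(tags), dimnames = list(NULL, tags))
  engage <- matrix(1, days, length(tags), dimnames = list(NULL, tags))
  for (tg in tags) {
    true_w[, tg] <- weight_trajectory(mice[[tg]], days, streams$behaviour)
    target_ml[, tg] <- draw_daily_intake(mice[[tg]], days, streams$behaviour)
    engage[, tg] <- draw_daily_engagement(mice[[tg]], days, streams$behaviour)
  }
  water_ml <- drug_ml <- matrix(0, days, length(tags),
                                dimnames = list(NULL, tags))

  visits <- do.call(rbind, lapply(tags, function(tg)
    do.call(rbind, lapply(seq_len(days) - 1L, function(d)
      generate_visits(mice[[tg]], d, config, streams$behaviour,
                      rate_multiplier = engage[d + 1L, tg])))))
  visits <- resolve_single_occupancy(
    visits, min_gap_s = 2,
    min_visit_s = min(vapply(mice, `[[`, 0, "min_visit_s")))
  visits <- visits[visits$end < days * 86400, , drop = FALSE]
  n_visits <- nrow(visits)

  hz <- config$sampling_rate_hz
  last_t <- 0
  consumed <- stats::setNames(rep(0, length(tags)), tags)
  consumed_day <- stats::setNames(rep(-1L, length(tags)), tags)
  col_of <- stats::setNames(seq_along(tags), tags)

  for (i in seq_len(n_visits)) {
    vs <- visits$start[i]; ve <- visits$end[i]; tg <- visits$tag[i]
    mo <- mice[[tg]]

    # slow zero drift between occupancies, reset by tares
    gap_h <- max(vs - last_t, 0) / 3600
    if (options$zero_drift_sd_g_per_h > 0 && gap_h > 0)
      load_cell$zero_offset_g <- load_cell$zero_offset_g +
        stream_eval(streams$loadcell, function()
          stats::rnorm(1, 0, options$zero_drift_sd_g_per_h * sqrt(gap_h)))
    last_t <- ve

    # routine valve maintenance
    if (vs - valve$last_recalibration_t >= options$valve_recal_days * 86400)
      recalibrate_valve(valve, vs)

    failed <- options$rfid_fail_prob > 0 &&
      stream_eval(streams$rfid, function() stats::runif(1)) < options$rfid_fail_prob
    if (failed) {
      on_tag_in_range(ctrl, vs, NA_character_)
      next    # mouse never identified: no session, no weights, no drops
    }
    on_tag_in_range(ctrl, vs, tg)

    # weight stream for the whole occupancy (buffered per dosing day)
    ts <- seq(vs, ve - 1e-9, by = 1 / hz)
    dsel <- pmin(day_of(ts, config), days - 1L) + 1L
    readings <- load_cell_read(true_w[cbind(dsel, col_of[[tg]])],
                               load_cell, streams$loadcell)
    append_weight_samples(ctrl, tg, ts, readings)

    # licks, paced by the circadian intake schedule
    d0 <- day_of(vs, config)
    if (consumed_day[[tg]] != d0) { consumed[[tg]] <- 0; consumed_day[[tg]] <- d0 }
    remaining <- target_ml[d0 + 1L, tg] *
      .pacing_frac(hour_of(ve, config), mo, config) - consumed[[tg]]
    if (day_of(ve, config) > d0) remaining <- target_ml[d0 + 1L, tg] - consumed[[tg]]
    licks <- generate_licks(vs, ve, remaining, mo, config, streams$behaviour)
    for (lt in licks) {
      ld <- day_of(lt, config)
      if (ld >= days) break
      if (ld != consumed_day[[tg]]) { consumed[[tg]] <- 0; consumed_day[[tg]] <- ld }
      allowed <- target_ml[ld + 1L, tg] * .pacing_frac(hour_of(lt, config), mo, config)
      if (consumed[[tg]] >= allowed) next   # sated for now; pause drinking
      res <- on_lick(ctrl, lt)
      if (res$delivered) {
        ml <- res$volume_ul / 1000
        consumed[[tg]] <- consumed[[tg]] + ml
        if (res$type == "drug") drug_ml[ld + 1L, tg] <- drug_ml[ld + 1L, tg] + ml
        else water_ml[ld + 1L, tg] <- water_ml[ld + 1L, tg] + ml
      }
    }

    on_tag_out_of_range(ctrl, ve)

    # tare check fires only if nobody re-enters before the deadline
    deadline <- ve + config$exit_wait_s
    next_start <- if (i < n_visits) visits$start[i + 1L] else Inf
    if (deadline < next_start && deadline < days * 86400) {
      tare_readings <- load_cell_read(rep(0, config$tare_sample_count),
                                      load_cell, streams$loadcell)
      on_exit_wait_elapsed(ctrl, deadline, tare_readings)
    }
  }

  out <- controller_finalize(ctrl, days * 86400)
  truth_w <- data.frame(tag = rep(tags, each = days),
                        day = rep(seq_len(days) - 1L, length(tags)),
                        date = rep(origin_date + seq_len(days) - 1L,
                                   length(tags)),
                        true_g = as.vector(true_w), stringsAsFactors = FALSE)
  truth_i <- data.frame(tag = rep(tags, each = days),
                        day = rep(seq_len(days) - 1L, length(tags)),
                        water_ml = as.vector(water_ml),
                        drug_ml = as.vector(drug_ml),
                        total_ml = as.vector(water_ml + drug_ml),
                        target_ml = as.vector(target_ml),
                        stringsAsFactors = FALSE)
  structure(list(events = out$events, estimates = out$estimates,
                 schedules = out$schedules,
                 summary = build_summary(out$events, out$estimates, config),
                 truth = list(weights = truth_w, intake = truth_i),
                 controller = ctrl, pump = pump, valve = valve,
                 load_cell = load_cell, config = config, profiles = profiles,
                 mice = mice, seed = seed),
            class = "colony_run")
}

#' @export
print.colony_run <- function(x, ...) {
  cat(sprintf("<colony_run> %d mice x %d days, %d events, seed %d\n",
              length(x$profiles), max(x$estimates$day) + 1L,
              nrow(x$events), x$seed))
  invisible(x)
}
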