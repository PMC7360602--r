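# Post-hoc analytics over event logs, weight estimates and (in simulation)
# ground truth: weighing accuracy, circadian drinking structure, dosing
# window, weight-consumption correlation, and the contrast with dosing via
# the cage's shared drinking water.  Every statistic here is a direct
# function of its input tables -- no hidden state -- and all tables are
# sorted internally, so results are invariant to row order.

#' Weighing accuracy report
#'
#' Pairs automated daily weight estimates with reference weights (manual
#' weighings, or ground truth in simulation) by mouse-day and reports the
#' absolute discrepancy, the discrepancy as % of bodyweight, the squared
#' Pearson correlation between the two series, and the mean day-to-day
#' % change of the reference weights (the natural yardstick for the
#' weighing error).
#'
#' @param estimates `data.frame` with columns `tag`, `day`, `grams`.
#' @param references `data.frame` with columns `tag`, `day`, `grams`.
#' @return A list of class `accuracy_report`: `pairs` (per mouse-day table),
#'   `mean_abs_g`, `mean_pct`, `r_squared` (NA with a flag when fewer than
#'   3 pairs), `mean_daily_change_pct`, `n`.
#' @export
weight_accuracy <- function(estimates, references) {
  est <- estimates[!is.na(estimates$grams), c("tag", "day", "grams")]
  names(est)[3] <- "est_g"
  ref <- references[, c("tag", "day", "grams")]
  names(ref)[3] <- "ref_g"
  pairs <- merge(est, ref, by = c("tag", "day"))
  pairs <- pairs[order(pairs$tag, pairs$day), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$abs_diff_g <- abs(pairs$est_g - pairs$ref_g)
  pairs$pct_diff <- 100 * pairs$abs_diff_g / pairs$ref_g
  n <- nrow(pairs)
  r2 <- if (n >= 3L && stats::sd(pairs$est_g) > 0 && stats::sd(pairs$ref_g) > 0)
    stats::cor(pairs$est_g, pairs$ref_g)^2 else NA_real_
  # day-to-day change of the reference series, per mouse, consecutive days
  ch <- unlist(lapply(split(pairs, pairs$tag), function(d) {
    d <- d[order(d$day), ]
    keep <- diff(d$day) == 1L
    (100 * abs(diff(d$ref_g)) / utils::head(d$ref_g, -1))[keep]
  }), use.names = FALSE)
  structure(list(pairs = pairs,
                 mean_abs_g = mean(pairs$abs_diff_g),
                 mean_pct = mean(pairs$pct_diff),
                 r_squared = r2,
                 r_squared_flagged = n < 3L,
                 mean_daily_change_pct = if (length(ch)) mean(ch) else NA_real_,
                 n = n),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0("<accuracy_report> n=%d  mean |err| %.3f g (%.2f%% of ",
                     "bodyweight)  R^2 %.3f  day-to-day change %.2f%%\n"),
              x$n, x$mean_abs_g, x$mean_pct, x$r_squared,
              x$mean_daily_change_pct))
  invisible(x)
}

#' Fraction of drops dispensed in the dark phase
#'
#' @param events event `data.frame` (columns `time`, `code`); only
#'   `DROP_WATER` / `DROP_DRUG` rows count.
#' @param config a [system_config()] (light schedule; dark is the half-open
#'   complement of `[lights_on, lights_off)`).
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the stream
#'   contains no drops.
#' @export
dark_phase_fraction <- function(events, config) {
  drops <- events[events$code %in% c("DROP_WATER", "DROP_DRUG"), , drop = FALSE]
  if (nrow(drops) == 0L) {
    warning("no drop events; dark-phase fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  h <- (as.numeric(drops$time) %% 86400) / 3600
  mean(is_dark_hour(h, config))
}

#' Per-hour drop histogram across the light cycle
#'
#' @inheritParams dark_phase_fraction
#' @return `data.frame` with columns `hour` (0-23), `water_drops`,
#'   `drug_drops`.
#' @export
hourly_drop_histogram <- function(events, config) {
  drops <- events[events$code %in% c("DROP_WATER", "DROP_DRUG"), , drop = FALSE]
  h <- floor((as.numeric(drops$time) %% 86400) / 3600)
  out <- data.frame(hour = 0:23)
  out$water_drops <- as.integer(tabulate(h[drops$code == "DROP_WATER"] + 1L, 24))
  out$drug_drops <- as.integer(tabulate(h[drops$code == "DROP_DRUG"] + 1L, 24))
  out
}

#' Daily dosing window per mouse
#'
#' Time from first to last drug drop within each mouse-day; 0 for a single
#' drop; days without drug drops are absent from the table.
#'
#' @param events event `data.frame` (columns `time`, `tag`, `code`).
#' @return `data.frame` with columns `tag`, `date`, `window_h`.
#' @export
dosing_window <- function(events) {
  drug <- events[events$code == "DROP_DRUG", , drop = FALSE]
  if (nrow(drug) == 0L)
    return(data.frame(tag = character(), date = as.Date(character()),
                      window_h = numeric(), stringsAsFactors = FALSE))
  drug$date <- as.Date(drug$time, tz = "UTC")
  agg <- stats::aggregate(as.numeric(drug$time),
                          by = list(tag = drug$tag, date = drug$date),
                          FUN = function(x) (max(x) - min(x)) / 3600)
  names(agg)[3] <- "window_h"
  agg <- agg[order(agg$tag, agg$date), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Squared correlation between daily bodyweight and daily intake
#'
#' @param weights `data.frame` with columns `tag`, `day`, `grams`.
#' @param intakes `data.frame` with columns `tag`, `day`, `ml`.
#' @return List: `r_squared`, `p_value`, `n`, `significant` (at 0.05),
#'   `flagged` (constant series or fewer than 3 pairs).
#' @export
weight_intake_correlation <- function(weights, intakes) {
  m <- merge(weights[, c("tag", "day", "grams")],
             intakes[, c("tag", "day", "ml")], by = c("tag", "day"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L || stats::sd(m$grams) == 0 || stats::sd(m$ml) == 0) {
    warning("correlation undefined: constant series or too few pairs",
            call. = FALSE)
    return(list(r_squared = NA_real_, p_value = NA_real_, n = n,
                significant = NA, flagged = TRUE))
  }
  ct <- stats::cor.test(m$grams, m$ml)
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = n,
       significant = ct$p.value < 0.05, flagged = FALSE)
}

#' Contrast closed-loop dosing with drug in the drinking water
#'
#' For the drinking-water strategy the realised dose is implicit:
#' `conc * intake / weight` for each mouse-day, with the concentration
#' calibrated (by default) so the cage-average realised dose equals the
#' target -- the strategy's own best case.  For the closed-loop strategy
#' the realised dose is the quantised quota for the day's true weight.
#' Heavier-than-average mice are systematically underdosed by the
#' drinking-water strategy unless intake is exactly proportional to
#' weight, and its day-to-day dose variability inherits the full intake
#' variability.
#'
#' @param intake `data.frame` with columns `tag`, `day`, `total_ml`
#'   (ground-truth daily consumption).
#' @param weights `data.frame` with columns `tag`, `day`, `true_g`.
#' @param config a [system_config()].
#' @param dose_mg_per_kg target dose.
#' @param conc_ug_per_ml drinking-water drug concentration; `NULL`
#'   calibrates it from the cage means.
#' @return A list of class `strategy_comparison`: `per_day` table with both
#'   realised doses, `per_mouse` table (mean and CV of each strategy per
#'   mouse), and `conc_ug_per_ml` used.
#' @export
compare_cage_water_strategy <- function(intake, weights, config,
                                        dose_mg_per_kg = 1,
                                        conc_ug_per_ml = NULL) {
  m <- merge(intake[, c("tag", "day", "total_ml")],
             weights[, c("tag", "day", "true_g")], by = c("tag", "day"))
  m <- m[order(m$tag, m$day), , drop = FALSE]
  rownames(m) <- NULL
  if (is.null(conc_ug_per_ml))
    conc_ug_per_ml <- dose_mg_per_kg * mean(m$true_g) / mean(m$total_ml)
  # ug consumed / g bodyweight == mg/kg; zero-intake days keep dose 0
  m$dose_water_mg_kg <- conc_ug_per_ml * m$total_ml / m$true_g
  m$dose_closed_mg_kg <- vapply(seq_len(nrow(m)), function(i)
    delivered_dose_mg_per_kg(
      required_drug_drops(m$true_g[i], dose_mg_per_kg, config),
      m$true_g[i], config), 0)
  cv <- function(x) if (mean(x) > 0) stats::sd(x) / mean(x) else NA_real_
  per_mouse <- do.call(rbind, lapply(split(m, m$tag), function(d)
    data.frame(tag = d$tag[1],
               mean_weight_g = mean(d$true_g),
               mean_dose_water = mean(d$dose_water_mg_kg),
               cv_dose_water = cv(d$dose_water_mg_kg),
               mean_dose_closed = mean(d$dose_closed_mg_kg),
               cv_dose_closed = cv(d$dose_closed_mg_kg),
               intake_cv = cv(d$total_ml),
               stringsAsFactors = FALSE)))
  rownames(per_mouse) <- NULL
  structure(list(per_day = m, per_mouse = per_mouse,
                 conc_ug_per_ml = conc_ug_per_ml,
                 dose_mg_per_kg = dose_mg_per_kg),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison> target %.2g mg/kg, water conc %.2f ug/mL\n",
              x$dose_mg_per_kg, x$conc_ug_per_ml))
  print(x$per_mouse, digits = 3)
  invisible(x)
}
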