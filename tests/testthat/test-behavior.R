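cfg <- system_config()

test_that("visits follow the light cycle and degenerate rates pin them to the dark phase", {
  m <- sim_mouse("A", visit_rate_dark = 2, visit_rate_light = 0)
  s <- rng_stream(5)
  v <- do.call(rbind, lapply(0:6, function(d) generate_visits(m, d, cfg, s)))
  expect_gt(nrow(v), 0)
  h <- hour_of(v$start, cfg)
  expect_true(all(is_dark_hour(h, cfg)))
})

test_that("the long-run dark-phase activity fraction converges to the configured bias", {
  # 10 mice x 56 days of generated visits; occupancy-weighted dark fraction
  s <- rng_stream(56)
  dark_s <- 0; total_s <- 0
  for (i in 1:10) {
    m <- sim_mouse(sprintf("M%02d", i))
    for (d in 0:55) {
      v <- generate_visits(m, d, cfg, s)
      if (!nrow(v)) next
      dur <- v$end - v$start
      dark_s <- dark_s + sum(dur[is_dark_hour(hour_of(v$start, cfg), cfg)])
      total_s <- total_s + sum(dur)
    }
  }
  expect_lte(abs(dark_s / total_s - 0.739), 0.05)
})

test_that("single-occupancy resolution leaves no overlapping visits", {
  s <- rng_stream(9)
  mice <- lapply(1:4, function(i) sim_mouse(sprintf("M%d", i)))
  v <- do.call(rbind, lapply(mice, function(m)
    do.call(rbind, lapply(0:2, function(d) generate_visits(m, d, cfg, s)))))
  r <- resolve_single_occupancy(v)
  expect_true(all(diff(r$start) >= 0))
  expect_true(all(utils::head(r$end, -1) <= utils::tail(r$start, -1)))
})

test_that("true weights grow ~5 g over 60 days with ~1-2% daily change", {
  m <- sim_mouse("A", start_weight_g = 25)
  expect_equal(weight_trajectory(sim_mouse("B", weight_fluct_sd_g = 0), 10),
               25 + (0:9) * 5 / 60)
  s <- rng_stream(60)
  gains <- vapply(1:30, function(i) {
    w <- weight_trajectory(m, 60, s)
    w[60] - w[1]
  }, 0)
  expect_gt(mean(gains), 4); expect_lt(mean(gains), 6)
  w <- weight_trajectory(m, 60, s)
  daily_pct <- 100 * abs(diff(w)) / utils::head(w, -1)
  expect_gt(mean(daily_pct), 0.5); expect_lt(mean(daily_pct), 2.5)
})

test_that("licking stops when satiety is exhausted and keeps the bout floor", {
  m <- sim_mouse("A")
  s <- rng_stream(3)
  expect_length(generate_licks(0, 100, 0, m, cfg, s), 0)
  licks <- generate_licks(1000, 1120, 5, m, cfg, s)
  expect_gt(length(licks), 10)
  expect_true(all(licks > 1000 & licks < 1120))
  expect_true(all(diff(licks) >= 0.2))
})

test_that("every dispensed microlitre is accounted for in the ground truth", {
  run <- shared_colony_run()
  ev <- run$events
  drops <- ev[ev$code %in% c("DROP_WATER", "DROP_DRUG"), ]
  vol_ml <- as.numeric(drops$payload) / 1000
  key <- paste(drops$tag, as.Date(drops$time, tz = "UTC"))
  tally <- tapply(vol_ml, key, sum)
  truth <- run$truth$intake
  tkey <- paste(truth$tag, as.Date("2024-01-01") + truth$day)
  got <- unname(tally[tkey]); got[is.na(got)] <- 0
  # payloads are printed at 3 dp (microlitre), so agreement is to rounding
  expect_lte(max(abs(got - truth$total_ml)), 1e-3)
  # conservation on the pump itself
  expect_equal(run$pump$dispensed_ul + run$pump$syringe_remaining_ul,
               run$pump$syringe_capacity_ul)
})

test_that("simulated consumption sits in the empirically observed band", {
  run <- run_colony(cfg, make_profiles(4, 4), days = 14, seed = 808)
  daily <- run$truth$intake$total_ml
  expect_gte(mean(daily), 1.4)
  expect_lte(mean(daily), 2.0)
  # day-to-day consumption variability is substantial (tens of percent)
  cvs <- vapply(split(run$truth$intake, run$truth$intake$tag),
                function(d) sd(d$total_ml) / mean(d$total_ml), 0)
  expect_gt(mean(cvs), 0.2)
})

test_that("treatment mice typically finish their quota before mid-day", {
  run <- shared_colony_run()
  ev <- run$events
  drug <- ev[ev$code == "DROP_DRUG", ]
  last_h <- tapply((as.numeric(drug$time) %% 86400) / 3600,
                   paste(drug$tag, as.Date(drug$time, tz = "UTC")), max)
  expect_lt(median(last_h), 12)
})

test_that("identical seeds reproduce a run byte for byte", {
  profs <- make_profiles(1, 0)
  quiet <- sim_options(rfid_fail_prob = 0, zero_drift_sd_g_per_h = 0)
  r1 <- run_colony(cfg, profs, days = 2, seed = 7, options = quiet)
  r2 <- run_colony(cfg, profs, days = 2, seed = 7, options = quiet)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$truth, r2$truth)
})

test_that("a noise-free virtual cage is deterministic end to end", {
  profs <- make_profiles(1, 0)
  mice <- list(T01 = sim_mouse("T01", weight_fluct_sd_g = 0, engagement_cv = 0,
                               intake_cv = 0))
  mk <- function(seed) run_colony(
    cfg, profs, days = 2, seed = seed, mice = mice,
    pump = pump_model(volume_error_sd_ul = 0),
    valve = valve_model(size_cv = 0, drift_rate = 0),
    load_cell = load_cell_model(noise_sd_g = 0, empty_noise_sd_g = 0,
                                transient_prob = 0),
    options = sim_options(rfid_fail_prob = 0, zero_drift_sd_g_per_h = 0))
  r1 <- mk(1)
  # drop payloads are exact nominal volumes: no stochastic actuator error
  drops <- r1$events[r1$events$code %in% c("DROP_WATER", "DROP_DRUG"), ]
  expect_true(all(drops$payload == "10.000"))
  # weight estimate equals the true weight to the rounding quantum
  m <- merge(r1$estimates, r1$truth$weights, by = c("tag", "day"))
  expect_true(all(abs(m$grams - round_half_away(m$true_g, 1)) < 1e-9))
})
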