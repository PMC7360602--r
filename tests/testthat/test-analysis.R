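cfg <- system_config()

test_that("weighing accuracy is exact on identical series and matches hand arithmetic", {
  est <- data.frame(tag = "a", day = 0:9, grams = seq(25, 27, length.out = 10))
  rep_ <- weight_accuracy(est, est)
  expect_equal(rep_$mean_abs_g, 0)
  expect_equal(rep_$r_squared, 1)
  # 4 mouse-days with known covariance structure, checked against an
  # explicit sum-based Pearson formula
  e <- data.frame(tag = "a", day = 1:4, grams = c(20.1, 22.3, 23.9, 26.2))
  r <- data.frame(tag = "a", day = 1:4, grams = c(20.0, 22.0, 24.0, 26.0))
  rep2 <- weight_accuracy(e, r)
  expect_equal(rep2$r_squared, oracle_pearson(e$grams, r$grams)^2)
  expect_equal(rep2$mean_abs_g, mean(c(0.1, 0.3, 0.1, 0.2)))
  expect_equal(rep2$mean_pct, mean(100 * c(0.1 / 20, 0.3 / 22, 0.1 / 24, 0.2 / 26)))
  expect_equal(rep2$mean_daily_change_pct,
               mean(100 * c(2 / 20, 2 / 22, 2 / 24)))
  # fewer than 3 pairs: correlation omitted and flagged
  rep3 <- weight_accuracy(e[1:2, ], r[1:2, ])
  expect_true(is.na(rep3$r_squared))
  expect_true(rep3$r_squared_flagged)
})

test_that("dark-phase fraction matches a per-event tally and handles edge cases", {
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  ev <- data.frame(time = t0 + c(2, 2.5, 3) * 3600, tag = "a",
                   code = "DROP_WATER", payload = "")
  expect_equal(dark_phase_fraction(ev, cfg), 1.0)   # 02:00-03:00, lights 06-18
  s <- rng_stream(12)
  hrs <- stream_eval(s, function() runif(5000, 0, 24))
  ev2 <- data.frame(time = t0 + sort(hrs) * 3600, tag = "a",
                    code = sample(c("DROP_WATER", "DROP_DRUG", "LICK"), 5000,
                                  replace = TRUE), payload = "")
  manual <- {
    n <- 0L; dark <- 0L
    for (i in seq_len(nrow(ev2))) {
      if (!ev2$code[i] %in% c("DROP_WATER", "DROP_DRUG")) next
      h <- (as.numeric(ev2$time[i]) %% 86400) / 3600
      n <- n + 1L
      if (h < 6 || h >= 18) dark <- dark + 1L
    }
    dark / n
  }
  expect_equal(dark_phase_fraction(ev2, cfg), manual)
  expect_warning(res <- dark_phase_fraction(ev2[ev2$code == "LICK", ], cfg),
                 "no drop events")
  expect_true(is.na(res))
  # a schedule with lights-on spanning midnight
  cfg_inv <- system_config(lights_on_hour = 20, lights_off_hour = 8)
  expect_equal(dark_phase_fraction(ev, cfg_inv), 0)  # 02:00 is lights-on there
})

test_that("the dosing window spans first to last drug drop within each day", {
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  ev <- data.frame(
    time = t0 + c(10 * 60, 10 * 3600 + 28 * 60, 86400 + 3600),
    tag = c("a", "a", "a"), code = "DROP_DRUG", payload = "")
  w <- dosing_window(ev)
  expect_equal(w$window_h, c(10.3, 0))    # 00:10 -> 10:28, then a single drop
  expect_equal(nrow(dosing_window(ev[0, ])), 0L)  # control mouse: absent
})

test_that("weight-intake correlation reports R^2 with sensible degenerate handling", {
  w <- data.frame(tag = "a", day = 1:10, grams = seq(20, 29))
  i <- data.frame(tag = "a", day = 1:10, ml = 2 * seq(20, 29))
  expect_equal(weight_intake_correlation(w, i)$r_squared, 1.0)
  s <- rng_stream(70)
  w2 <- data.frame(tag = rep(letters[1:10], each = 7), day = rep(1:7, 10),
                   grams = stream_eval(s, function() runif(70, 20, 30)))
  i2 <- data.frame(tag = w2$tag, day = w2$day,
                   ml = stream_eval(s, function() runif(70, 1, 2.5)))
  res <- weight_intake_correlation(w2, i2)
  expect_lt(res$r_squared, 0.1)          # independent series: near zero
  expect_equal(res$n, 70L)
  h <- data.frame(tag = "a", day = 1:5, grams = c(21, 23, 24, 27, 30))
  hi <- data.frame(tag = "a", day = 1:5, ml = c(1.5, 1.4, 1.9, 1.7, 2.2))
  expect_equal(weight_intake_correlation(h, hi)$r_squared,
               oracle_pearson(h$grams, hi$ml)^2)
  expect_warning(cons <- weight_intake_correlation(
    data.frame(tag = "a", day = 1:5, grams = rep(25, 5)), hi), "undefined")
  expect_true(cons$flagged)
})

test_that("the drinking-water strategy underdoses heavy mice and inherits intake variability", {
  # idealised assumption: intake proportional to weight -> everyone on target
  w <- data.frame(tag = rep(c("a", "b"), each = 5), day = rep(1:5, 2),
                  true_g = rep(c(20, 40), each = 5))
  i <- data.frame(tag = w$tag, day = w$day, total_ml = w$true_g * 0.08)
  cmpP <- compare_cage_water_strategy(i, w, cfg, dose_mg_per_kg = 1)
  expect_equal(cmpP$per_day$dose_water_mg_kg, rep(1, 10))
  # equal absolute intake: the 40 g mouse gets half the dose of the 20 g mouse
  i2 <- data.frame(tag = w$tag, day = w$day, total_ml = 1.6)
  cmp2 <- compare_cage_water_strategy(i2, w, cfg, dose_mg_per_kg = 1,
                                      conc_ug_per_ml = 18.75)
  pm <- cmp2$per_mouse
  expect_equal(pm$mean_dose_water[pm$tag == "b"],
               pm$mean_dose_water[pm$tag == "a"] / 2)
  # variable intake, stable weight: water-dose CV tracks intake CV while the
  # closed-loop dose stays pinned at the quantised target
  s <- rng_stream(21)
  mice <- lapply(1:6, function(k) sim_mouse(sprintf("m%d", k),
                                            start_weight_g = 20 + 2 * k))
  days <- 30
  wt <- do.call(rbind, lapply(mice, function(m)
    data.frame(tag = m$tag, day = 1:days,
               true_g = weight_trajectory(m, days, s))))
  it <- do.call(rbind, lapply(mice, function(m)
    data.frame(tag = m$tag, day = 1:days,
               total_ml = draw_daily_intake(m, days, s))))
  cmp3 <- compare_cage_water_strategy(it, wt, cfg, dose_mg_per_kg = 1)
  expect_true(all(cmp3$per_mouse$intake_cv >= 0.2))
  expect_true(all(cmp3$per_mouse$cv_dose_water >
                    cmp3$per_mouse$cv_dose_closed))
})

test_that("analysis results are invariant to event-stream row order", {
  run <- shared_colony_run()
  ev <- run$events
  s <- rng_stream(2)
  shuffled <- ev[stream_eval(s, function() sample(nrow(ev))), ]
  expect_equal(dark_phase_fraction(shuffled, cfg),
               dark_phase_fraction(ev, cfg))
  expect_equal(dosing_window(shuffled), dosing_window(ev))
  expect_equal(build_summary(shuffled, run$estimates, cfg), run$summary)
})
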