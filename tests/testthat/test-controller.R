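cfg <- system_config()

new_test_ctrl <- function(profiles = make_profiles(1, 0), config = cfg, ...) {
  controller_new(config, profiles, ...)
}

codes_of <- function(ctrl) controller_events(ctrl)$code

test_that("a readable registered tag opens a session; re-reads confirm silently", {
  ctrl <- new_test_ctrl()
  on_tag_in_range(ctrl, 10, "T01")
  expect_equal(ctrl$phase, "OCCUPIED")
  expect_equal(ctrl$current_tag, "T01")
  expect_equal(codes_of(ctrl), "ENTRY")
  on_tag_in_range(ctrl, 12, "T01")        # same mouse, momentary re-read
  expect_equal(codes_of(ctrl), "ENTRY")   # no second ENTRY
})

test_that("a different confirmed tag closes the old session implicitly", {
  ctrl <- new_test_ctrl(make_profiles(2, 0))
  on_tag_in_range(ctrl, 10, "T01")
  on_tag_in_range(ctrl, 20, "T02")
  ev <- controller_events(ctrl)
  expect_equal(ev$code, c("ENTRY", "EXIT", "ENTRY"))
  expect_equal(ev$tag, c("T01", "T01", "T02"))
  expect_equal(ctrl$current_tag, "T02")
})

test_that("unreadable and unregistered tags are logged and never dosed", {
  ctrl <- new_test_ctrl()
  on_tag_in_range(ctrl, 10, NA_character_)
  on_tag_in_range(ctrl, 11, "GHOST")
  expect_equal(codes_of(ctrl), c("RFID_FAIL", "RFID_FAIL"))
  expect_equal(ctrl$phase, "IDLE")
  res <- on_lick(ctrl, 12)
  expect_false(res$delivered)
  expect_equal(sum(codes_of(ctrl) %in% c("DROP_WATER", "DROP_DRUG")), 0L)
})

test_that("too many consecutive failed reads reboot without losing drop counts", {
  ctrl <- new_test_ctrl()
  # accrue some delivered drops first
  on_tag_in_range(ctrl, 5, "T01")
  on_lick(ctrl, 6)
  on_tag_out_of_range(ctrl, 7)
  st <- get("T01", envir = ctrl$mouse)
  drops_before <- st$water + st$drug
  expect_equal(drops_before, 1L)
  for (k in 1:10) on_tag_in_range(ctrl, 10 + k, NA_character_)
  ev <- controller_events(ctrl)
  expect_equal(sum(ev$code == "RFID_FAIL"), 10L)
  expect_equal(sum(ev$code == "REBOOT"), 1L)
  expect_equal(ctrl$phase, "IDLE")
  expect_equal(ctrl$failed_reads, 0L)
  st <- get("T01", envir = ctrl$mouse)
  expect_equal(st$water + st$drug, drops_before)  # persisted across reboot
  # a success in between resets the consecutive count
  ctrl2 <- new_test_ctrl()
  for (k in 1:9) on_tag_in_range(ctrl2, k, NA_character_)
  on_tag_in_range(ctrl2, 10, "T01")
  on_tag_in_range(ctrl2, 11, NA_character_)
  expect_equal(sum(codes_of(ctrl2) == "REBOOT"), 0L)
})

test_that("licks deliver exactly one drop plus image, then enforce the lockout", {
  ctrl <- new_test_ctrl()
  on_tag_in_range(ctrl, 100, "T01")
  res <- on_lick(ctrl, 101)
  expect_true(res$delivered)
  ev <- controller_events(ctrl)
  expect_equal(ev$code, c("ENTRY", "LICK", "DROP_WATER", "IMAGE"))
  expect_equal(ev$time[3], ev$time[4])     # image at the drop timestamp
  # licks inside the 10 s lockout log the lick but dispense nothing
  res2 <- on_lick(ctrl, 105)
  expect_false(res2$delivered)
  expect_equal(codes_of(ctrl)[5], "LICK")
  # at exactly lockout expiry delivery resumes
  res3 <- on_lick(ctrl, 111)
  expect_true(res3$delivered)
})

test_that("the lockout survives exit and re-entry", {
  ctrl <- new_test_ctrl()
  on_tag_in_range(ctrl, 100, "T01")
  on_lick(ctrl, 101)
  on_tag_out_of_range(ctrl, 102)
  on_tag_in_range(ctrl, 103, "T01")
  expect_false(on_lick(ctrl, 104)$delivered)
  expect_true(on_lick(ctrl, 111.5)$delivered)
})

test_that("exit starts the wait; re-entry cancels it; a stable empty cell tares", {
  tared <- FALSE
  ctrl <- new_test_ctrl(on_tare = function() tared <<- TRUE)
  on_tag_in_range(ctrl, 10, "T01")
  on_tag_out_of_range(ctrl, 50)
  expect_equal(ctrl$phase, "EXIT_WAIT")
  expect_equal(ctrl$exit_deadline, 80)
  # re-entry at +5 s: back to OCCUPIED, the pending check later is a no-op
  on_tag_in_range(ctrl, 55, "T01")
  expect_equal(ctrl$phase, "OCCUPIED")
  on_exit_wait_elapsed(ctrl, 80, rep(0, 20))
  expect_false(tared)
  # clean exit, stable readings: tare fires
  on_tag_out_of_range(ctrl, 100)
  on_exit_wait_elapsed(ctrl, 130, rep(0.02, 20))
  expect_true(tared)
  expect_equal(ctrl$phase, "IDLE")
  expect_equal(sum(codes_of(ctrl) == "TARE"), 1L)
  # unstable readings: no tare, but still back to IDLE
  tared <- FALSE
  on_tag_in_range(ctrl, 200, "T01")
  on_tag_out_of_range(ctrl, 210)
  on_exit_wait_elapsed(ctrl, 240, c(rep(0, 19), 0.15))
  expect_false(tared)
  expect_equal(ctrl$phase, "IDLE")
  # out-of-range while idle is ignored
  n_ev <- nrow(controller_events(ctrl))
  on_tag_out_of_range(ctrl, 300)
  expect_equal(nrow(controller_events(ctrl)), n_ev)
})

test_that("weight ticks buffer only while a session is open", {
  ctrl <- new_test_ctrl()
  on_weight_tick(ctrl, 1, 25.0)            # no session: dropped
  on_tag_in_range(ctrl, 10, "T01")
  for (k in 1:300) on_weight_tick(ctrl, 10 + k * 0.2, 25.0)
  on_tag_out_of_range(ctrl, 75)
  out <- controller_finalize(ctrl, 86400)
  expect_equal(out$estimates$n_readings, 300L)
  expect_equal(out$estimates$grams, 25.0)
})

test_that("day rollover computes the quota from the previous day's estimate", {
  ctrl <- new_test_ctrl()
  on_tag_in_range(ctrl, 1000, "T01")
  append_weight_samples(ctrl, "T01", 1000 + (1:500) * 0.2, rep(25.04, 500))
  on_tag_out_of_range(ctrl, 1101)
  # first event past midnight triggers the rollover
  on_tag_in_range(ctrl, 86400 + 60, "T01")
  sch <- do.call(rbind, lapply(ctrl$schedules, as.data.frame))
  expect_equal(sch$quota[sch$day == 0], 0L)          # baseline day
  expect_equal(sch$quota[sch$day == 1], 50L)         # from the 25.0 g estimate
  res <- on_lick(ctrl, 86400 + 61)
  expect_equal(res$type, "drug")
  st <- get("T01", envir = ctrl$mouse)
  expect_equal(st$drug, 1L)
})

test_that("a session spanning midnight splits its weight buffer at the boundary", {
  ctrl <- new_test_ctrl()
  t0 <- 86400 - 30
  on_tag_in_range(ctrl, t0, "T01")
  ts <- t0 + (0:299) * 0.2   # 60 s straddling midnight
  append_weight_samples(ctrl, "T01", ts, rep(25.0, 300))
  on_tag_out_of_range(ctrl, t0 + 60)
  out <- controller_finalize(ctrl, 2 * 86400)
  est <- out$estimates[order(out$estimates$day), ]
  expect_equal(est$n_readings, c(150L, 150L))
  expect_equal(est$grams, c(25.0, 25.0))
})

test_that("identical scripted inputs yield identical logs", {
  script <- function() {
    ctrl <- new_test_ctrl(make_profiles(2, 0))
    on_tag_in_range(ctrl, 10, "T01")
    for (t in seq(11, 120, by = 3)) on_lick(ctrl, t)
    on_tag_out_of_range(ctrl, 121)
    on_exit_wait_elapsed(ctrl, 151, rep(0, 20))
    on_tag_in_range(ctrl, 200, "T02")
    on_lick(ctrl, 201)
    on_tag_out_of_range(ctrl, 220)
    controller_finalize(ctrl, 86400)
  }
  expect_identical(script()$events, script()$events)
})
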