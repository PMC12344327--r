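params <- srt_params()

test_that("detect_entry finds the first in-AOI sample after onset (linear-scan oracle)", {
  onset <- 500
  stream <- make_trial_stream(jump_ms = onset + 308.3)
  aoi <- aoi_rect(10, 0, 2.85, 2.85, 0.9)
  got <- detect_entry(stream, aoi, onset, onset + 1500)
  # independent oracle: scan every sample in order
  idx <- which(stream$t_ms > onset &
                 !is.na(stream$x_deg) &
                 abs(stream$x_deg - 10) <= 3.75 & abs(stream$y_deg) <= 3.75)[1]
  expect_equal(got$entry_ms, stream$t_ms[idx])
  expect_false(got$preceded_by_missing)
  expect_equal(got$entry_ms - onset, 308.3, tolerance = 1000 / 120)
})

test_that("detect_entry returns none when the gaze never enters before the deadline", {
  stream <- make_stream(rep(0, 200))
  aoi <- aoi_rect(10, 0, 2.85, 2.85, 0.9)
  got <- detect_entry(stream, aoi, 100, 900)
  expect_true(is.na(got$entry_ms))
  expect_error(detect_entry(stream, aoi, 900, 100), "onset")
})

test_that("a clean trial is valid with SRT equal to the first post-jump sample", {
  ev <- make_trial_events(onset_new = 500)
  stream <- make_trial_stream(jump_ms = 800)
  rec <- extract_srt(stream, ev, params)
  expect_equal(rec$status, "valid")
  first_in <- stream$t_ms[which(stream$t_ms >= 800)[1]]
  expect_equal(rec$srt_ms, first_in - 500)
  expect_equal(rec$prev_target_distance_deg, 10)
})

test_that("pre-saccade wandering off the previous target rejects the start position", {
  ev <- make_trial_events(onset_new = 500)
  t <- seq(0, 2500, by = 1000 / 120)
  x <- ifelse(t >= 900, 10, 0)
  y <- rep(0, length(t))
  wander <- t >= 550 & t <= 750          # 3 degrees outside the expanded AOI
  y[wander] <- 6.76
  rec <- extract_srt(make_stream(x, y), ev, params)
  expect_equal(rec$status, "reject_start_position")
})

test_that("gaze off the previous target already at onset rejects the start position", {
  ev <- make_trial_events(onset_new = 500)
  t <- seq(0, 2500, by = 1000 / 120)
  x <- ifelse(t >= 800, 10, 5)           # 5 deg: outside expanded prev AOI
  rec <- extract_srt(make_stream(x), ev, params)
  expect_equal(rec$status, "reject_start_position")
})

test_that("anticipatory entries before 100 ms reject on the response window", {
  ev <- make_trial_events(onset_new = 500)
  stream <- make_trial_stream(jump_ms = 580)   # entry ~80 ms after onset
  rec <- extract_srt(stream, ev, params)
  expect_equal(rec$status, "reject_window")
  # late entries past 1000 ms reject on the window too
  stream_late <- make_trial_stream(jump_ms = 1650, dur_ms = 3000)
  rec_late <- extract_srt(stream_late, ev, params)
  expect_equal(rec_late$status, "reject_window")
})

test_that("a missing run longer than 100 ms before entry rejects the trial", {
  ev <- make_trial_events(onset_new = 500)
  t <- seq(0, 2500, by = 1000 / 120)
  x <- ifelse(t >= 800, 10, 0)
  x[t >= 650 & t <= 770] <- NA           # 120 ms blink, ends 30 ms pre-entry
  rec <- extract_srt(make_stream(x), ev, params)
  expect_equal(rec$status, "reject_gap_run")
})

test_that("an entry immediately after a short gap rejects on entry-after-missing", {
  ev <- make_trial_events(onset_new = 500)
  t <- seq(0, 2500, by = 1000 / 120)
  x <- ifelse(t >= 800, 10, 0)
  x[t >= 730 & t < 800] <- NA            # 70 ms gap touching the entry
  rec <- extract_srt(make_stream(x), ev, params)
  expect_equal(rec$status, "reject_entry_after_missing")
})

test_that("a trial with no entry is classified no_entry", {
  ev <- make_trial_events(onset_new = 500)
  stream <- make_stream(rep(0, 300))
  rec <- extract_srt(stream, ev, params)
  expect_equal(rec$status, "no_entry")
})

test_that("statuses are exhaustive and validation is idempotent", {
  s <- simulate_session(400, session_config(n_blocks = 4), seed = 11,
                        participant_id = "p", visit_label = "v")
  stream <- preprocess_recording(s$recording)
  rec1 <- extract_srt(stream, s$events, params, "p", "v")
  rec2 <- extract_srt(stream, s$events, params, "p", "v")
  expect_identical(rec1, rec2)
  expect_true(all(rec1$status %in% c("valid", "reject_start_position",
                                     "reject_gap_run",
                                     "reject_entry_after_missing",
                                     "reject_window", "no_entry")))
  expect_true(all(is.na(rec1$srt_ms) == (rec1$status != "valid")))
  v <- rec1$status == "valid"
  expect_true(all(rec1$srt_ms[v] >= 100 & rec1$srt_ms[v] <= 1000))
})

test_that("widening the AOI margin never loses valid trials", {
  s <- simulate_session(420, session_config(n_blocks = 4), seed = 21,
                        participant_id = "p", visit_label = "v")
  stream <- preprocess_recording(s$recording)
  n_valid <- vapply(c(0.3, 0.6, 0.9, 1.2), function(m) {
    sum(extract_srt(stream, s$events, srt_params(margin_deg = m),
                    "p", "v")$status == "valid")
  }, numeric(1))
  expect_true(all(diff(n_valid) >= 0))
})

test_that("log-scale outlier rule: degenerate, analytic and scale-invariance cases", {
  # identical SRTs: zero SD, nothing excluded
  rec <- make_records(list(p1 = rep(300, 12), p2 = rep(300, 12)))
  out <- exclude_outliers(rec)
  expect_true(all(out$status == "valid"))

  # log-normal draws: exclusion fraction near the 2.5-SD normal tail
  set.seed(101)
  n <- 1e5
  rec <- make_records(list(p = exp(rnorm(n, log(350), 0.3))))
  out <- exclude_outliers(rec)
  frac <- mean(out$status == "outlier")
  expect_equal(frac, 2 * (1 - pnorm(2.5)), tolerance = 0.1)

  # multiplying all SRTs by a constant changes no exclusion decision
  rec2 <- rec
  rec2$srt_ms <- rec2$srt_ms * 3.7
  out2 <- exclude_outliers(rec2)
  expect_identical(out$status, out2$status)

  # fewer than 2 valid records: warning, no-op
  one <- make_records(list(p = 250))
  expect_warning(res <- exclude_outliers(one), "fewer than 2")
  expect_equal(res$status, "valid")
})

test_that("retention rule counts only valid, non-outlier trials", {
  rec <- rbind(make_records(list(keep = rep(300, 10))),
               make_records(list(drop = rep(300, 9))),
               make_records(list(drop = rep(900, 2)), status = "outlier"))
  sel <- select_participants(rec, min_valid = 10)
  expect_true(sel$retained[sel$participant_id == "keep"])
  expect_false(sel$retained[sel$participant_id == "drop"])
  expect_equal(sel$n_valid[sel$participant_id == "drop"], 9)
})

test_that("cohort retention matches the binomial expectation", {
  set.seed(33)
  p_valid <- 0.6
  n_trials <- 20
  statuses <- lapply(1:300, function(i) {
    ifelse(runif(n_trials) < p_valid, "valid", "no_entry")
  })
  rec <- do.call(rbind, lapply(seq_along(statuses), function(i) {
    r <- make_records(stats::setNames(list(rep(300, n_trials)),
                                      sprintf("p%03d", i)))
    r$status <- statuses[[i]]
    r
  }))
  sel <- select_participants(rec, 10)
  expected <- 1 - pbinom(9, n_trials, p_valid)
  se <- sqrt(expected * (1 - expected) / 300)
  expect_lt(abs(mean(sel$retained) - expected), 3 * se)
})

test_that("monocular transitions at entry are flagged, none on clean binocular data", {
  ev <- make_trial_events(onset_new = 500)
  t <- seq(0, 2500, by = 1000 / 120)
  x <- ifelse(t >= 800, 10, 0)
  src <- ifelse(t >= 800, "left_only", "both_eyes")
  stream_mono <- make_stream(x, source = src)
  rec <- extract_srt(stream_mono, ev, params)
  expect_true(rec$monocular_entry_flag)
  # the standalone QC audit reproduces the flag set during extraction
  expect_identical(flag_monocular_transitions(stream_mono, rec)$monocular_entry_flag,
                   rec$monocular_entry_flag)

  rec2 <- extract_srt(make_stream(x), ev, params)
  expect_false(rec2$monocular_entry_flag)

  # clean synthetic session without dropouts: zero flags
  s <- simulate_session(400, session_config(n_blocks = 4,
                                            monocular_rate_per_min = 0),
                        seed = 3, participant_id = "p", visit_label = "v")
  stream <- preprocess_recording(s$recording)
  recs <- extract_srt(stream, s$events, params, "p", "v")
  expect_equal(sum(recs$monocular_entry_flag), 0)
})
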