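test_that("the generator is deterministic under a fixed seed", {
  cc <- cohort_config(n_households = 20)
  a <- simulate_cohort(cc, seed = 9)
  b <- simulate_cohort(cc, seed = 9)
  expect_identical(a, b)
  sc <- session_config(n_blocks = 2)
  s1 <- simulate_session(400, sc, seed = 4, participant_id = "p", visit_label = "v")
  s2 <- simulate_session(400, sc, seed = 4, participant_id = "p", visit_label = "v")
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_session(400, sc, seed = 5,
                                              participant_id = "p",
                                              visit_label = "v")))
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(cohort_config(prob_second_child = 2), "prob_second_child")
  expect_error(cohort_config(n_households = 1), "n_households")
  expect_error(session_config(spacing_range_deg = c(5, 14)), "spacing")
  expect_error(session_config(blink_rate_per_min = -1), "rate")
})

test_that("a zero assets effect leaves the index uncorrelated with latent SRT", {
  cc <- cohort_config(n_households = 300, assets_effect_ms_per_sd = 0)
  cohort <- simulate_cohort(cc, seed = 13)
  one_visit <- cohort$latent[cohort$latent$visit_label == "visit1", ]
  idx <- cohort$covariates$assets[match(one_visit$participant_id,
                                        cohort$covariates$participant_id)]
  expect_lt(abs(cor(idx, one_visit$latent_mean_srt_ms)), 0.15)
})

test_that("simulated survey marginals are in a plausible infant-cohort range", {
  cc <- cohort_config(n_households = 300)
  cohort <- simulate_cohort(cc, seed = 17)
  hh <- cohort$households
  n_owned <- rowSums(hh[grep("^asset_", names(hh))])
  expect_gt(mean(n_owned), 5)
  expect_lt(mean(n_owned), 25)
  cov <- cohort$covariates
  expect_true(all(cov$screen_time >= 0))
  expect_lt(mean(cov$screen_time), 6)
  expect_gt(mean(cov$haz), -3)
  expect_lt(mean(cov$haz), 1)
  v1 <- cov$visit_label == "visit1"
  expect_equal(mean(cov$age_months[v1]), 7.6, tolerance = 0.3)
})

test_that("noise-free sessions reproduce programmed latencies within one sample", {
  sc0 <- session_config(fixation_jitter_sd_deg = 0, blink_rate_per_min = 0,
                        spike_rate_per_min = 0, monocular_rate_per_min = 0,
                        prob_invalid_start = 0, n_blocks = 8)
  s <- simulate_session(400, sc0, seed = 19, participant_id = "p",
                        visit_label = "v")
  stream <- preprocess_recording(s$recording)
  rec <- extract_srt(stream, s$events, participant_id = "p", visit_label = "v")
  cmp <- merge(rec, s$truth, by = c("block_id", "trial_index"))
  expect_equal(mean(cmp$status == cmp$programmed_status), 1)
  ok <- cmp$status == "valid"
  err <- cmp$srt_ms[ok] - cmp$programmed_latency_ms[ok]
  expect_true(all(err >= 0 & err <= 1000 / 120 + 1e-9))
})

test_that("programmed latencies of 300 ms with zero spread give a 300 ms mean", {
  sc0 <- session_config(fixation_jitter_sd_deg = 0, blink_rate_per_min = 0,
                        spike_rate_per_min = 0, monocular_rate_per_min = 0,
                        prob_invalid_start = 0, n_blocks = 4)
  s <- simulate_session(300, sc0, trial_sigma = 0, seed = 23,
                        participant_id = "p", visit_label = "v")
  stream <- preprocess_recording(s$recording)
  rec <- extract_srt(stream, s$events, participant_id = "p", visit_label = "v")
  expect_true(all(rec$status == "valid"))
  expect_equal(mean(rec$srt_ms), 300, tolerance = 1000 / 120 / 300)
})

test_that("isolated spikes change no SRT after filtering", {
  sc0 <- session_config(fixation_jitter_sd_deg = 0.2, blink_rate_per_min = 0,
                        spike_rate_per_min = 0, monocular_rate_per_min = 0,
                        prob_invalid_start = 0, n_blocks = 4)
  s <- simulate_session(400, sc0, seed = 29, participant_id = "p",
                        visit_label = "v")
  clean <- extract_srt(preprocess_recording(s$recording), s$events,
                       participant_id = "p", visit_label = "v")
  # inject isolated 1-7-sample spikes away from each other
  spiked <- s$recording
  set.seed(31)
  n <- nrow(spiked$samples)
  starts <- seq(100, n - 10, by = 97)
  lens <- rep(1:7, length.out = length(starts))
  for (k in seq_along(starts)) {
    w <- starts[k]:(starts[k] + lens[k] - 1)
    spiked$samples$left_x_deg[w] <- spiked$samples$left_x_deg[w] + 10
    spiked$samples$right_x_deg[w] <- spiked$samples$right_x_deg[w] + 10
  }
  got <- extract_srt(preprocess_recording(spiked), s$events,
                     participant_id = "p", visit_label = "v")
  expect_identical(got$status, clean$status)
  expect_identical(got$srt_ms, clean$srt_ms)
})

test_that("a blink across the entry never yields a valid trial", {
  sc0 <- session_config(fixation_jitter_sd_deg = 0, blink_rate_per_min = 0,
                        spike_rate_per_min = 0, monocular_rate_per_min = 0,
                        prob_invalid_start = 0, n_blocks = 1)
  s <- simulate_session(400, sc0, seed = 37, participant_id = "p",
                        visit_label = "v")
  rec <- s$recording
  # cover the first trial's entry with a 150 ms blink
  entry <- s$truth$onset_ms[1] + s$truth$programmed_latency_ms[1]
  w <- rec$samples$t_ms >= entry - 120 & rec$samples$t_ms <= entry + 30
  rec$samples$left_valid[w] <- FALSE
  rec$samples$right_valid[w] <- FALSE
  rec <- gaze_recording(rec$samples, 120, participant_id = "p",
                        visit_label = "v")
  got <- extract_srt(preprocess_recording(rec), s$events,
                     participant_id = "p", visit_label = "v")
  expect_true(got$status[1] %in% c("reject_gap_run",
                                   "reject_entry_after_missing"))
})

test_that("programmed invalid-start trials are rejected on the start position", {
  sc <- session_config(fixation_jitter_sd_deg = 0.2, blink_rate_per_min = 0,
                       spike_rate_per_min = 0, monocular_rate_per_min = 0,
                       prob_invalid_start = 1, n_blocks = 2)
  s <- simulate_session(400, sc, seed = 41, participant_id = "p",
                        visit_label = "v")
  got <- extract_srt(preprocess_recording(s$recording), s$events,
                     participant_id = "p", visit_label = "v")
  expect_true(all(got$status == "reject_start_position"))
})

test_that("social videos reproduce the programmed SRT-latency coupling", {
  slope <- 0.62
  lat_srt <- seq(300, 500, length.out = 40)
  mean_lat <- vapply(seq_along(lat_srt), function(i) {
    sv <- simulate_social_video(lat_srt[i], seed = 400 + i,
                                social_srt_slope = slope,
                                participant_id = sprintf("p%02d", i))
    stream <- preprocess_recording(sv$recording)
    rec <- extract_social_latencies(stream, sv$cues,
                                    participant_id = sprintf("p%02d", i))
    mean(rec$latency_ms[rec$status == "valid"])
  }, numeric(1))
  fit <- lm(mean_lat ~ lat_srt)
  est <- coef(fit)[["lat_srt"]]
  se <- summary(fit)$coefficients["lat_srt", "Std. Error"]
  expect_lt(abs(est - slope), 3 * se)
})

test_that("a child already fixating the cued object is rejected", {
  sv <- simulate_social_video(400, seed = 43, participant_id = "p")
  cue <- sv$cues[1, ]
  t <- sv$recording$samples$t_ms
  n <- length(t)
  rec <- make_recording(lx = rep(cue$center_x_deg, n),
                        ly = rep(cue$center_y_deg, n),
                        rx = rep(cue$center_x_deg, n),
                        ry = rep(cue$center_y_deg, n))
  got <- extract_cue_latency(merge_eyes(rec), cue)
  expect_equal(got$status, "reject_start_position")
})
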