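#' Configuration of a synthetic longitudinal cohort
#'
#' Defines the study conditions the generator emulates: a cohort of
#' households with binary asset indicators driven by a latent wealth factor,
#' one or two children per household, three visits at infant/toddler ages,
#' and a child-level latency model in which the latent mean SRT of child i
#' at visit v is
#' `visit_mean_srt[v] + beta_assets * asset_index + beta_age * age_dev +
#'  beta_hsize * (household_size - mean) + beta_haz * HAZ + child intercept`,
#' with trial latencies drawn log-normally around that mean. Defaults mirror
#' the observed cohort: visit mean ages 7.6 / 16.4 / 36.8 months, visit mean
#' SRTs 395 / 385 / 337 ms, an asset gradient of -5.43 ms per SD of the
#' index, and a child intercept SD (47 ms) consistent with an odd-even
#' split-half reliability near 0.78 at 12 trials per half.
#'
#' @param n_households Number of households.
#' @param prob_second_child Probability a household contributes two children.
#' @param n_visits Number of visits (default 3).
#' @param visit_labels Visit labels.
#' @param visit_mean_ages_months,visit_age_sd_months Age distribution per visit.
#' @param visit_mean_srt_ms Marginal mean latent SRT per visit (ms).
#' @param n_assets Number of binary asset indicators (29 for the primary
#'   protocol, 10 for the replication protocol).
#' @param asset_loading Logit slope of each indicator on latent wealth.
#' @param assets_effect_ms_per_sd Programmed gradient: ms per SD of the
#'   asset index.
#' @param age_effect_ms_per_month Programmed age-deviation slope.
#' @param household_size_effect_ms Programmed household-size slope.
#' @param haz_effect_ms_per_unit Programmed direct HAZ slope on SRT.
#' @param child_intercept_sd_ms Between-child SD of the latency intercept.
#' @param trial_lognormal_sigma Log-scale SD of trial latencies.
#' @param trials_per_visit Programmed trials per session (trial-level path).
#' @param haz_wealth_slope,haz_resid_sd,haz_mean HAZ model: linear in the
#'   asset index plus noise.
#' @param screen_time_wealth_cor,screen_time_mean,screen_time_sd Screen-time
#'   model (h/day), correlated with the asset index.
#' @param milestone_wealth_slope,milestone_resid_sd Milestone-score model.
#' @param size_wealth_log_slope Household size vs wealth (log-Poisson slope),
#'   giving the weak positive size-assets association seen in survey data.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_households = 100,
                          prob_second_child = 0,
                          n_visits = 3,
                          visit_labels = paste0("visit", seq_len(n_visits)),
                          visit_mean_ages_months = c(7.6, 16.4, 36.8)[seq_len(n_visits)],
                          visit_age_sd_months = c(0.9, 0.5, 2.7)[seq_len(n_visits)],
                          visit_mean_srt_ms = c(395, 385, 337)[seq_len(n_visits)],
                          n_assets = 29,
                          asset_loading = 1.5,
                          assets_effect_ms_per_sd = -5.43,
                          age_effect_ms_per_month = -2.4,
                          household_size_effect_ms = 0,
                          haz_effect_ms_per_unit = 0,
                          child_intercept_sd_ms = 47,
                          trial_lognormal_sigma = 0.25,
                          trials_per_visit = 20,
                          haz_wealth_slope = 0.2,
                          haz_resid_sd = 1.1,
                          haz_mean = -0.5,
                          screen_time_wealth_cor = 0.29,
                          screen_time_mean = 2.7,
                          screen_time_sd = 1.8,
                          milestone_wealth_slope = 0.07,
                          milestone_resid_sd = 0.5,
                          size_wealth_log_slope = 0.15) {
  cfg <- as.list(environment())
  sds <- c(cfg$visit_age_sd_months, cfg$child_intercept_sd_ms,
           cfg$trial_lognormal_sigma, cfg$haz_resid_sd, cfg$screen_time_sd,
           cfg$milestone_resid_sd)
  bad <- character(0)
  if (any(sds < 0)) bad <- c(bad, "negative SD")
  if (cfg$prob_second_child < 0 || cfg$prob_second_child > 1) {
    bad <- c(bad, "prob_second_child outside [0,1]")
  }
  if (cfg$n_households < 2) bad <- c(bad, "n_households < 2")
  if (length(bad)) stop("invalid cohort_config: ", paste(bad, collapse = "; "))
  structure(cfg, class = "cohort_config")
}

#' Simulate a cohort: households, children, covariates, ground truth
#'
#' Draws households (latent wealth, binary asset indicators, household
#' size), children with visit ages, HAZ, screen time and milestone scores,
#' computes the asset index with [asset_index()], and programs each child's
#' latent mean SRT per visit according to the configured linear model. All
#' output is reproducible given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `households` (asset indicators and survey columns),
#'   `covariates` (one row per participant-visit: `assets`, `age_months`,
#'   `age_dev_months`, `household_size`, `haz`, `screen_time`, `milestone`,
#'   `family_id`), and `truth` (latent wealth, child intercepts, per
#'   participant-visit latent mean SRT, programmed effects).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  nh <- config$n_households
  wealth <- stats::rnorm(nh)
  alpha <- stats::qlogis(seq(0.15, 0.85, length.out = config$n_assets))
  assets <- matrix(0L, nh, config$n_assets,
                   dimnames = list(NULL, paste0("asset_", seq_len(config$n_assets))))
  for (j in seq_len(config$n_assets)) {
    assets[, j] <- stats::rbinom(nh, 1,
                                 stats::plogis(alpha[j] + config$asset_loading * wealth))
  }
  idx <- asset_index(assets)
  hsize <- 1L + stats::rpois(nh, exp(log(3.5) +
                                       config$size_wealth_log_slope * wealth))
  households <- data.frame(household_id = sprintf("hh%04d", seq_len(nh)),
                           stringsAsFactors = FALSE)
  households <- cbind(households, as.data.frame(assets))
  households$household_size <- hsize
  households$asset_index <- idx$score

  n_children <- 1L + stats::rbinom(nh, 1, config$prob_second_child)
  child_hh <- rep(seq_len(nh), n_children)
  nch <- length(child_hh)
  child_id <- sprintf("p%04d", seq_len(nch))
  b_child <- stats::rnorm(nch, 0, config$child_intercept_sd_ms)

  rows <- list()
  for (v in seq_len(config$n_visits)) {
    age <- stats::rnorm(nch, config$visit_mean_ages_months[v],
                        config$visit_age_sd_months[v])
    haz <- config$haz_mean + config$haz_wealth_slope * idx$score[child_hh] +
      stats::rnorm(nch, 0, config$haz_resid_sd)
    z <- stats::rnorm(nch)
    st <- config$screen_time_mean + config$screen_time_sd *
      (config$screen_time_wealth_cor * idx$score[child_hh] +
         sqrt(1 - config$screen_time_wealth_cor^2) * z)
    st <- pmax(0, st)
    milestone <- config$milestone_wealth_slope * idx$score[child_hh] +
      stats::rnorm(nch, 0, config$milestone_resid_sd)
    rows[[v]] <- data.frame(participant_id = child_id,
                            visit_label = config$visit_labels[v],
                            household_id = households$household_id[child_hh],
                            family_id = households$household_id[child_hh],
                            assets = idx$score[child_hh],
                            household_size = hsize[child_hh],
                            age_months = age,
                            haz = haz,
                            screen_time = st,
                            milestone = milestone,
                            stringsAsFactors = FALSE)
  }
  covariates <- do.call(rbind, rows)
  covariates$age_dev_months <- center_age(covariates$age_months,
                                          covariates$visit_label)
  v_idx <- match(covariates$visit_label, config$visit_labels)
  covariates$latent_mean_srt_ms <-
    config$visit_mean_srt_ms[v_idx] +
    config$assets_effect_ms_per_sd * covariates$assets +
    config$age_effect_ms_per_month * covariates$age_dev_months +
    config$household_size_effect_ms *
      (covariates$household_size - mean(hsize)) +
    config$haz_effect_ms_per_unit * covariates$haz +
    b_child[match(covariates$participant_id, child_id)]
  if (any(covariates$latent_mean_srt_ms <= 0)) {
    stop("programmed latent SRT non-positive; check effect sizes")
  }
  truth <- list(wealth = wealth,
                asset_index = idx$score,
                child_intercepts = stats::setNames(b_child, child_id),
                effects = config[c("assets_effect_ms_per_sd",
                                   "age_effect_ms_per_month",
                                   "household_size_effect_ms",
                                   "haz_effect_ms_per_unit",
                                   "visit_mean_srt_ms")])
  latent <- covariates[c("participant_id", "visit_label", "latent_mean_srt_ms")]
  covariates$latent_mean_srt_ms <- NULL
  list(households = households, covariates = covariates,
       latent = latent, truth = truth)
}

#' Programmed valid-trial latencies (trial-level generator path)
#'
#' Draws each participant-visit's programmed trial latencies directly
#' (log-normal around the latent mean, so the latent mean is the expected
#' trial latency), bypassing the raw gaze stream. This is the ground-truth
#' trial table against which the extraction pipeline is checked, and a fast
#' path for reliability and model studies that do not involve the
#' sample-level rules.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The same [cohort_config()].
#' @param seed Integer seed.
#' @return SRT record table (all rows status `"valid"`).
#' @export
simulate_trial_table <- function(cohort, config = cohort_config(), seed = 1L) {
  set.seed(seed)
  m <- config$trials_per_visit
  sigma <- config$trial_lognormal_sigma
  n <- nrow(cohort$latent)
  lat <- cohort$latent$latent_mean_srt_ms
  draws <- exp(stats::rnorm(n * m,
                            rep(log(lat) - sigma^2 / 2, each = m), sigma))
  data.frame(participant_id = rep(cohort$latent$participant_id, each = m),
             visit_label = rep(cohort$latent$visit_label, each = m),
             block_id = rep(((seq_len(m) - 1L) %/% 5L) + 1L, n),
             trial_index = rep(((seq_len(m) - 1L) %% 5L) + 1L, n),
             onset_ms = NA_real_,
             srt_ms = draws,
             status = "valid",
             prev_target_distance_deg = stats::runif(n * m, 9, 14),
             monocular_entry_flag = FALSE,
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic gaze session
#'
#' Emulates a 120 Hz remote-eye-tracker recording of the saccade task:
#' square targets (~5.7 degrees, half-size 2.85) presented 9-14 degrees
#' apart, an initial centre target, fixation jitter, blinks (missing runs
#' with a log-normal duration, median 150 ms, so both harmless sub-100 ms
#' and rejecting super-100 ms gaps occur), isolated 1-7-sample spikes,
#' monocular dropouts, and occasional pre-saccade wandering that violates
#' the start-position rule. The saccade itself relocates gaze
#' instantaneously; the next target appears after a dwell period on the
#' current target.
#'
#' @param sampling_rate_hz Sampling rate (default 120).
#' @param n_blocks,targets_per_block Session layout (primary protocol: 8 x 5;
#'   replication protocol: 6 x 11).
#' @param target_half_size_deg Target half-extent (2.85 for 5.7-degree
#'   targets, 2.5 for 5.0-degree).
#' @param spacing_range_deg Distance between consecutive targets (degrees).
#' @param screen_half_extent_deg Usable half-extents of the screen (x, y).
#' @param fixation_jitter_sd_deg Per-eye fixation jitter SD.
#' @param blink_rate_per_min,blink_median_ms,blink_sigma Blink process.
#' @param spike_rate_per_min,spike_max_samples,spike_amplitude_deg Spikes.
#' @param monocular_rate_per_min,monocular_median_ms One-eye dropout runs.
#' @param prob_invalid_start Probability a trial's pre-saccade gaze wanders
#'   off the previous target (programmed `reject_start_position`).
#' @param dwell_ms Dwell on the current target before the next onset.
#' @return A list of class `session_config`.
#' @export
session_config <- function(sampling_rate_hz = 120,
                           n_blocks = 8, targets_per_block = 5,
                           target_half_size_deg = 2.85,
                           spacing_range_deg = c(9, 14),
                           screen_half_extent_deg = c(13, 9),
                           fixation_jitter_sd_deg = 0.3,
                           blink_rate_per_min = 3,
                           blink_median_ms = 150,
                           blink_sigma = 0.5,
                           spike_rate_per_min = 2,
                           spike_max_samples = 7,
                           spike_amplitude_deg = 10,
                           monocular_rate_per_min = 2,
                           monocular_median_ms = 300,
                           prob_invalid_start = 0.05,
                           dwell_ms = 1000) {
  cfg <- as.list(environment())
  rates <- c(cfg$blink_rate_per_min, cfg$spike_rate_per_min,
             cfg$monocular_rate_per_min)
  bad <- character(0)
  if (any(rates < 0)) bad <- c(bad, "negative rate")
  if (cfg$spacing_range_deg[1] < 9 - 1e-9 ||
      cfg$spacing_range_deg[2] > 14 + 1e-9) {
    bad <- c(bad, "spacing outside [9, 14] degrees")
  }
  if (cfg$prob_invalid_start < 0 || cfg$prob_invalid_start > 1) {
    bad <- c(bad, "prob_invalid_start outside [0,1]")
  }
  if (length(bad)) stop("invalid session_config: ", paste(bad, collapse = "; "))
  structure(cfg, class = "session_config")
}

# random target sequence respecting the spacing range and screen bounds
draw_target_positions <- function(n, cfg) {
  pos <- matrix(0, n + 1, 2)  # row 1 = centre target
  for (i in seq_len(n)) {
    repeat {
      theta <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, cfg$spacing_range_deg[1], cfg$spacing_range_deg[2])
      cand <- pos[i, ] + d * c(cos(theta), sin(theta))
      if (abs(cand[1]) <= cfg$screen_half_extent_deg[1] &&
          abs(cand[2]) <= cfg$screen_half_extent_deg[2]) break
    }
    pos[i + 1, ] <- cand
  }
  pos
}

#' Simulate one gaze session of the saccade task
#'
#' Generates the target event table and the raw binocular gaze recording for
#' one participant-visit, with complete per-trial ground truth. Trial
#' latencies are drawn log-normally around `latent_mean_srt_ms` (so the
#' latent mean is the expected latency); gaze fixates the previous target
#' (with jitter) until onset + latency, relocates instantaneously into the
#' new target's area, and dwells there until the next onset. Blinks, spikes,
#' monocular dropouts and invalid-start wandering are injected per the
#' config.
#'
#' @param latent_mean_srt_ms The child's latent mean SRT at this visit (ms).
#' @param config A [session_config()].
#' @param trial_sigma Log-scale SD of trial latencies.
#' @param seed Integer seed.
#' @param participant_id,visit_label Identifiers.
#' @return List: `recording` ([gaze_recording()]), `events` (target table),
#'   `truth` (per-trial programmed latency and status).
#' @export
simulate_session <- function(latent_mean_srt_ms, config = session_config(),
                             trial_sigma = 0.25, seed = 1L,
                             participant_id = NA_character_,
                             visit_label = NA_character_) {
  set.seed(seed)
  cfg <- config
  n_tr <- cfg$n_blocks * cfg$targets_per_block
  pos <- draw_target_positions(n_tr, cfg)
  lat <- exp(stats::rnorm(n_tr, log(latent_mean_srt_ms) - trial_sigma^2 / 2,
                          trial_sigma))
  invalid_start <- stats::runif(n_tr) < cfg$prob_invalid_start

  onsets <- numeric(n_tr)
  entries <- numeric(n_tr)
  t_cursor <- cfg$dwell_ms          # centre target shown at t = 0
  for (i in seq_len(n_tr)) {
    onsets[i] <- t_cursor
    entries[i] <- onsets[i] + lat[i]
    t_cursor <- entries[i] + cfg$dwell_ms
  }
  total_ms <- t_cursor + 500
  period <- 1000 / cfg$sampling_rate_hz
  t <- seq(0, total_ms, by = period)
  n <- length(t)

  # gaze position: target index currently fixated (0 = centre target)
  fix_idx <- findInterval(t, entries)
  gx <- pos[fix_idx + 1, 1]
  gy <- pos[fix_idx + 1, 2]

  # invalid-start wandering: off-target point before and shortly after onset
  # (6 degrees from the previous target centre: even diagonally that clears
  # the margin-expanded AOI half-extent, and it is >= spacing + 6 from the
  # new target)
  for (i in which(invalid_start)) {
    dir <- pos[i, ] - pos[i + 1, ]
    dir <- dir / sqrt(sum(dir^2))
    q <- pos[i, ] + 6 * dir
    w <- t >= onsets[i] - 150 & t <= entries[i] - 100
    gx[w] <- q[1]
    gy[w] <- q[2]
  }

  jit <- function() stats::rnorm(n, 0, cfg$fixation_jitter_sd_deg)
  lx <- gx + jit(); ly <- gy + jit()
  rx <- gx + jit(); ry <- gy + jit()
  lv <- rep(TRUE, n); rv <- rep(TRUE, n)

  minutes <- total_ms / 60000
  # blinks: both eyes missing
  n_blink <- stats::rpois(1, cfg$blink_rate_per_min * minutes)
  if (n_blink) {
    starts <- stats::runif(n_blink, 0, total_ms)
    durs <- exp(stats::rnorm(n_blink, log(cfg$blink_median_ms), cfg$blink_sigma))
    for (b in seq_len(n_blink)) {
      w <- t >= starts[b] & t <= starts[b] + durs[b]
      lv[w] <- FALSE; rv[w] <- FALSE
    }
  }
  # monocular dropouts: one random eye missing
  n_mono <- stats::rpois(1, cfg$monocular_rate_per_min * minutes)
  if (n_mono) {
    starts <- stats::runif(n_mono, 0, total_ms)
    durs <- exp(stats::rnorm(n_mono, log(cfg$monocular_median_ms), 0.5))
    eye <- stats::runif(n_mono) < 0.5
    for (b in seq_len(n_mono)) {
      w <- t >= starts[b] & t <= starts[b] + durs[b]
      if (eye[b]) lv[w] <- FALSE else rv[w] <- FALSE
    }
  }
  # isolated spikes, 1-7 samples, same offset on both eyes
  n_spike <- stats::rpois(1, cfg$spike_rate_per_min * minutes)
  if (n_spike) {
    starts <- sample.int(n, n_spike, replace = TRUE)
    lens <- sample.int(cfg$spike_max_samples, n_spike, replace = TRUE)
    for (b in seq_len(n_spike)) {
      w <- starts[b]:min(n, starts[b] + lens[b] - 1)
      lx[w] <- lx[w] + cfg$spike_amplitude_deg
      rx[w] <- rx[w] + cfg$spike_amplitude_deg
    }
  }
  samples <- data.frame(t_ms = t,
                        left_x_deg = ifelse(lv, lx, NA_real_),
                        left_y_deg = ifelse(lv, ly, NA_real_),
                        right_x_deg = ifelse(rv, rx, NA_real_),
                        right_y_deg = ifelse(rv, ry, NA_real_),
                        left_valid = lv, right_valid = rv)
  rec <- gaze_recording(samples, cfg$sampling_rate_hz,
                        participant_id = participant_id,
                        visit_label = visit_label)
  events <- data.frame(
    onset_ms = c(0, onsets),
    center_x_deg = pos[, 1], center_y_deg = pos[, 2],
    half_w_deg = cfg$target_half_size_deg,
    half_h_deg = cfg$target_half_size_deg,
    block = c(0L, ((seq_len(n_tr) - 1L) %/% cfg$targets_per_block) + 1L),
    trial = c(0L, ((seq_len(n_tr) - 1L) %% cfg$targets_per_block) + 1L),
    kind = c("center", rep("target", n_tr)),
    stringsAsFactors = FALSE)
  events$is_first_center_target <- events$kind == "center"
  prog_status <- ifelse(invalid_start, "reject_start_position",
                        ifelse(lat < 100 | lat > 1000, "reject_window",
                               "valid"))
  truth <- data.frame(participant_id = participant_id,
                      visit_label = visit_label,
                      block_id = events$block[-1],
                      trial_index = events$trial[-1],
                      onset_ms = onsets,
                      programmed_latency_ms = lat,
                      programmed_status = prog_status,
                      stringsAsFactors = FALSE)
  list(recording = rec, events = events, truth = truth)
}

#' Simulate a social-video viewing session
#'
#' The child fixates the speaker's face between cues; after each cue the
#' gaze relocates to the cued object's AOI after a latency drawn log-normally
#' around the child's social latency mean, which is programmed as a linear
#' function of the child's latent SRT
#' (`social_base + social_srt_slope * (latent SRT - 370)`), then returns to
#' the speaker. Blinks are injected as in the saccade task.
#'
#' @param latent_mean_srt_ms Child's latent mean SRT (ms).
#' @param cue_protocol Cue table from [default_cue_protocol()].
#' @param config A [session_config()] (sampling, jitter and blink fields are
#'   used).
#' @param social_base,social_srt_slope Programmed latency model (defaults
#'   450 ms base, slope 0.62 per ms of SRT).
#' @param trial_sigma Log-scale SD of cue latencies.
#' @param seed Integer seed.
#' @param participant_id Identifier.
#' @return List: `recording`, `cues` (the protocol), `truth` (programmed
#'   per-cue latency).
#' @export
simulate_social_video <- function(latent_mean_srt_ms,
                                  cue_protocol = default_cue_protocol(),
                                  config = session_config(),
                                  social_base = 450, social_srt_slope = 0.62,
                                  trial_sigma = 0.25, seed = 1L,
                                  participant_id = NA_character_) {
  set.seed(seed)
  cfg <- config
  cues <- cue_protocol
  n_cue <- nrow(cues)
  mu <- social_base + social_srt_slope * (latent_mean_srt_ms - 370)
  lat <- exp(stats::rnorm(n_cue, log(mu) - trial_sigma^2 / 2, trial_sigma))
  total_ms <- max(cues$cue_onset_ms) + 2500
  period <- 1000 / cfg$sampling_rate_hz
  t <- seq(0, total_ms, by = period)
  n <- length(t)
  # speaker face AOI at the protocol's speaker position
  gx <- rep(cues$speaker_x_deg[1], n)
  gy <- rep(cues$speaker_y_deg[1], n)
  look_dur <- 700
  for (i in seq_len(n_cue)) {
    w <- t >= cues$cue_onset_ms[i] + lat[i] &
      t <= cues$cue_onset_ms[i] + lat[i] + look_dur
    gx[w] <- cues$center_x_deg[i]
    gy[w] <- cues$center_y_deg[i]
  }
  jit <- function() stats::rnorm(n, 0, cfg$fixation_jitter_sd_deg)
  lx <- gx + jit(); ly <- gy + jit()
  rx <- gx + jit(); ry <- gy + jit()
  lv <- rep(TRUE, n); rv <- rep(TRUE, n)
  n_blink <- stats::rpois(1, cfg$blink_rate_per_min * total_ms / 60000)
  if (n_blink) {
    starts <- stats::runif(n_blink, 0, total_ms)
    durs <- exp(stats::rnorm(n_blink, log(cfg$blink_median_ms), cfg$blink_sigma))
    for (b in seq_len(n_blink)) {
      w <- t >= starts[b] & t <= starts[b] + durs[b]
      lv[w] <- FALSE; rv[w] <- FALSE
    }
  }
  samples <- data.frame(t_ms = t,
                        left_x_deg = ifelse(lv, lx, NA_real_),
                        left_y_deg = ifelse(lv, ly, NA_real_),
                        right_x_deg = ifelse(rv, rx, NA_real_),
                        right_y_deg = ifelse(rv, ry, NA_real_),
                        left_valid = lv, right_valid = rv)
  rec <- gaze_recording(samples, cfg$sampling_rate_hz,
                        participant_id = participant_id,
                        visit_label = "social")
  truth <- data.frame(participant_id = participant_id,
                      video_id = cues$video_id, cue_index = cues$cue_index,
                      programmed_latency_ms = lat,
                      stringsAsFactors = FALSE)
  list(recording = rec, cues = cues, truth = truth)
}

#' Default social-cue protocol
#'
#' Three videos with 4-6 pointing cues each (14 cues total), a speaker face
#' region near the screen centre-top, and spatially separated object AOIs.
#'
#' @param cues_per_video Number of cues per video.
#' @return Cue table consumable by [extract_social_latencies()].
#' @export
default_cue_protocol <- function(cues_per_video = c(4, 5, 5)) {
  obj_x <- c(-9, -4.5, 0, 4.5, 9)
  rows <- list()
  for (v in seq_along(cues_per_video)) {
    k <- cues_per_video[v]
    rows[[v]] <- data.frame(
      video_id = sprintf("video%d", v),
      cue_index = seq_len(k),
      cue_onset_ms = 3000 + (seq_len(k) - 1) * 3000,
      center_x_deg = obj_x[((seq_len(k) - 1) %% 5) + 1],
      center_y_deg = -5,
      half_w_deg = 2, half_h_deg = 2,
      cue_kind = "point",
      speaker_x_deg = 0, speaker_y_deg = 4,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
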