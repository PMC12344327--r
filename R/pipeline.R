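#' Simulate a full study: cohort plus one gaze session per participant-visit
#'
#' @param cohort_cfg A [cohort_config()].
#' @param session_cfg A [session_config()].
#' @param seed Integer seed; per-session seeds are derived deterministically.
#' @return List: `cohort` (see [simulate_cohort()]) and `sessions` (one
#'   [simulate_session()] result per participant-visit, in `cohort$latent`
#'   row order).
#' @export
simulate_study <- function(cohort_cfg = cohort_config(),
                           session_cfg = session_config(), seed = 1L) {
  cohort <- simulate_cohort(cohort_cfg, seed = seed)
  lat <- cohort$latent
  # per-session seeds drawn from the base-seeded stream (stays within the
  # 32-bit integer range for any base seed)
  session_seeds <- sample.int(.Machine$integer.max, nrow(lat))
  sessions <- vector("list", nrow(lat))
  for (i in seq_len(nrow(lat))) {
    sessions[[i]] <- simulate_session(
      lat$latent_mean_srt_ms[i], session_cfg,
      trial_sigma = cohort_cfg$trial_lognormal_sigma,
      seed = session_seeds[i],
      participant_id = lat$participant_id[i],
      visit_label = lat$visit_label[i])
  }
  list(cohort = cohort, sessions = sessions)
}

#' Preprocess and extract SRTs for every session of a study
#'
#' Runs binocular merging, median filtering, entry detection and the
#' validity criteria on each simulated (or loaded) session, then applies the
#' log-scale outlier rule across the pooled records.
#'
#' @param sessions List of sessions (each with `recording` and `events`).
#' @param params An [srt_params()].
#' @param exclude Apply the log-scale outlier rule across the pooled records
#'   (default `TRUE`). Parameter-recovery studies on programmed-valid trials
#'   set this to `FALSE`, since trimming the clean log-normal tails shrinks
#'   between-child contrasts by construction.
#' @return SRT record table (with outlier statuses set when `exclude`).
#' @export
extract_study <- function(sessions, params = srt_params(), exclude = TRUE) {
  recs <- lapply(sessions, function(s) {
    stream <- preprocess_recording(s$recording, params$median_window_samples)
    extract_srt(stream, s$events, params,
                participant_id = s$recording$participant_id,
                visit_label = s$recording$visit_label)
  })
  records <- do.call(rbind, recs)
  if (!exclude) return(records)
  exclude_outliers(records, k_sd = params$outlier_k_sd, scope = "per_visit")
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' End-to-end orchestration: simulate the cohort and gaze sessions,
#' preprocess and extract SRTs, apply outlier exclusion and retention,
#' compute the quality/reliability summary, rebuild the asset index from the
#' simulated household survey, fit the gradient model (and, at the final
#' visit, extract social-cue latencies and gaze-probability curves), and
#' optionally write all stage outputs as flat CSV/JSON files.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param session_cfg A [session_config()].
#' @param params An [srt_params()].
#' @param seed Integer seed; the full run is deterministic given it.
#' @param out_dir Optional output directory for the report bundle.
#' @param social Include the social-video stage (default `TRUE`).
#' @return A report list: `records`, `retention`, `reliability`, `fit`,
#'   `social` (latencies and gaze-probability curves), `config`.
#' @export
run_pipeline <- function(cohort_cfg = cohort_config(),
                         session_cfg = session_config(),
                         params = srt_params(), seed = 1L, out_dir = NULL,
                         social = TRUE) {
  study <- simulate_study(cohort_cfg, session_cfg, seed = seed)
  records <- extract_study(study$sessions, params)

  retention <- retention_summary(records, min_valid = params$min_valid_trials,
                                 seed = seed)
  visits <- unique(records$visit_label)
  reliability <- lapply(visits, function(v) split_half(records, v))
  names(reliability) <- visits

  # rebuild the asset index from the simulated household survey so the
  # covariates stage is exercised end to end
  hh <- study$cohort$households
  asset_cols <- grep("^asset_", names(hh), value = TRUE)
  idx <- asset_index(hh[asset_cols])
  cov <- study$cohort$covariates
  cov$assets <- idx$score[match(cov$household_id, hh$household_id)]

  trials <- retained_valid_trials(records,
                                  min_valid = params$min_valid_trials)
  fit <- fit_gradient_model(trials, cov)

  social_out <- NULL
  if (social) {
    last_visit <- cohort_cfg$visit_labels[cohort_cfg$n_visits]
    lat <- study$cohort$latent
    lat <- lat[lat$visit_label == last_visit, , drop = FALSE]
    protocol <- default_cue_protocol()
    set.seed(seed + 1L)
    social_seeds <- sample.int(.Machine$integer.max, nrow(lat))
    lat_records <- vector("list", nrow(lat))
    streams <- vector("list", nrow(lat))
    for (i in seq_len(nrow(lat))) {
      sv <- simulate_social_video(lat$latent_mean_srt_ms[i],
                                  protocol, session_cfg,
                                  seed = social_seeds[i],
                                  participant_id = lat$participant_id[i])
      stream <- preprocess_recording(sv$recording,
                                     params$median_window_samples)
      streams[[i]] <- stream
      lat_records[[i]] <- extract_social_latencies(
        stream, sv$cues, params, participant_id = lat$participant_id[i])
    }
    lrec <- exclude_latency_outliers(do.call(rbind, lat_records))
    aois <- list(
      speaker = aoi_rect(protocol$speaker_x_deg[1], protocol$speaker_y_deg[1],
                         2, 2, 0),
      cued_object = aoi_rect(protocol$center_x_deg[1], protocol$center_y_deg[1],
                             protocol$half_w_deg[1], protocol$half_h_deg[1], 0))
    grid <- seq(protocol$cue_onset_ms[1] - 1000,
                protocol$cue_onset_ms[1] + 1500, by = 100)
    curves <- gaze_probability_curves(streams, aois, grid)
    social_out <- list(latencies = lrec,
                       retention = select_social_participants(lrec),
                       curves = curves)
  }

  report <- list(records = records, retention = retention,
                 reliability = reliability, fit = fit, social = social_out,
                 config = list(cohort = unclass(cohort_cfg),
                               session = unclass(session_cfg),
                               params = unclass(params), seed = seed))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# gazegrad pipeline, seed %d", report$config$seed)
  write_csv_prov <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(df, path, sep = ",",
                                        row.names = FALSE, append = TRUE))
    path
  }
  write_csv_prov(report$records, "srt_records.csv")
  write_csv_prov(report$retention, "retention_summary.csv")
  if (!is.null(report$social)) {
    write_csv_prov(report$social$latencies, "social_latencies.csv")
    write_csv_prov(report$social$curves, "gaze_probability.csv")
  }
  rel <- lapply(report$reliability, function(r)
    list(r = r$r, ci_low = r$ci_low, ci_high = r$ci_high, n = r$n))
  jsonlite::write_json(
    list(reliability = rel,
         coefficients = report$fit$coefficients,
         variance_components = as.list(report$fit$variance_components),
         n_obs = report$fit$n_obs,
         converged = report$fit$converged,
         singular = report$fit$singular,
         config = report$config),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(format_retention_markdown(report$retention),
             file.path(out_dir, "retention_summary.md"))
  invisible(out_dir)
}
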