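#' Extract the latency of an eye movement to a socially cued object
#'
#' Social-video data are segmented into 1-s windows starting at each spatial
#' cue (a pointing gesture or gaze shift towards a target object). A segment
#' is analyzed with the same validation core as the saccade task, with the
#' start-position rule replaced by an at-onset constraint: the trial is
#' rejected when the gaze is already inside the target object's AOI at cue
#' onset (otherwise the gaze may start anywhere in the scene). The remaining
#' rules -- missing-run limit, entry-after-missing, and the 100-1000 ms
#' response window -- are identical.
#'
#' @param stream A preprocessed `monocular_stream` aligned to video time.
#' @param cue One-row data frame (or list) with `cue_onset_ms`,
#'   `center_x_deg`, `center_y_deg`, `half_w_deg`, `half_h_deg`, plus
#'   identifiers `video_id` and `cue_index`.
#' @param params An [srt_params()] (shared constants).
#' @return One-row data frame: `latency_ms`, `status`, identifiers.
#' @export
extract_cue_latency <- function(stream, cue, params = srt_params()) {
  onset <- cue$cue_onset_ms
  aoi <- aoi_rect(cue$center_x_deg, cue$center_y_deg,
                  cue$half_w_deg, cue$half_h_deg, params$margin_deg)
  period <- 1000 / (attr(stream, "sampling_rate_hz") %||% 120)
  rec <- data.frame(video_id = cue$video_id, cue_index = cue$cue_index,
                    cue_onset_ms = onset, latency_ms = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  # criterion (1): gaze must be OUTSIDE the target AOI at cue onset
  pre <- which(stream$t_ms <= onset & !is.na(stream$x_deg))
  if (length(pre)) {
    i0 <- max(pre)
    if (isTRUE(aoi_contains(aoi, stream$x_deg[i0], stream$y_deg[i0]))) {
      rec$status <- "reject_start_position"
      return(rec)
    }
  }
  ent <- detect_entry(stream, aoi, onset, onset + params$search_max_ms)
  if (is.na(ent$entry_ms)) {
    rec$status <- "no_entry"
    return(rec)
  }
  seg <- which(stream$t_ms > onset & stream$t_ms < ent$entry_ms)
  runs <- missing_run_durations(stream$t_ms[seg], is.na(stream$x_deg[seg]),
                                period)
  if (any(runs > params$max_gap_ms)) {
    rec$status <- "reject_gap_run"
    return(rec)
  }
  if (isTRUE(ent$preceded_by_missing)) {
    rec$status <- "reject_entry_after_missing"
    return(rec)
  }
  lat <- ent$entry_ms - onset
  if (lat < params$window_min_ms || lat > params$window_max_ms) {
    rec$status <- "reject_window"
  } else {
    rec$latency_ms <- lat
    rec$status <- "valid"
  }
  rec
}

#' Extract all cue latencies for one participant's video session
#'
#' @param stream A preprocessed `monocular_stream` aligned to video time.
#' @param cues Cue table: one row per cue with the columns documented in
#'   [extract_cue_latency()].
#' @param params An [srt_params()].
#' @param participant_id Identifier stamped on every record.
#' @return Data frame of latency records.
#' @export
extract_social_latencies <- function(stream, cues, params = srt_params(),
                                     participant_id = NA_character_) {
  out <- lapply(seq_len(nrow(cues)), function(i)
    extract_cue_latency(stream, cues[i, ], params))
  res <- do.call(rbind, out)
  cbind(data.frame(participant_id = participant_id,
                   stringsAsFactors = FALSE), res)
}

#' Log-scale outlier exclusion for cue latencies
#'
#' Identical contract to [exclude_outliers()], operating on `latency_ms`.
#'
#' @inheritParams exclude_outliers
#' @export
exclude_latency_outliers <- function(records, k_sd = 2.5,
                                     scope = c("per_visit", "pooled")) {
  scope <- match.arg(scope)
  if (is.null(records$visit_label)) scope <- "pooled"
  exclude_outliers(records, k_sd, scope, value_col = "latency_ms")
}

#' Retention rule for the social-cue task
#'
#' Participants with at least `min_valid` valid cue latencies (after outlier
#' exclusion) are retained.
#'
#' @param records Latency record table.
#' @param min_valid Default 3.
#' @return Data frame: `participant_id`, `n_valid`, `retained`.
#' @export
select_social_participants <- function(records, min_valid = 3) {
  agg <- stats::aggregate(list(n_valid = records$status == "valid"),
                          by = list(participant_id = records$participant_id),
                          FUN = sum)
  agg$retained <- agg$n_valid >= min_valid
  agg
}

#' Probability-of-gaze curves by AOI over video time
#'
#' For each grid time and AOI, the proportion of participants whose gaze is
#' inside the AOI among participants with non-missing gaze at that time,
#' with a Wilson 95% binomial interval. An `elsewhere` row completes the
#' partition (gaze on screen but in none of the listed AOIs), so across
#' mutually exclusive AOIs plus `elsewhere` the probabilities sum to one.
#'
#' @param streams List of `monocular_stream`s aligned to video time (one per
#'   participant).
#' @param aois Named list of [aoi_rect()]s (mutually exclusive regions).
#' @param time_grid Vector of video times (ms) at which to evaluate.
#' @return Data frame: `t_ms`, `aoi`, `p`, `ci_low`, `ci_high`, `n`.
#' @export
gaze_probability_curves <- function(streams, aois, time_grid) {
  if (!length(time_grid)) stop("time_grid must be non-empty")
  if (!length(streams)) stop("at least one recording is required")
  # sample each stream at the grid (nearest preceding sample within a period)
  pos <- lapply(streams, function(s) {
    i <- findInterval(time_grid, s$t_ms)
    i[i == 0] <- NA
    list(x = s$x_deg[i], y = s$y_deg[i])
  })
  out <- list()
  aoi_names <- names(aois)
  for (k in seq_along(time_grid)) {
    xs <- vapply(pos, function(p) p$x[k], numeric(1))
    ys <- vapply(pos, function(p) p$y[k], numeric(1))
    ok <- !is.na(xs)
    n <- sum(ok)
    inside_any <- rep(FALSE, length(xs))
    for (a in aoi_names) {
      inside <- ok & aoi_contains(aois[[a]], xs, ys)
      inside[is.na(inside)] <- FALSE
      inside_any <- inside_any | inside
      ci <- wilson_ci(sum(inside), n)
      out[[length(out) + 1L]] <- data.frame(
        t_ms = time_grid[k], aoi = a, p = if (n) sum(inside) / n else NA_real_,
        ci_low = ci[1], ci_high = ci[2], n = n, stringsAsFactors = FALSE)
    }
    elsewhere <- ok & !inside_any
    ci <- wilson_ci(sum(elsewhere), n)
    out[[length(out) + 1L]] <- data.frame(
      t_ms = time_grid[k], aoi = "elsewhere",
      p = if (n) sum(elsewhere) / n else NA_real_,
      ci_low = ci[1], ci_high = ci[2], n = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}
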