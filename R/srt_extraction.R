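#' Parameters for latency extraction
#'
#' Bundles the tunable constants of the validity rules. Defaults follow the
#' standard protocol: a 0.9 degree AOI margin for calibration error, an
#' expected response window of 100-1000 ms after stimulus onset, a maximum
#' tolerated run of consecutive missing samples of 100 ms, and a 50 ms
#' transition exemption immediately before AOI entry during which the gaze
#' may already have left the previous target's area.
#'
#' @param margin_deg AOI calibration margin in degrees (default 0.9).
#' @param window_min_ms,window_max_ms Accepted latency window (100, 1000).
#' @param max_gap_ms Longest tolerated missing run between onset and entry.
#' @param transition_ms Pre-entry exemption from the start-position rule.
#' @param search_max_ms How far past onset to scan for an AOI entry; entries
#'   later than `window_max_ms` are classified `reject_window` rather than
#'   `no_entry`.
#' @param median_window_samples Median filter window used upstream.
#' @param outlier_k_sd Log-scale outlier cut in SD units (default 2.5).
#' @param min_valid_trials Retention threshold per participant-visit (10).
#' @return A list of class `srt_params`.
#' @export
srt_params <- function(margin_deg = 0.9, window_min_ms = 100,
                       window_max_ms = 1000, max_gap_ms = 100,
                       transition_ms = 50, search_max_ms = 1500,
                       median_window_samples = 15, outlier_k_sd = 2.5,
                       min_valid_trials = 10) {
  structure(list(margin_deg = margin_deg, window_min_ms = window_min_ms,
                 window_max_ms = window_max_ms, max_gap_ms = max_gap_ms,
                 transition_ms = transition_ms, search_max_ms = search_max_ms,
                 median_window_samples = median_window_samples,
                 outlier_k_sd = outlier_k_sd,
                 min_valid_trials = min_valid_trials),
            class = "srt_params")
}

srt_statuses <- c("valid", "reject_start_position", "reject_gap_run",
                  "reject_entry_after_missing", "reject_window",
                  "no_entry", "outlier")

#' Detect the first gaze entry into an AOI
#'
#' Scans the stream for the first non-missing sample strictly after
#' `onset_ms` and no later than `deadline_ms` that falls inside the
#' margin-expanded AOI (closed rectangle: boundary points are inside).
#'
#' @param stream A `monocular_stream`.
#' @param aoi An [aoi_rect()] (margin already included in the object).
#' @param onset_ms Stimulus onset time.
#' @param deadline_ms Last time considered.
#' @return A list: `entry_ms` (`NA` if no entry), `entry_index` (row in the
#'   stream), and `preceded_by_missing` (`TRUE` when the sample immediately
#'   before the entry sample is missing).
#' @export
detect_entry <- function(stream, aoi, onset_ms, deadline_ms) {
  if (onset_ms >= deadline_ms) stop("onset_ms must precede deadline_ms")
  idx <- which(stream$t_ms > onset_ms & stream$t_ms <= deadline_ms)
  if (length(idx)) {
    inside <- aoi_contains(aoi, stream$x_deg[idx], stream$y_deg[idx])
    hit <- idx[which(!is.na(inside) & inside)[1]]
  } else {
    hit <- NA_integer_
  }
  if (is.na(hit)) {
    return(list(entry_ms = NA_real_, entry_index = NA_integer_,
                preceded_by_missing = NA))
  }
  prev_missing <- hit > 1 && is.na(stream$x_deg[hit - 1])
  list(entry_ms = stream$t_ms[hit], entry_index = hit,
       preceded_by_missing = isTRUE(prev_missing))
}

# duration of every run of consecutive missing samples among stream rows idx
# (a run's duration is last - first missing timestamp + one sample period)
missing_run_durations <- function(t_ms, is_missing, period_ms) {
  if (!length(is_missing) || !any(is_missing)) return(numeric(0))
  r <- rle(is_missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  t_ms[ends[keep]] - t_ms[starts[keep]] + period_ms
}

#' Validate a single saccade trial and extract its SRT
#'
#' Applies the four validity criteria in order, stopping at the first
#' failure:
#' (1) start position: the gaze must be inside the margin-expanded previous
#' target AOI at onset, and every non-missing sample between onset and AOI
#' entry must remain inside it, except samples within the trailing
#' `transition_ms` before entry;
#' (2) no run of consecutive missing samples exceeding `max_gap_ms` between
#' onset and entry;
#' (3) the entry sample must not be preceded by a missing sample;
#' (4) the SRT must fall in the `[window_min_ms, window_max_ms]` window.
#' All criteria passed gives status `valid` with `srt_ms = entry - onset`.
#'
#' @param stream A preprocessed `monocular_stream`.
#' @param prev_aoi [aoi_rect()] of the previous target (the initial centre
#'   target for the first analyzable trial).
#' @param target One-row data frame (or list) with `onset_ms`,
#'   `center_x_deg`, `center_y_deg`, `half_w_deg`, `half_h_deg`, `block`,
#'   `trial`.
#' @param params An [srt_params()].
#' @return One-row data frame with the trial's `srt_ms`, `status`,
#'   `monocular_entry_flag` and bookkeeping columns.
#' @export
validate_trial <- function(stream, prev_aoi, target, params = srt_params()) {
  period <- 1000 / (attr(stream, "sampling_rate_hz") %||% 120)
  core <- validate_trial_core(stream$t_ms, stream$x_deg, stream$y_deg,
                              stream$source, period, prev_aoi, target, params)
  data.frame(block_id = target$block, trial_index = target$trial,
             onset_ms = target$onset_ms, srt_ms = core$srt_ms,
             status = core$status,
             prev_target_distance_deg = sqrt(
               (target$center_x_deg - prev_aoi$center_x_deg)^2 +
               (target$center_y_deg - prev_aoi$center_y_deg)^2),
             monocular_entry_flag = core$monocular_entry_flag,
             stringsAsFactors = FALSE)
}

# validation core shared by the saccade and social-cue paths; operates on
# raw vectors to keep the per-trial cost low
validate_trial_core <- function(t, x, y, src, period, prev_aoi, target,
                                params) {
  onset <- target$onset_ms
  res <- list(srt_ms = NA_real_, status = NA_character_,
              monocular_entry_flag = FALSE)
  hw_new <- target$half_w_deg + params$margin_deg
  hh_new <- target$half_h_deg + params$margin_deg
  hw_prev <- prev_aoi$half_width_deg + params$margin_deg
  hh_prev <- prev_aoi$half_height_deg + params$margin_deg

  # index range scanned for this trial
  i0 <- findInterval(onset, t) + 1L           # first sample with t > onset
  i1 <- findInterval(onset + params$search_max_ms, t)  # last with t <= deadline
  ent <- NA_integer_
  if (i1 >= i0) {
    w <- i0:i1
    inside_new <- abs(x[w] - target$center_x_deg) <= hw_new &
      abs(y[w] - target$center_y_deg) <= hh_new
    hit <- which(!is.na(inside_new) & inside_new)[1]
    if (!is.na(hit)) ent <- w[hit]
  }

  # criterion (1a): gaze inside previous AOI at onset (last known position)
  pre <- i0 - 1L
  while (pre >= 1L && is.na(x[pre])) pre <- pre - 1L
  at_onset_ok <- pre >= 1L &&
    abs(x[pre] - prev_aoi$center_x_deg) <= hw_prev &&
    abs(y[pre] - prev_aoi$center_y_deg) <= hh_prev
  if (!at_onset_ok) {
    res$status <- "reject_start_position"
    return(res)
  }
  if (is.na(ent)) {
    res$status <- "no_entry"
    return(res)
  }
  entry_ms <- t[ent]
  # criterion (1b): gaze stays in the previous AOI up to its final exit,
  # i.e. every non-missing pre-entry sample earlier than the trailing
  # transition window must be inside prev_aoi
  j1 <- findInterval(entry_ms - params$transition_ms, t)
  if (j1 >= i0) {
    w <- i0:j1
    off <- !is.na(x[w]) &
      (abs(x[w] - prev_aoi$center_x_deg) > hw_prev |
         abs(y[w] - prev_aoi$center_y_deg) > hh_prev)
    if (any(off)) {
      res$status <- "reject_start_position"
      return(res)
    }
  }
  # criterion (2): missing runs between onset and entry
  if (ent > i0) {
    w <- i0:(ent - 1L)
    runs <- missing_run_durations(t[w], is.na(x[w]), period)
    if (any(runs > params$max_gap_ms)) {
      res$status <- "reject_gap_run"
      return(res)
    }
  }
  # criterion (3): entry preceded by a missing sample
  if (ent > 1L && is.na(x[ent - 1L])) {
    res$status <- "reject_entry_after_missing"
    return(res)
  }
  # criterion (4): expected response window
  srt <- entry_ms - onset
  if (srt < params$window_min_ms || srt > params$window_max_ms) {
    res$status <- "reject_window"
    return(res)
  }
  res$srt_ms <- srt
  res$status <- "valid"
  if (!is.null(src) && ent > 1L) {
    s0 <- src[ent - 1L]
    s1 <- src[ent]
    res$monocular_entry_flag <- s0 != "missing" && s1 != "missing" && s0 != s1
  }
  res
}

#' Extract saccadic reaction times from a preprocessed session
#'
#' Walks the saccade-target sequence of one session, validating each
#' analyzable trial against the previous target's AOI (the initial centre
#' target serves as the previous AOI for the first analyzable trial) and
#' extracting its SRT. The first centre target itself is never analyzed.
#'
#' @param stream A preprocessed `monocular_stream` (see
#'   [preprocess_recording()]).
#' @param events Event table as returned by [read_events()] (saccade targets;
#'   rows of kind `"cue"` are ignored).
#' @param params An [srt_params()].
#' @param participant_id,visit_label Identifiers stamped on every record.
#' @return A data frame with one `SRT` record per analyzable trial.
#' @export
extract_srt <- function(stream, events, params = srt_params(),
                        participant_id = NA_character_,
                        visit_label = NA_character_) {
  targets <- events[events$kind != "cue", , drop = FALSE]
  targets <- targets[order(targets$onset_ms), , drop = FALSE]
  n <- nrow(targets)
  if (n < 2) {
    return(empty_srt_table(participant_id, visit_label))
  }
  t <- stream$t_ms
  x <- stream$x_deg
  y <- stream$y_deg
  src <- stream$source
  period <- 1000 / (attr(stream, "sampling_rate_hz") %||% 120)
  m <- n - 1L
  srt <- numeric(m)
  status <- character(m)
  flag <- logical(m)
  dist <- numeric(m)
  for (i in 2:n) {
    prev <- list(center_x_deg = targets$center_x_deg[i - 1],
                 center_y_deg = targets$center_y_deg[i - 1],
                 half_width_deg = targets$half_w_deg[i - 1],
                 half_height_deg = targets$half_h_deg[i - 1])
    tgt <- list(onset_ms = targets$onset_ms[i],
                center_x_deg = targets$center_x_deg[i],
                center_y_deg = targets$center_y_deg[i],
                half_w_deg = targets$half_w_deg[i],
                half_h_deg = targets$half_h_deg[i])
    core <- validate_trial_core(t, x, y, src, period, prev, tgt, params)
    srt[i - 1] <- core$srt_ms
    status[i - 1] <- core$status
    flag[i - 1] <- core$monocular_entry_flag
    dist[i - 1] <- sqrt((tgt$center_x_deg - prev$center_x_deg)^2 +
                          (tgt$center_y_deg - prev$center_y_deg)^2)
  }
  data.frame(participant_id = participant_id, visit_label = visit_label,
             block_id = targets$block[-1], trial_index = targets$trial[-1],
             onset_ms = targets$onset_ms[-1], srt_ms = srt, status = status,
             prev_target_distance_deg = dist, monocular_entry_flag = flag,
             stringsAsFactors = FALSE)
}

empty_srt_table <- function(participant_id = character(0),
                            visit_label = character(0)) {
  data.frame(participant_id = character(0), visit_label = character(0),
             block_id = integer(0), trial_index = integer(0),
             onset_ms = numeric(0), srt_ms = numeric(0),
             status = character(0), prev_target_distance_deg = numeric(0),
             monocular_entry_flag = logical(0), stringsAsFactors = FALSE)
}

#' Exclude latency outliers on the log scale
#'
#' Within each scope (by default each visit's dataset), computes the mean and
#' SD of `log(latency)` over currently valid records and marks any record
#' whose log latency lies more than `k_sd` SDs from that grand mean as an
#' `outlier` (two-sided). The rule runs once; it is not iterated.
#'
#' @param records SRT or cue-latency record table with `srt_ms` (or
#'   `latency_ms`) and `status` columns.
#' @param k_sd Cut in SD units (default 2.5).
#' @param scope `"per_visit"` (grand average within each visit) or
#'   `"pooled"`.
#' @param value_col Column holding the latency (default `"srt_ms"`).
#' @return The record table with outlier statuses set.
#' @export
exclude_outliers <- function(records, k_sd = 2.5,
                             scope = c("per_visit", "pooled"),
                             value_col = "srt_ms") {
  scope <- match.arg(scope)
  if (k_sd <= 0) stop("k_sd must be positive")
  groups <- if (scope == "per_visit") records$visit_label else
    rep("all", nrow(records))
  for (g in unique(groups)) {
    in_g <- groups == g
    vidx <- which(in_g & records$status == "valid")
    if (length(vidx) < 2) {
      warning("fewer than 2 valid records in scope '", g,
              "'; outlier rule skipped")
      next
    }
    lx <- log(records[[value_col]][vidx])
    m <- mean(lx)
    s <- stats::sd(lx)
    if (s > 0) {
      out <- vidx[abs(lx - m) > k_sd * s]
      records$status[out] <- "outlier"
    }
  }
  records
}

#' Apply the minimum-valid-trial retention rule
#'
#' A participant-visit is retained when it has at least `min_valid` records
#' with status `valid` after outlier exclusion (outliers do not count).
#'
#' @param records Record table (post [exclude_outliers()]).
#' @param min_valid Retention threshold (default 10 for saccade sessions).
#' @return Data frame with one row per participant-visit: `n_valid`,
#'   `retained`.
#' @export
select_participants <- function(records, min_valid = 10) {
  if (nrow(records) == 0) {
    return(data.frame(participant_id = character(0),
                      visit_label = character(0),
                      n_valid = integer(0), retained = logical(0)))
  }
  agg <- stats::aggregate(list(n_valid = records$status == "valid"),
                          by = list(participant_id = records$participant_id,
                                    visit_label = records$visit_label),
                          FUN = sum)
  agg$retained <- agg$n_valid >= min_valid
  agg
}

#' Flag AOI entries at monocular/binocular tracking transitions
#'
#' QC audit for the concern that a switch between one- and two-eye tracking
#' could produce a spurious gaze shift between areas of interest: a record
#' is flagged when its AOI-entry sample's source (left/right/both eyes)
#' differs from the immediately preceding sample's source, both non-missing.
#' [extract_srt()] sets the same flag during extraction; this operation
#' recomputes it for an existing record table against its stream.
#'
#' @param stream The preprocessed `monocular_stream` the records came from.
#' @param records SRT record table for that stream (one session).
#' @return `records` with `monocular_entry_flag` recomputed.
#' @export
flag_monocular_transitions <- function(stream, records) {
  records$monocular_entry_flag <- FALSE
  ok <- which(records$status == "valid")
  for (i in ok) {
    ent <- findInterval(records$onset_ms[i] + records$srt_ms[i], stream$t_ms)
    if (ent > 1) {
      s0 <- stream$source[ent - 1L]
      s1 <- stream$source[ent]
      records$monocular_entry_flag[i] <-
        s0 != "missing" && s1 != "missing" && s0 != s1
    }
  }
  records
}

#' Keep only retained, valid trials
#'
#' Convenience filter combining [select_participants()] with the validity
#' statuses: returns the rows used by the reliability and model stages.
#'
#' @inheritParams select_participants
#' @return Subset of `records` (status `valid`, retained participants).
#' @export
retained_valid_trials <- function(records, min_valid = 10) {
  keep <- select_participants(records, min_valid)
  keep <- keep[keep$retained, c("participant_id", "visit_label")]
  m <- merge(records[records$status == "valid", , drop = FALSE], keep,
             by = c("participant_id", "visit_label"))
  m[order(m$participant_id, m$visit_label, m$block_id, m$trial_index), ,
    drop = FALSE]
}
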