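# shared fixture builders: tiny streams, recordings and event tables built
# in code so every test is self-contained

default_geometry <- function() screen_geometry(1920, 1080, 510, 287, 600)

# a monocular stream on a regular 120 Hz grid from vectors of x/y (NA = gap)
make_stream <- function(x, y = rep(0, length(x)), rate = 120,
                        source = NULL) {
  n <- length(x)
  if (is.null(source)) source <- ifelse(is.na(x), "missing", "both_eyes")
  out <- data.frame(t_ms = (seq_len(n) - 1) * 1000 / rate,
                    x_deg = x, y_deg = y, source = source,
                    stringsAsFactors = FALSE)
  attr(out, "sampling_rate_hz") <- rate
  class(out) <- c("monocular_stream", "data.frame")
  out
}

# binocular recording from per-eye coordinate vectors
make_recording <- function(lx, ly, rx, ry, lv = !is.na(lx), rv = !is.na(rx),
                           rate = 120, ...) {
  n <- length(lx)
  gaze_recording(data.frame(t_ms = (seq_len(n) - 1) * 1000 / rate,
                            left_x_deg = lx, left_y_deg = ly,
                            right_x_deg = rx, right_y_deg = ry,
                            left_valid = lv, right_valid = rv),
                 sampling_rate_hz = rate, ...)
}

# a two-target event table: previous target at origin, new target at (10, 0)
make_trial_events <- function(onset_new = 500, half = 2.85) {
  data.frame(onset_ms = c(0, onset_new),
             center_x_deg = c(0, 10), center_y_deg = c(0, 0),
             half_w_deg = half, half_h_deg = half,
             block = c(0L, 1L), trial = c(0L, 1L),
             kind = c("center", "target"),
             is_first_center_target = c(TRUE, FALSE),
             stringsAsFactors = FALSE)
}

# stream for one clean trial: fixate (0,0), jump to (10,0) at jump_ms,
# sampled at 120 Hz for dur_ms
make_trial_stream <- function(jump_ms, dur_ms = 2500, rate = 120) {
  t <- seq(0, dur_ms, by = 1000 / rate)
  make_stream(ifelse(t >= jump_ms, 10, 0), rep(0, length(t)), rate = rate)
}

# SRT record table from a matrix of per-participant trial latencies
make_records <- function(latencies_by_participant, visit = "visit1",
                         status = "valid") {
  rows <- lapply(names(latencies_by_participant), function(p) {
    srt <- latencies_by_participant[[p]]
    m <- length(srt)
    data.frame(participant_id = p, visit_label = visit,
               block_id = ((seq_len(m) - 1) %/% 5) + 1,
               trial_index = ((seq_len(m) - 1) %% 5) + 1,
               onset_ms = NA_real_, srt_ms = srt, status = status,
               prev_target_distance_deg = 10, monocular_entry_flag = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force NA-aware running median (independent oracle for the C++ filter)
median_filter_oracle <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (is.na(x[i])) return(NA_real_)
    w <- x[max(1, i - h):min(n, i + h)]
    stats::median(w[!is.na(w)])
  }, numeric(1))
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))
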