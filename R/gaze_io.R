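#' Construct a gaze recording
#'
#' A gaze recording holds time-ordered binocular gaze samples in degrees of
#' visual angle relative to the screen centre (x rightward, y downward),
#' together with the screen geometry and the nominal sampling rate.
#'
#' Invariants enforced: timestamps strictly increasing; an eye flagged
#' invalid has missing coordinates; the median inter-sample interval must lie
#' within 20% of the nominal sample period.
#'
#' @param samples A data frame with columns `t_ms`, `left_x_deg`,
#'   `left_y_deg`, `right_x_deg`, `right_y_deg`, `left_valid`, `right_valid`.
#' @param sampling_rate_hz Nominal sampling rate in Hz (default 120).
#' @param geometry A [screen_geometry()].
#' @param participant_id,visit_label Identifiers carried through extraction.
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, sampling_rate_hz = 120, geometry = NULL,
                           participant_id = NA_character_,
                           visit_label = NA_character_) {
  needed <- c("t_ms", "left_x_deg", "left_y_deg", "right_x_deg",
              "right_y_deg", "left_valid", "right_valid")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("gaze samples missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(samples)[needed]
  o <- order(samples$t_ms)
  samples <- samples[o, , drop = FALSE]
  rownames(samples) <- NULL
  dt <- diff(samples$t_ms)
  if (any(dt <= 0)) {
    stop("non-monotone timestamps: first offending row ",
         which(dt <= 0)[1] + 1L)
  }
  samples$left_valid <- as.logical(samples$left_valid)
  samples$right_valid <- as.logical(samples$right_valid)
  # invalid eye => coordinates missing
  samples$left_x_deg[!samples$left_valid] <- NA_real_
  samples$left_y_deg[!samples$left_valid] <- NA_real_
  samples$right_x_deg[!samples$right_valid] <- NA_real_
  samples$right_y_deg[!samples$right_valid] <- NA_real_
  # an eye with missing coordinates cannot be valid
  samples$left_valid <- samples$left_valid &
    !is.na(samples$left_x_deg) & !is.na(samples$left_y_deg)
  samples$right_valid <- samples$right_valid &
    !is.na(samples$right_x_deg) & !is.na(samples$right_y_deg)
  samples$left_x_deg[!samples$left_valid] <- NA_real_
  samples$left_y_deg[!samples$left_valid] <- NA_real_
  samples$right_x_deg[!samples$right_valid] <- NA_real_
  samples$right_y_deg[!samples$right_valid] <- NA_real_
  if (length(dt) >= 2) {
    nominal <- 1000 / sampling_rate_hz
    med <- stats::median(dt)
    if (abs(med - nominal) > 0.2 * nominal) {
      stop(sprintf(
        "median inter-sample interval %.2f ms deviates >20%% from nominal %.2f ms",
        med, nominal))
    }
  }
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 geometry = geometry,
                 participant_id = participant_id,
                 visit_label = visit_label),
            class = "gaze_recording")
}

#' @method print gaze_recording
#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s / %s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$visit_label, nrow(x$samples),
              x$sampling_rate_hz,
              diff(range(x$samples$t_ms)) / 1000))
  invisible(x)
}

#' Read a gaze sample table
#'
#' Reads a delimited gaze table with columns
#' `t_ms,left_x,left_y,left_valid,right_x,right_y,right_valid`. Units may be
#' pixels or degrees; pixel input is converted to degrees using `geometry`.
#' A sidecar YAML/JSON config (same path plus `.yaml`/`.json`) may declare
#' `units` and a `geometry` block; explicit arguments override the sidecar.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param geometry A [screen_geometry()]; required when `units = "px"`.
#' @param sampling_rate_hz Nominal sampling rate (default 120).
#' @param units `"deg"` or `"px"`; default taken from the sidecar config,
#'   else `"deg"`.
#' @param participant_id,visit_label Identifiers stored on the recording.
#'
#' @return A [gaze_recording()].
#' @export
read_gaze_table <- function(path, geometry = NULL, sampling_rate_hz = NULL,
                            units = NULL, participant_id = NA_character_,
                            visit_label = NA_character_) {
  cfg <- read_gaze_sidecar(path)
  if (is.null(units)) units <- cfg$units %||% "deg"
  units <- match.arg(units, c("deg", "px"))
  if (is.null(geometry) && !is.null(cfg$geometry)) {
    g <- cfg$geometry
    geometry <- screen_geometry(g$width_px, g$height_px, g$width_mm,
                                g$height_mm, g$viewing_distance_mm)
  }
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- cfg$sampling_rate_hz %||% 120
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("t_ms", "left_x", "left_y", "left_valid",
              "right_x", "right_y", "right_valid")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("gaze table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (units == "px") {
    if (is.null(geometry)) stop("pixel-unit gaze table requires a geometry")
    l <- pixels_to_degrees(tab$left_x, tab$left_y, geometry)
    r <- pixels_to_degrees(tab$right_x, tab$right_y, geometry)
  } else {
    l <- list(x_deg = tab$left_x, y_deg = tab$left_y)
    r <- list(x_deg = tab$right_x, y_deg = tab$right_y)
  }
  samples <- data.frame(t_ms = tab$t_ms,
                        left_x_deg = l$x_deg, left_y_deg = l$y_deg,
                        right_x_deg = r$x_deg, right_y_deg = r$y_deg,
                        left_valid = as.logical(tab$left_valid),
                        right_valid = as.logical(tab$right_valid))
  gaze_recording(samples, sampling_rate_hz, geometry,
                 participant_id, visit_label)
}

read_gaze_sidecar <- function(path) {
  for (ext in c(".yaml", ".yml", ".json")) {
    side <- paste0(path, ext)
    if (file.exists(side)) {
      if (ext == ".json") return(jsonlite::read_json(side, simplifyVector = TRUE))
      if (requireNamespace("yaml", quietly = TRUE)) {
        return(yaml::read_yaml(side))
      }
      warning("yaml package unavailable; ignoring sidecar ", side)
    }
  }
  list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gaze recording to a CSV table
#'
#' Writes the degree-unit sample table in the same dialect [read_gaze_table()]
#' consumes, at full double precision so that a write/read round trip is
#' lossless.
#'
#' @param recording A [gaze_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recording, path) {
  s <- recording$samples
  out <- data.frame(t_ms = format_full(s$t_ms),
                    left_x = format_full(s$left_x_deg),
                    left_y = format_full(s$left_y_deg),
                    left_valid = as.integer(s$left_valid),
                    right_x = format_full(s$right_x_deg),
                    right_y = format_full(s$right_y_deg),
                    right_valid = as.integer(s$right_valid))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Rectangular area of interest in degrees
#'
#' An AOI is a closed rectangle centred on a stimulus, expanded on every side
#' by a margin that absorbs calibration error (default 0.9 degrees). Points
#' exactly on the expanded boundary count as inside.
#'
#' @param center_x_deg,center_y_deg AOI centre, degrees from screen centre.
#' @param half_width_deg,half_height_deg Half-extents of the stimulus itself.
#' @param margin_deg Calibration-error margin added to each half-extent.
#' @return An object of class `aoi_rect`.
#' @export
aoi_rect <- function(center_x_deg, center_y_deg, half_width_deg,
                     half_height_deg, margin_deg = 0.9) {
  if (half_width_deg <= 0 || half_height_deg <= 0 || margin_deg < 0) {
    stop("AOI half sizes must be positive and margin non-negative")
  }
  structure(list(center_x_deg = center_x_deg, center_y_deg = center_y_deg,
                 half_width_deg = half_width_deg,
                 half_height_deg = half_height_deg,
                 margin_deg = margin_deg),
            class = "aoi_rect")
}

#' Test points for membership in a margin-expanded AOI
#'
#' @param aoi An [aoi_rect()].
#' @param x_deg,y_deg Point coordinates (vectorised); `NA` yields `NA`.
#' @return Logical vector; boundary points are inside (closed rectangle).
#' @export
aoi_contains <- function(aoi, x_deg, y_deg) {
  hw <- aoi$half_width_deg + aoi$margin_deg
  hh <- aoi$half_height_deg + aoi$margin_deg
  abs(x_deg - aoi$center_x_deg) <= hw & abs(y_deg - aoi$center_y_deg) <= hh
}

#' Read a saccade-target (or cue) event table
#'
#' Expects a CSV with columns
#' `onset_ms,center_x_deg,center_y_deg,half_w_deg,half_h_deg,block,trial,kind`.
#' Events are returned sorted by onset; the first event of kind `"center"`
#' is flagged as the initial centre target, which is excluded from SRT
#' analysis (the gaze position at its onset is not standardised).
#'
#' @param path CSV path.
#' @return A data frame of events with an `is_first_center_target` column.
#' @export
read_events <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty event table: ", path)
    tab$is_first_center_target <- logical(0)
    return(tab)
  }
  needed <- c("onset_ms", "center_x_deg", "center_y_deg",
              "half_w_deg", "half_h_deg", "block", "trial", "kind")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("event table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[order(tab$onset_ms), , drop = FALSE]
  rownames(tab) <- NULL
  first_center <- match("center", tab$kind)
  tab$is_first_center_target <- !is.na(first_center) &
    seq_len(nrow(tab)) == first_center
  # saccade targets are presented one at a time: within a block, an event's
  # interval [onset, next onset) must not overlap the previous one
  for (b in unique(tab$block)) {
    tb <- tab[tab$block == b & tab$kind != "cue", , drop = FALSE]
    if (nrow(tb) > 1 && any(duplicated(tb$onset_ms))) {
      stop("overlapping saccade-target intervals in block ", b)
    }
  }
  tab
}

#' Count the analyzable saccade trials in an event table
#'
#' The initial centre target is excluded; every other saccade target is an
#' analyzable trial (40 in an 8-block x 5-target session, 66 in a 6 x 11
#' session).
#'
#' @param events Event data frame from [read_events()].
#' @return Integer count.
#' @export
n_analyzable_trials <- function(events) {
  sum(!events$is_first_center_target & events$kind != "cue")
}
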