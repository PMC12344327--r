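#' Merge binocular gaze samples into a single (cyclopean) stream
#'
#' Per sample: when both eyes are valid the coordinates are averaged; when
#' only one eye is valid that eye's coordinates are used; when neither is
#' valid the sample is missing. The per-sample source flag records which case
#' applied, which later feeds the monocular-transition QC flag.
#'
#' @param recording A [gaze_recording()].
#' @return A `monocular_stream`: data frame with columns `t_ms`, `x_deg`,
#'   `y_deg` and `source` (one of `both_eyes`, `left_only`, `right_only`,
#'   `missing`).
#' @export
merge_eyes <- function(recording) {
  s <- recording$samples
  if (nrow(s) == 0) stop("cannot merge an empty recording")
  lv <- s$left_valid
  rv <- s$right_valid
  x <- ifelse(lv & rv, (s$left_x_deg + s$right_x_deg) / 2,
              ifelse(lv, s$left_x_deg, s$right_x_deg))
  y <- ifelse(lv & rv, (s$left_y_deg + s$right_y_deg) / 2,
              ifelse(lv, s$left_y_deg, s$right_y_deg))
  src <- rep("missing", nrow(s))
  src[lv & rv] <- "both_eyes"
  src[lv & !rv] <- "left_only"
  src[!lv & rv] <- "right_only"
  x[src == "missing"] <- NA_real_
  y[src == "missing"] <- NA_real_
  out <- data.frame(t_ms = s$t_ms, x_deg = x, y_deg = y,
                    source = src, stringsAsFactors = FALSE)
  attr(out, "sampling_rate_hz") <- recording$sampling_rate_hz
  class(out) <- c("monocular_stream", "data.frame")
  out
}

#' Median-filter a gaze stream to remove abrupt spikes
#'
#' Applies an NA-aware centred running median (default 15 samples, i.e.
#' 125 ms at 120 Hz) independently to the x and y coordinate series. The
#' median is taken over non-missing neighbours only, so gaps survive
#' filtering unchanged and continue to drive the missing-run validity
#' criterion; only a sample that is itself missing stays missing. The window
#' shrinks at the recording edges. Source flags are unchanged.
#'
#' @param stream A `monocular_stream` from [merge_eyes()].
#' @param window_samples Odd window length in samples (default 15).
#' @return The filtered `monocular_stream`.
#' @export
median_filter_stream <- function(stream, window_samples = 15) {
  if (length(window_samples) != 1 || window_samples < 3 ||
      window_samples %% 2 == 0) {
    stop("window_samples must be a single odd integer >= 3")
  }
  stream$x_deg <- median_filter_cpp(stream$x_deg, as.integer(window_samples))
  stream$y_deg <- median_filter_cpp(stream$y_deg, as.integer(window_samples))
  stream
}

#' Preprocess a recording for latency extraction
#'
#' Runs binocular merging and median filtering. The default order merges the
#' two eyes first and filters the merged stream, which maximises the number
#' of non-missing samples available to the filter; `filter_first` filters
#' each eye's series before merging.
#'
#' @param recording A [gaze_recording()].
#' @param window_samples Median-filter window (default 15 samples).
#' @param filter_order `"merge_first"` (default) or `"filter_first"`.
#' @return A filtered `monocular_stream`.
#' @export
preprocess_recording <- function(recording, window_samples = 15,
                                 filter_order = c("merge_first", "filter_first")) {
  filter_order <- match.arg(filter_order)
  if (filter_order == "merge_first") {
    return(median_filter_stream(merge_eyes(recording), window_samples))
  }
  rec <- recording
  for (col in c("left_x_deg", "left_y_deg", "right_x_deg", "right_y_deg")) {
    rec$samples[[col]] <- median_filter_cpp(rec$samples[[col]],
                                            as.integer(window_samples))
  }
  merge_eyes(rec)
}
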