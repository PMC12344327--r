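#' Within-session split-half (odd-even) reliability
#'
#' For each participant, valid non-outlier trials are ordered by block and
#' trial position and split by their odd/even position *among valid trials*
#' (which balances half sizes under missingness). The per-participant means
#' of the two halves are correlated across participants (Pearson r), with a
#' 95% CI by the Fisher z transform. No Spearman-Brown correction is applied
#' by default; set `spearman_brown = TRUE` for the full-length projection.
#'
#' @param records SRT record table (statuses already assigned).
#' @param visit_label Optional: restrict to one visit.
#' @param spearman_brown Apply the 2r/(1+r) correction (default `FALSE`).
#' @return A `reliability_estimate`: list with `r`, `ci_low`, `ci_high`,
#'   `n`, `method`.
#' @export
split_half <- function(records, visit_label = NULL, spearman_brown = FALSE) {
  if (!is.null(visit_label)) {
    records <- records[records$visit_label == visit_label, , drop = FALSE]
  }
  v <- records[records$status == "valid", , drop = FALSE]
  v <- v[order(v$participant_id, v$block_id, v$trial_index), , drop = FALSE]
  halves <- lapply(split(v$srt_ms, v$participant_id), function(srt) {
    if (length(srt) < 2) return(c(NA_real_, NA_real_))
    pos <- seq_along(srt)
    c(mean(srt[pos %% 2 == 1]), mean(srt[pos %% 2 == 0]))
  })
  h <- do.call(rbind, halves)
  h <- h[stats::complete.cases(h), , drop = FALSE]
  n <- nrow(h)
  if (n < 2) stop("split-half reliability needs >= 2 participants with >= 2 valid trials")
  r <- stats::cor(h[, 1], h[, 2])
  if (spearman_brown) r <- 2 * r / (1 + r)
  ci <- fisher_z_ci(r, n)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n,
                 method = "split_half_odd_even"),
            class = "reliability_estimate")
}

#' Cross-visit stability of mean SRT
#'
#' Pearson correlation of per-participant mean valid SRT between two visits,
#' over participants retained at both, with a Fisher-z 95% CI.
#'
#' @param records_a,records_b Record tables for the two visits (valid,
#'   retained trials; see [retained_valid_trials()]).
#' @return A `reliability_estimate` with `method = "cross_visit"`.
#' @export
cross_visit_correlation <- function(records_a, records_b) {
  ma <- tapply(records_a$srt_ms[records_a$status == "valid"],
               records_a$participant_id[records_a$status == "valid"], mean)
  mb <- tapply(records_b$srt_ms[records_b$status == "valid"],
               records_b$participant_id[records_b$status == "valid"], mean)
  common <- intersect(names(ma), names(mb))
  if (length(common) < 3) stop("cross-visit correlation needs >= 3 paired participants")
  r <- stats::cor(ma[common], mb[common])
  ci <- fisher_z_ci(r, length(common))
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2],
                 n = length(common), method = "cross_visit"),
            class = "reliability_estimate")
}

#' @method print reliability_estimate
#' @export
print.reliability_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" [%.2f, %.2f]", x$ci_low, x$ci_high)
  cat(sprintf("%s r = %.2f%s (n = %d)\n", x$method, x$r, ci, x$n))
  invisible(x)
}

fisher_z_ci <- function(r, n, conf = 0.95) {
  if (n < 4) {
    warning("too few participants for a Fisher-z CI")
    return(c(NA_real_, NA_real_))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Retention and descriptive summary by visit
#'
#' Reproduces the standard per-visit quality table: number of participants
#' assessed, number retained under the minimum-valid-trials rule, the mean /
#' min / max number of valid trials among retained participants, and the
#' mean valid-trial SRT. Because trials are clustered within participants,
#' the trial-level mean's 95% CI is obtained by a cluster bootstrap
#' (resampling participants with replacement); a participant-level CI (over
#' per-participant means) is also reported.
#'
#' @param records SRT record table for one or more visits (post outlier
#'   exclusion).
#' @param min_valid Retention threshold (default 10).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame with one row per visit.
#' @export
retention_summary <- function(records, min_valid = 10, n_boot = 1000,
                              seed = 1L) {
  out <- lapply(unique(records$visit_label), function(vl) {
    rv <- records[records$visit_label == vl, , drop = FALSE]
    sel <- select_participants(rv, min_valid)
    n_assessed <- nrow(sel)
    ret <- sel[sel$retained, , drop = FALSE]
    keep <- rv$status == "valid" & rv$participant_id %in% ret$participant_id
    v <- rv[keep, , drop = FALSE]
    pm <- tapply(v$srt_ms, v$participant_id, mean)
    boot_ci <- cluster_boot_mean_ci(v$srt_ms, v$participant_id, n_boot, seed)
    data.frame(visit_label = vl,
               n_assessed = n_assessed,
               n_retained = nrow(ret),
               valid_trials_mean = if (nrow(ret)) mean(ret$n_valid) else NA_real_,
               valid_trials_min = if (nrow(ret)) min(ret$n_valid) else NA_integer_,
               valid_trials_max = if (nrow(ret)) max(ret$n_valid) else NA_integer_,
               mean_srt = mean(v$srt_ms),
               mean_srt_ci_low = boot_ci[1],
               mean_srt_ci_high = boot_ci[2],
               mean_srt_participant_level = mean(pm),
               mean_srt_participant_ci_low =
                 mean(pm) - 1.96 * stats::sd(pm) / sqrt(length(pm)),
               mean_srt_participant_ci_high =
                 mean(pm) + 1.96 * stats::sd(pm) / sqrt(length(pm)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cluster_boot_mean_ci <- function(x, cluster, n_boot = 1000, seed = 1L,
                                 conf = 0.95) {
  if (!length(x)) return(c(NA_real_, NA_real_))
  by_cl <- split(x, cluster)
  k <- length(by_cl)
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(k, k, replace = TRUE)
      mean(unlist(by_cl[idx], use.names = FALSE))
    }, numeric(1))
  })
  unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Markdown rendering of the retention summary
#'
#' @param summary_df Output of [retention_summary()].
#' @return A character vector of markdown lines.
#' @export
format_retention_markdown <- function(summary_df) {
  hdr <- c("| Variable | " %+% paste(summary_df$visit_label, collapse = " | ") %+% " |",
           "|---" %+% paste(rep("|---", nrow(summary_df)), collapse = "") %+% "|")
  row <- function(label, vals) "| " %+% label %+% " | " %+%
    paste(vals, collapse = " | ") %+% " |"
  c(hdr,
    row("N assessed", summary_df$n_assessed),
    row("N retained", summary_df$n_retained),
    row("Valid trials (min, max)",
        sprintf("%.1f (%d, %d)", summary_df$valid_trials_mean,
                summary_df$valid_trials_min, summary_df$valid_trials_max)),
    row("Mean SRT [95% CI]",
        sprintf("%.0f [%.0f %.0f]", summary_df$mean_srt,
                summary_df$mean_srt_ci_low, summary_df$mean_srt_ci_high)))
}

`%+%` <- function(a, b) paste0(a, b)
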