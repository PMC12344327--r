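#' Asset-based household wealth index (first principal component)
#'
#' Implements the Filmer-Pritchett procedure: binary asset-ownership
#' indicators are standardized to mean 0 / SD 1 (zero-variance indicators
#' are dropped with a warning), the first principal component is extracted
#' from their correlation structure, and each household's score on that
#' component is taken as its wealth index. The sign is oriented so that the
#' index correlates positively with the raw asset count, and scores are
#' standardized to mean 0, SD 1 across households, so downstream model
#' coefficients read "per SD of household resources".
#'
#' Missing indicator values are imputed to the indicator mean; households
#' missing more than `max_missing` of their indicators are excluded (score
#' `NA`).
#'
#' @param asset_matrix Numeric matrix or data frame, households x indicators,
#'   values 0/1 (NA allowed).
#' @param max_missing Per-household missingness cap (default 0.2).
#' @return List of class `asset_index`: `score` (per household), `loadings`,
#'   `explained_variance_share`, `dropped_indicators`.
#' @export
asset_index <- function(asset_matrix, max_missing = 0.2) {
  m <- as.matrix(asset_matrix)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("asset index needs >= 2 households")
  bad <- rowMeans(is.na(m)) > max_missing
  work <- m[!bad, , drop = FALSE]
  # mean-impute remaining missing entries per indicator
  for (j in seq_len(ncol(work))) {
    nas <- is.na(work[, j])
    if (any(nas)) work[nas, j] <- mean(work[, j], na.rm = TRUE)
  }
  sds <- apply(work, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all asset indicators are constant")
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " zero-variance indicator(s)")
  }
  work <- work[, keep, drop = FALSE]
  std <- scale(work)
  pc <- stats::prcomp(std, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  # orient positively with the total asset count. The coding convention
  # (1 = owns) fixes the wealth direction: a globally flipped coding yields
  # the negated (rank-reversed) index, since the wealth direction cannot be
  # identified from the data alone.
  total <- rowSums(work)
  if (stats::sd(total) > 0 && stats::cor(score, total) < 0) {
    score <- -score
    loadings <- -loadings
  }
  score <- as.numeric(scale(score))
  full <- rep(NA_real_, nrow(m))
  full[!bad] <- score
  structure(list(score = full, loadings = loadings,
                 explained_variance_share =
                   pc$sdev[1]^2 / sum(pc$sdev^2),
                 dropped_indicators = which(!keep),
                 excluded_households = which(bad)),
            class = "asset_index")
}

#' @method print asset_index
#' @export
print.asset_index <- function(x, ...) {
  cat(sprintf("<asset_index> %d households, PC1 explains %.1f%% of indicator variance\n",
              sum(!is.na(x$score)), 100 * x$explained_variance_share))
  invisible(x)
}

#' Daily screen time from weekday/weekend responses (36-month protocol)
#'
#' Weekday and weekend hours-per-day responses, given on the instrument's
#' half-hour grid {0, 0.5, 1, 2, ..., 9}, are averaged (they are highly
#' correlated in practice). Off-grid values trigger a validation warning but
#' are still averaged.
#'
#' @param hours_weekday,hours_weekend Hours per day.
#' @return Hours per day.
#' @export
screen_time_sa_36m <- function(hours_weekday, hours_weekend) {
  grid <- c(0, 0.5, 1:9)
  vals <- c(hours_weekday, hours_weekend)
  if (any(!is.na(vals) & !vals %in% grid)) {
    warning("screen-time response off the instrument grid {0, 0.5, 1..9}")
  }
  (hours_weekday + hours_weekend) / 2
}

#' Daily screen time from weekly totals (replication-cohort protocol)
#'
#' Weekday and weekend totals are summed and divided by 7.
#'
#' @param hours_weekday,hours_weekend Reported hours (non-negative).
#' @param weighted If `TRUE`, use a 5/7-weekday + 2/7-weekend weighted day
#'   instead of the literal sum/7.
#' @return Hours per day.
#' @export
screen_time_zm <- function(hours_weekday, hours_weekend, weighted = FALSE) {
  if (any(stats::na.omit(c(hours_weekday, hours_weekend)) < 0)) {
    stop("screen-time hours must be non-negative")
  }
  out <- if (weighted) (5 * hours_weekday + 2 * hours_weekend) / 7
         else (hours_weekday + hours_weekend) / 7
  stopifnot(all(is.na(out) | out <= 24))
  out
}

#' Centre child age within visit
#'
#' Returns each child's age as a deviation from the mean age of their visit,
#' the form in which age enters the gradient models.
#'
#' @param ages Ages (months).
#' @param visit_labels Visit label per row.
#' @return Numeric vector of within-visit age deviations (mean 0 per visit).
#' @export
center_age <- function(ages, visit_labels) {
  stats::ave(ages, visit_labels, FUN = function(a) a - mean(a))
}
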