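#' Fit the household-resource gradient model for trial-level latencies
#'
#' Fits the study's linear mixed-effects model by REML:
#' `SRT ~ Visit * Assets + Age-deviation + Household size +
#' (1 | Participant) + (1 | Block:Trial)`,
#' where Assets is the standardized household asset index, age enters as the
#' deviation from the visit's mean age, visit is a categorical factor with
#' the first visit as reference, and the block:trial random intercept
#' captures stimulus-sequence effects (each block x trial-position
#' combination, crossed with participants). The assets main effect and the
#' visit x assets interaction are the headline gradient terms. Wald 95% CIs
#' are reported for all fixed effects.
#'
#' @param trial_table Trial-level records (valid, retained trials; see
#'   [retained_valid_trials()]) with `participant_id`, `visit_label`,
#'   `block_id`, `trial_index` and the response column.
#' @param covariate_table Per participant-visit covariates: `assets`,
#'   `age_dev_months`, `household_size` and any adjustment columns.
#' @param response Response column (default `"srt_ms"`).
#' @param adjust_for Character vector of extra covariate columns entered as
#'   fixed effects (e.g. `"haz"`, `"screen_time"`).
#' @param block_trial `"crossed"` (default: one level per block x
#'   trial-position) or `"by_block"` (one level per block).
#' @param reml Use REML (default `TRUE`).
#' @return An object of class `gradient_fit`.
#' @export
fit_gradient_model <- function(trial_table, covariate_table,
                               response = "srt_ms", adjust_for = NULL,
                               block_trial = c("crossed", "by_block"),
                               reml = TRUE) {
  block_trial <- match.arg(block_trial)
  dat <- merge(trial_table, covariate_table,
               by = c("participant_id", "visit_label"))
  if (length(unique(dat$participant_id)) < 2) {
    stop("gradient model needs >= 2 participants")
  }
  dat$visit <- factor(dat$visit_label)
  dat$participant <- factor(dat$participant_id)
  dat$block_trial <- if (block_trial == "crossed") {
    interaction(dat$block_id, dat$trial_index, drop = TRUE)
  } else {
    factor(dat$block_id)
  }
  dat$.y <- dat[[response]]
  fixed <- c(if (nlevels(dat$visit) > 1) "visit * assets" else "assets",
             "age_dev_months", "household_size", adjust_for)
  f <- stats::as.formula(paste(
    ".y ~", paste(fixed, collapse = " + "),
    "+ (1 | participant) + (1 | block_trial)"))
  fit_lmm(f, dat, reml, response = response)
}

#' Covariate-adjusted gradient model
#'
#' The gradient model of [fit_gradient_model()] with one further covariate
#' (screen time, HAZ, ...) added as a fixed effect.
#'
#' @inheritParams fit_gradient_model
#' @param extra_covariate Name of the covariate column to add.
#' @return A `gradient_fit`.
#' @export
fit_adjusted <- function(trial_table, covariate_table, extra_covariate,
                         response = "srt_ms", ...) {
  fit_gradient_model(trial_table, covariate_table, response = response,
                     adjust_for = extra_covariate, ...)
}

#' Replication-cohort (single-visit) model variant
#'
#' Single-visit variant with the varying previous-target distance as a fixed
#' covariate and a nested random effect for family and child (some children
#' share a household). When the full random structure yields a singular or
#' non-converged fit, the stated reduction sequence is applied: first the
#' trial-level random effect is dropped, then the nested child effect
#' (leaving a family intercept only). The reduction actually used is
#' recorded on the returned object (`$reduction`).
#'
#' @param trial_table Trial records carrying `prev_target_distance_deg`.
#' @param covariate_table Covariates including `family_id`.
#' @param response Response column.
#' @param reml Use REML (default `TRUE`).
#' @return A `gradient_fit` with a `reduction` field
#'   (`"none"`, `"drop_trial_re"`, or `"drop_nested_child"`).
#' @export
fit_zambia_variant <- function(trial_table, covariate_table,
                               response = "srt_ms", reml = TRUE) {
  dat <- merge(trial_table, covariate_table,
               by = c("participant_id", "visit_label"))
  dat$participant <- factor(dat$participant_id)
  dat$family <- factor(dat$family_id)
  dat$block_trial <- interaction(dat$block_id, dat$trial_index, drop = TRUE)
  dat$.y <- dat[[response]]
  fixed <- ".y ~ assets + age_dev_months + household_size + prev_target_distance_deg"
  forms <- list(
    none = paste(fixed, "+ (1 | family / participant) + (1 | block_trial)"),
    drop_trial_re = paste(fixed, "+ (1 | family / participant)"),
    drop_nested_child = paste(fixed, "+ (1 | family)"))
  last_err <- NULL
  for (red in names(forms)) {
    fit <- tryCatch(
      fit_lmm(stats::as.formula(forms[[red]]), dat, reml, response = response),
      error = function(e) e)
    if (inherits(fit, "error")) {
      last_err <- fit
      next
    }
    if (!fit$singular && fit$converged) {
      fit$reduction <- red
      return(fit)
    }
    last_err <- fit
  }
  if (inherits(last_err, "gradient_fit")) {
    # every reduction was singular/non-converged; return the last, flagged
    last_err$reduction <- "drop_nested_child"
    warning("all random-effect reductions singular or non-converged; ",
            "returning the maximally reduced fit")
    return(last_err)
  }
  stop("replication-variant model failed: ", conditionMessage(last_err))
}

#' Gradient model for participant-level outcomes
#'
#' Same fixed structure as the trial-level model, for outcomes observed once
#' per participant-visit (HAZ, milestone scores): the trial-level random
#' effects are dropped and only the participant random intercept is kept.
#'
#' @param outcome_table One row per participant-visit with the outcome
#'   column.
#' @param covariate_table Covariates as in [fit_gradient_model()].
#' @param outcome Outcome column name (e.g. `"haz"`, `"milestone"`).
#' @param reml Use REML (default `TRUE`).
#' @return A `gradient_fit`.
#' @export
fit_outcome_gradient <- function(outcome_table, covariate_table,
                                 outcome = "haz", reml = TRUE) {
  dat <- merge(outcome_table, covariate_table,
               by = c("participant_id", "visit_label"))
  dat$.y <- dat[[outcome]]
  if (stats::var(dat$.y, na.rm = TRUE) == 0) {
    stop("outcome '", outcome, "' is constant (zero residual variance)")
  }
  dat$visit <- factor(dat$visit_label)
  dat$participant <- factor(dat$participant_id)
  fixed <- c(if (nlevels(dat$visit) > 1) "visit * assets" else "assets",
             "age_dev_months", "household_size")
  f <- stats::as.formula(paste(
    ".y ~", paste(fixed, collapse = " + "), "+ (1 | participant)"))
  fit_lmm(f, dat, reml, response = outcome)
}

# shared lme4 backend with rank checks, Wald CIs and metadata
fit_lmm <- function(formula, data, reml = TRUE, response = "y") {
  fe_form <- lme4::nobars(formula)
  X <- stats::model.matrix(fe_form, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lme4::lmer(formula, data = data, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  q <- stats::qnorm(0.975)
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta),
                      se = se, ci_low = beta - q * se, ci_high = beta + q * se,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, ifelse(is.na(vc$var1), vc$grp,
                                             paste(vc$grp, vc$var1, sep = ".")))
  structure(list(coefficients = coefs,
                 variance_components = varcomp,
                 n_obs = stats::nobs(fit),
                 n_participants = if ("participant" %in% names(data))
                   length(unique(data$participant)) else NA_integer_,
                 converged = converged,
                 singular = lme4::isSingular(fit),
                 response = response,
                 formula = formula,
                 fit = fit),
            class = "gradient_fit")
}

#' @method print gradient_fit
#' @export
print.gradient_fit <- function(x, digits = 3, ...) {
  cat("Household-resource gradient model (", x$response, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d observations, %d participants%s%s\n", x$n_obs,
              x$n_participants,
              if (x$singular) ", SINGULAR fit" else "",
              if (!x$converged) ", NOT converged" else ""))
  co <- x$coefficients
  cat("\nFixed effects (Wald 95% CI):\n")
  print(data.frame(term = co$term,
                   estimate = round(co$estimate, digits),
                   ci = sprintf("[%s, %s]", round(co$ci_low, digits),
                                round(co$ci_high, digits))),
        row.names = FALSE)
  cat("\nVariance components:\n")
  print(round(x$variance_components, digits))
  invisible(x)
}

#' @method summary gradient_fit
#' @export
summary.gradient_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              variance_components = object$variance_components,
              n_obs = object$n_obs, n_participants = object$n_participants,
              converged = object$converged, singular = object$singular,
              reduction = object$reduction)
  class(out) <- "summary.gradient_fit"
  out
}

#' @method print summary.gradient_fit
#' @export
print.summary.gradient_fit <- function(x, ...) {
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @method coef gradient_fit
#' @export
coef.gradient_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Extract one fixed-effect row (estimate and Wald CI) from a fit
#'
#' @param fit A `gradient_fit`.
#' @param term Coefficient name (e.g. `"assets"`, `"haz"`).
#' @return One-row data frame with `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
gradient_term <- function(fit, term = "assets") {
  co <- fit$coefficients
  row <- co[co$term == term, , drop = FALSE]
  if (!nrow(row)) stop("no fixed-effect term '", term, "' in the fit")
  row
}
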