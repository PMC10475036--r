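#' Valence-split feedback-learning betas for one subject
#'
#' Models the T2 re-evaluation as the T1 self-evaluation plus the feedback
#' mismatch weighted by a valence-specific slope:
#' `SelfEval(T2) = SelfEval(T1) + beta_pos * dEval` for positive mismatch
#' and `+ beta_neg * dEval` for negative mismatch. Estimated by ordinary
#' least squares of the T2-T1 change on the two sign-masked mismatch
#' regressors; the printed model has no intercept, so none is fitted by
#' default. Trials with a mismatch of exactly zero carry no valence
#' information and are excluded.
#'
#' @param trials One subject's trial data.frame with columns
#'   `delta_eval`, `self_eval_t1_val`, `self_eval_t2_val` (and optionally
#'   `subject_id`, `group`).
#' @param include_intercept Add an intercept to the change regression.
#' @return An object of class `learning_betas`: list with `subject_id`,
#'   `beta_pos`, `beta_neg`, `bias` (`beta_pos - beta_neg`),
#'   `n_pos_trials`, `n_neg_trials`, `residual_sd`.
#' @export
fit_valence_betas <- function(trials, include_intercept = FALSE) {
  d <- trials$delta_eval
  y <- trials$self_eval_t2_val - trials$self_eval_t1_val
  keep <- !is.na(d) & !is.na(y) & d != 0
  d <- d[keep]
  y <- y[keep]
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  if (n_pos < 2) {
    stop("cannot estimate beta_pos: fewer than 2 trials with positive mismatch",
         call. = FALSE)
  }
  if (n_neg < 2) {
    stop("cannot estimate beta_neg: fewer than 2 trials with negative mismatch",
         call. = FALSE)
  }
  X <- cbind(delta_pos = d * (d > 0), delta_neg = d * (d < 0))
  if (include_intercept) X <- cbind(intercept = 1, X)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient design in valence-split regression", call. = FALSE)
  }
  cf <- stats::coef(fit)
  res_df <- length(y) - ncol(X)
  structure(
    list(
      subject_id = if ("subject_id" %in% names(trials)) trials$subject_id[1] else NA_character_,
      group = if ("group" %in% names(trials)) trials$group[1] else NA_character_,
      beta_pos = unname(cf["delta_pos"]),
      beta_neg = unname(cf["delta_neg"]),
      bias = unname(cf["delta_pos"] - cf["delta_neg"]),
      n_pos_trials = n_pos,
      n_neg_trials = n_neg,
      residual_sd = if (res_df > 0) sqrt(sum(fit$residuals^2) / res_df) else NA_real_,
      include_intercept = include_intercept
    ),
    class = "learning_betas"
  )
}

#' @export
print.learning_betas <- function(x, ...) {
  cat(sprintf("Valence-split learning betas (%s)\n",
              ifelse(is.na(x$subject_id), "unnamed subject", x$subject_id)))
  cat(sprintf("  beta_pos = %.4f (%d trials), beta_neg = %.4f (%d trials)\n",
              x$beta_pos, x$n_pos_trials, x$beta_neg, x$n_neg_trials))
  cat(sprintf("  social influence bias (pos - neg) = %.4f\n", x$bias))
  invisible(x)
}

#' Per-subject learning betas for a whole cohort
#'
#' First level of the summary-statistics approach: fits
#' [fit_valence_betas()] to every subject and returns one row each,
#' preserving group labels for second-level tests.
#'
#' @param cohort A `cohort` or long trial data.frame.
#' @param include_intercept Passed to [fit_valence_betas()].
#' @return data.frame with columns `subject_id`, `group`, `beta_pos`,
#'   `beta_neg`, `bias`, `n_pos_trials`, `n_neg_trials`, `residual_sd`.
#' @export
cohort_betas <- function(cohort, include_intercept = FALSE) {
  subs <- split_subjects(cohort)
  rows <- lapply(names(subs), function(id) {
    b <- tryCatch(
      fit_valence_betas(subs[[id]], include_intercept = include_intercept),
      error = function(e) stop("subject ", id, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    data.frame(subject_id = id, group = b$group, beta_pos = b$beta_pos,
               beta_neg = b$beta_neg, bias = b$bias,
               n_pos_trials = b$n_pos_trials, n_neg_trials = b$n_neg_trials,
               residual_sd = b$residual_sd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
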