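#' Single-subject mediation path decomposition
#'
#' Three OLS regressions on one subject's trial series: path `a` is the
#' slope of mediator on predictor (`M ~ X`), paths `b` and `c_prime` come
#' from the outcome on mediator and predictor jointly (`Y ~ M + X`), and
#' the total effect `c` from `Y ~ X`; all with intercepts. The indirect
#' (mediated) effect is the product `ab = a * b`, and the OLS identity
#' `c = c_prime + ab` holds exactly on common trials. By default X, M and
#' Y are z-scored within subject so paths are comparable across subjects.
#'
#' @param x Per-trial predictor (e.g., feedback mismatch).
#' @param m Per-trial mediator amplitude (one region).
#' @param y Per-trial outcome (e.g., T2 - T1 self-evaluation change).
#' @param standardize Z-score x, m, y within subject (default TRUE).
#' @return Object of class `mediation_paths`: `a`, `b`, `c`, `c_prime`,
#'   `ab`, `n_trials`.
#' @export
subject_paths <- function(x, m, y, standardize = TRUE) {
  n <- length(x)
  if (length(m) != n || length(y) != n || n < 8) {
    stop("x, m, y must have equal length >= 8", call. = FALSE)
  }
  if (any(!is.finite(c(x, m, y)))) {
    stop("x, m, y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate input: constant x", call. = FALSE)
  if (stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant mediator or outcome", call. = FALSE)
  }
  if (standardize) {
    x <- zscore(x); m <- zscore(m); y <- zscore(y)
  }
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  a <- sum(xc * mc) / sum(xc^2)
  c_tot <- sum(xc * yc) / sum(xc^2)
  # pivoted QR: a mediator perfectly collinear with x aliases the direct
  # path, whose coefficient is then zero (full mediation)
  bc <- stats::coef(stats::lm.fit(cbind(mc = mc, xc = xc), yc))
  bc[is.na(bc)] <- 0
  structure(
    list(a = a, b = unname(bc["mc"]), c = c_tot, c_prime = unname(bc["xc"]),
         ab = a * unname(bc["mc"]), n_trials = n),
    class = "mediation_paths"
  )
}

#' @export
print.mediation_paths <- function(x, ...) {
  cat(sprintf("Mediation paths (%d trials): a = %.3f, b = %.3f, ab = %.3f, c = %.3f, c' = %.3f\n",
              x$n_trials, x$a, x$b, x$ab, x$c, x$c_prime))
  invisible(x)
}

#' Two-level mediation across subjects
#'
#' First level: [subject_paths()] per subject. Second level
#' (summary-statistics approach): a one-sample t-test across subjects on
#' each of `a`, `b`, `ab`, `c`, `c_prime`, plus a bias-corrected
#' percentile bootstrap (resampling subjects) confidence interval for the
#' mean indirect effect `ab`, whose sampling distribution is non-normal.
#' The result is classified as "suppression" when the mean `ab` is
#' significant and opposes the sign of the mean total effect,
#' "mediation" when significant and sign-consistent, otherwise "none".
#'
#' @param all_series List of per-subject lists/data.frames with elements
#'   `x`, `m`, `y`.
#' @param n_boot Bootstrap resamples for the `ab` CI (0 skips the CI).
#' @param seed Seed for the bootstrap resampling.
#' @param alpha Significance threshold for classification.
#' @param conf_level Bootstrap CI coverage (default 0.95).
#' @param standardize Passed to [subject_paths()].
#' @return Object of class `mediation_group_result`: `paths`
#'   (subjects x 5 matrix), `summary` (per-path mean, t, df, p),
#'   `ab_ci`, `classification`, `n_subjects`, `n_boot`, `seed`.
#' @export
group_mediation <- function(all_series, n_boot = 5000, seed = NULL,
                            alpha = 0.05, conf_level = 0.95,
                            standardize = TRUE) {
  if (length(all_series) < 3) {
    stop("group mediation needs at least 3 subjects", call. = FALSE)
  }
  paths <- t(vapply(all_series, function(s) {
    p <- subject_paths(s$x, s$m, s$y, standardize = standardize)
    c(a = p$a, b = p$b, ab = p$ab, c = p$c, c_prime = p$c_prime)
  }, numeric(5)))
  rownames(paths) <- names(all_series)

  smry <- do.call(rbind, lapply(colnames(paths), function(pn) {
    v <- paths[, pn]
    tt <- stats::t.test(v)
    data.frame(path = pn, mean = mean(v), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))

  ab_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ab <- paths[, "ab"]
    n <- length(ab)
    boot_means <- vapply(seq_len(n_boot),
                         function(i) mean(ab[sample.int(n, n, replace = TRUE)]),
                         numeric(1))
    # bias-corrected percentile interval
    prop_below <- mean(boot_means < mean(ab))
    prop_below <- min(max(prop_below, 1 / n_boot), 1 - 1 / n_boot)
    z0 <- stats::qnorm(prop_below)
    zq <- stats::qnorm(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    probs <- stats::pnorm(2 * z0 + zq)
    ab_ci <- unname(stats::quantile(boot_means, probs, type = 7))
  }

  mean_ab <- smry$mean[smry$path == "ab"]
  p_ab <- smry$p[smry$path == "ab"]
  mean_c <- smry$mean[smry$path == "c"]
  classification <- if (p_ab < alpha) {
    if (sign(mean_ab) != sign(mean_c)) "suppression" else "mediation"
  } else "none"

  structure(
    list(paths = paths, summary = smry, ab_ci = ab_ci,
         classification = classification, n_subjects = nrow(paths),
         n_boot = n_boot, seed = seed, alpha = alpha,
         conf_level = conf_level),
    class = "mediation_group_result"
  )
}

#' @export
print.mediation_group_result <- function(x, ...) {
  cat(sprintf("Two-level mediation, %d subjects (%s)\n",
              x$n_subjects, x$classification))
  print(transform(x$summary, mean = round(mean, 3), t = round(t, 2),
                  p = signif(p, 3)), row.names = FALSE)
  if (!any(is.na(x$ab_ci))) {
    cat(sprintf("  bootstrap %.0f%% CI for mean ab: [%.4f, %.4f] (%d resamples)\n",
                100 * x$conf_level, x$ab_ci[1], x$ab_ci[2], x$n_boot))
  }
  invisible(x)
}

#' Build per-subject mediation series from a cohort
#'
#' Extracts, for one mediator region, the trial series the mediation
#' analysis consumes: `x = delta_eval`, `m = mediator_<region>`,
#' `y = self_eval_t2_val - self_eval_t1_val`.
#'
#' @param cohort A `cohort` or long trial data.frame.
#' @param region Region index (1-based).
#' @return Named list of per-subject lists with `x`, `m`, `y`.
#' @export
mediation_series <- function(cohort, region = 1) {
  col <- paste0("mediator_", region)
  trials <- if (inherits(cohort, "cohort")) cohort$trials else cohort
  if (!col %in% names(trials)) {
    stop("no such mediator column: ", col, call. = FALSE)
  }
  lapply(split_subjects(trials), function(s) {
    list(x = s$delta_eval, m = s[[col]],
         y = s$self_eval_t2_val - s$self_eval_t1_val)
  })
}

#' Conjunction across mediation paths
#'
#' Returns the regions whose `a`, `b` and `ab` paths are all significant
#' at `alpha`; optionally also requiring the indirect effect to share the
#' sign of the total effect (excluding suppression-style regions).
#'
#' @param results Named list of `mediation_group_result`s, one per region.
#' @param alpha Significance threshold.
#' @param sign_consistent Require `sign(mean ab) == sign(mean c)`.
#' @return Character vector of region names passing the conjunction.
#' @export
conjunction <- function(results, alpha = 0.05, sign_consistent = FALSE) {
  if (length(results) < 1) stop("need at least one region", call. = FALSE)
  if (is.null(names(results))) {
    names(results) <- paste0("region_", seq_along(results))
  }
  keep <- vapply(results, function(r) {
    s <- r$summary
    pv <- function(pn) s$p[s$path == pn]
    mv <- function(pn) s$mean[s$path == pn]
    ok <- pv("a") < alpha && pv("b") < alpha && pv("ab") < alpha
    if (ok && sign_consistent) ok <- sign(mv("ab")) == sign(mv("c"))
    ok
  }, logical(1))
  names(results)[keep]
}
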