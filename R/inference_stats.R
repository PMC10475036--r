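#' Cohen's d from a Welch t statistic
#'
#' Independent-samples convention: `d = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param t Welch t statistic.
#' @param n1,n2 Group sizes.
#' @return Cohen's d (keeps the sign of `t`).
#' @export
cohen_d_from_welch_t <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Cohen's d from a paired t statistic
#'
#' Paired (d_z) convention: `d = |t| / sqrt(n)`.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return Cohen's d (non-negative).
#' @export
cohen_d_from_paired_t <- function(t, n) {
  stopifnot(n >= 2)
  abs(t) / sqrt(n)
}

#' Welch two-sample t-test with effect size
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value; Cohen's d by the independent-samples conversion
#' `t * sqrt(1/n1 + 1/n2)`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return Object of class `t_test_result`: `t`, `df`, `p`, `d`,
#'   `mean_diff` (`mean(x) - mean(y)`), `n` (`c(n1, n2)`), `kind`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 || any(!is.finite(c(x, y)))) {
    stop("welch_t needs two finite samples of length >= 2", call. = FALSE)
  }
  if (stats::sd(x) <= near_zero(x) && stats::sd(y) <= near_zero(y)) {
    stop("degenerate input: both samples have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  t_stat <- unname(tt$statistic)
  structure(
    list(t = t_stat, df = unname(tt$parameter), p = tt$p.value,
         d = cohen_d_from_welch_t(t_stat, length(x), length(y)),
         mean_diff = mean(x) - mean(y), n = c(length(x), length(y)),
         kind = "welch"),
    class = "t_test_result"
  )
}

#' Paired t-test with effect size
#'
#' Student's t on the paired differences (`df = n - 1`), two-sided
#' p-value; Cohen's d by the within-subject (d_z) convention
#' `|t| / sqrt(n)`.
#'
#' @param x,y Paired numeric samples of equal length >= 2.
#' @return Object of class `t_test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2 || any(!is.finite(c(x, y)))) {
    stop("paired_t needs two finite samples of equal length >= 2",
         call. = FALSE)
  }
  if (stats::sd(x - y) <= near_zero(x - y)) {
    stop("degenerate input: paired differences have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  t_stat <- unname(tt$statistic)
  structure(
    list(t = t_stat, df = unname(tt$parameter), p = tt$p.value,
         d = cohen_d_from_paired_t(t_stat, length(x)),
         mean_diff = mean(x - y), n = length(x), kind = "paired"),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.1f) = %.2f, p = %.4g, Cohen's d = %.2f\n",
              x$kind, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Pearson or Spearman correlation test
#'
#' Thin wrapper around [stats::cor.test()] returning the package's
#' correlation-result container (two-sided p-values).
#'
#' @param x,y Numeric samples of equal length.
#' @param method "pearson" or "spearman".
#' @return Object of class `correlation_result`: `r`, `p`, `kind`, `n`,
#'   `controlled_for` (NA here).
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("correlation_test needs equal-length samples, n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant sample", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, kind = method,
         n = length(x), controlled_for = NA_character_),
    class = "correlation_result"
  )
}

#' Partial Pearson correlation controlling for a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary
#' least squares on `z` (with intercept); the p-value uses a t reference
#' distribution with `n - 3` degrees of freedom.
#'
#' @param x,y Numeric samples of equal length >= 4.
#' @param z Covariate (numeric; a two-level grouping can be passed as a
#'   0/1 indicator).
#' @param label Optional covariate label stored in the result.
#' @return Object of class `correlation_result` with `kind = "partial"`.
#' @export
partial_correlation <- function(x, y, z, label = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4) {
    stop("partial_correlation needs equal-length samples, n >= 4",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("degenerate input: constant sample or covariate", call. = FALSE)
  }
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  df <- n - 3
  if (stats::sd(rx) <= 1e-10 * stats::sd(x) ||
      stats::sd(ry) <= 1e-10 * stats::sd(y)) {
    # a variable fully explained by the covariate has nothing left to
    # correlate; the numerically-zero residuals would give arbitrary r
    r <- 0
    p <- 1
  } else {
    r <- stats::cor(rx, ry)
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(r = r, p = p, kind = "partial", n = n,
         controlled_for = if (is.null(label)) deparse(substitute(z)) else label),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  extra <- if (identical(x$kind, "partial"))
    sprintf(" (controlling for %s)", x$controlled_for) else ""
  cat(sprintf("%s correlation%s: r = %.2f, p = %.4g, n = %d\n",
              x$kind, extra, x$r, x$p, x$n))
  invisible(x)
}

#' Fisher z transform
#'
#' `arctanh(r)`; variance-stabilizing transform for correlation
#' coefficients, odd and strictly increasing.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' Robust regression by iteratively reweighted least squares
#'
#' Huber M-estimation (tuning constant 1.345, MAD residual scale
#' re-estimated each iteration) via [MASS::rlm()]; with clean Gaussian
#' data the estimates reduce toward ordinary least squares, while gross
#' outliers are down-weighted. Non-convergence within `max_iter`
#' iterations is flagged, not an error; the last iterate is returned.
#'
#' @param x Design matrix (or vector for a single predictor).
#' @param y Response vector.
#' @param intercept Prepend an intercept column (default TRUE).
#' @param psi Weight family: "huber" (default) or "bisquare".
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficients.
#' @return Object of class `robust_fit`: `coefficients`, `weights`,
#'   `scale`, `fitted`, `residuals`, `converged`, `psi`.
#' @export
robust_regression <- function(x, y, intercept = TRUE,
                              psi = c("huber", "bisquare"),
                              max_iter = 50, tol = 1e-8) {
  psi <- match.arg(psi)
  X <- as.matrix(x)
  if (intercept) X <- cbind(intercept = 1, X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < ncol(X) + 1) {
    stop("need at least one more observation than coefficients", call. = FALSE)
  }
  psifun <- switch(psi, huber = MASS::psi.huber, bisquare = MASS::psi.bisquare)
  fit <- MASS::rlm(X, y, psi = psifun, scale.est = "MAD",
                   maxit = max_iter, acc = tol)
  structure(
    list(coefficients = stats::coef(fit), weights = fit$w, scale = fit$s,
         fitted = fit$fitted.values, residuals = fit$residuals,
         converged = fit$converged, psi = psi),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Robust (%s IRLS) regression%s\n", x$psi,
              if (x$converged) "" else " [did not converge]"))
  print(round(x$coefficients, 4))
  invisible(x)
}
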