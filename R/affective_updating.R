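#' Asymmetric Rescorla-Wagner self-esteem trajectory
#'
#' State self-esteem starts at `prior` and after each trial moves toward
#' the valence of the current feedback by a fraction of the affective
#' prediction error (APE): `Feeling(t) = Feeling(t-1) + alpha * APE`,
#' `APE = v_feedback(t) - Feeling(t-1)`, with `alpha = alpha_pos` when
#' APE > 0 and `alpha_neg` when APE < 0 (an APE of exactly zero updates
#' nothing under either branch). Each step is a convex move toward a value
#' in \[0, 1\], so the trajectory is bounded for any learning rates in
#' \[0, 1\].
#'
#' @param params List with `prior`, `alpha_pos`, `alpha_neg`, each in
#'   \[0, 1\].
#' @param v_feedback Valence-coded feedback sequence in \[0, 1\].
#' @return Numeric vector of post-update self-esteem values, one per
#'   trial (the value compared against the rating given at the end of that
#'   trial).
#' @export
predict_trajectory <- function(params, v_feedback) {
  if (any(!is.finite(v_feedback)) || any(v_feedback < 0 | v_feedback > 1)) {
    stop("v_feedback values must lie in [0, 1]", call. = FALSE)
  }
  for (p in c("prior", "alpha_pos", "alpha_neg")) {
    if (!is_prob_scalar(params[[p]])) {
      stop(p, " must be a single value in [0, 1]", call. = FALSE)
    }
  }
  n <- length(v_feedback)
  out <- numeric(n)
  f <- params$prior
  ap <- params$alpha_pos
  an <- params$alpha_neg
  for (t in seq_len(n)) {
    ape <- v_feedback[t] - f
    f <- f + (if (ape > 0) ap else an) * ape
    out[t] <- f
  }
  out
}

# SSE of the asymmetric RW prediction against observed ratings; NA ratings
# are dropped from the error but the recursion still advances on their
# feedback.
rw_sse <- function(par, self_esteem, v_feedback, n_rates) {
  # optim's finite-difference gradient probes par +/- ndeps, which can sit
  # a hair outside the box at active bounds; evaluate at the projection
  par <- clip01(par)
  params <- if (n_rates == 2L) {
    list(prior = par[1], alpha_pos = par[2], alpha_neg = par[3])
  } else {
    list(prior = par[1], alpha_pos = par[2], alpha_neg = par[2])
  }
  pred <- predict_trajectory(params, v_feedback)
  sum((self_esteem - pred)^2, na.rm = TRUE)
}

#' Fit the asymmetric Rescorla-Wagner model by constrained least squares
#'
#' Minimizes the sum of squared errors between the observed self-esteem
#' time course and the model trajectory, with all parameters constrained
#' to \[0, 1\]. Because local optima are real for the asymmetric model,
#' bound-constrained local searches (`optim` L-BFGS-B) are launched from a
#' grid of starts (`{0.1, 0.5, 0.9}` per free parameter) and the best
#' solution is kept. The one-rate variant shares a single learning rate
#' across both prediction-error signs.
#'
#' Missing self-esteem ratings are dropped from the error term, but the
#' recursion still advances on their feedback. An all-constant rating
#' series is returned directly as `prior = constant`, learning rates 0,
#' with `constant_series = TRUE`.
#'
#' @param self_esteem Observed ratings in \[0, 1\] (NA allowed).
#' @param v_feedback Valence-coded feedback, same length, in \[0, 1\].
#' @param n_rates 2 (valence-specific rates) or 1 (shared rate).
#' @param starts Grid values for each free parameter's starting points.
#' @return Object of class `rw_fit`: list with `params` (`prior`,
#'   `alpha_pos`, `alpha_neg`), `n_rates`, `n_free_params`, `sse`, `bic`,
#'   `n_obs`, `predicted`, `converged`, `n_starts_used`,
#'   `constant_series`.
#' @export
fit_rw <- function(self_esteem, v_feedback, n_rates = 2,
                   starts = c(0.1, 0.5, 0.9)) {
  if (length(self_esteem) != length(v_feedback)) {
    stop("self_esteem and v_feedback must have the same length", call. = FALSE)
  }
  if (length(self_esteem) < 5) {
    stop("need at least 5 trials to fit the updating model", call. = FALSE)
  }
  n_rates <- as.integer(n_rates)
  if (!n_rates %in% c(1L, 2L)) stop("n_rates must be 1 or 2", call. = FALSE)
  obs <- self_esteem
  ok <- !is.na(obs)
  if (any(obs[ok] < 0 | obs[ok] > 1)) {
    stop("self_esteem values must lie in [0, 1]", call. = FALSE)
  }
  n_obs <- sum(ok)
  k <- if (n_rates == 2L) 3L else 2L

  finish <- function(par, converged, n_starts, constant = FALSE) {
    par <- clip01(par)
    params <- list(
      prior = unname(par[1]),
      alpha_pos = unname(par[2]),
      alpha_neg = unname(if (n_rates == 2L) par[3] else par[2])
    )
    pred <- predict_trajectory(params, v_feedback)
    sse <- sum((obs - pred)^2, na.rm = TRUE)
    structure(
      list(params = params, n_rates = n_rates, n_free_params = k, sse = sse,
           bic = bic_sse(sse, n_obs, k), n_obs = n_obs, predicted = pred,
           converged = converged, n_starts_used = n_starts,
           constant_series = constant),
      class = "rw_fit"
    )
  }

  if (stats::sd(obs[ok]) == 0) {
    par <- c(obs[ok][1], rep(0, k - 1L))
    return(finish(par, converged = TRUE, n_starts = 0L, constant = TRUE))
  }

  grid <- do.call(expand.grid, rep(list(starts), k))
  best <- NULL
  best_sse <- Inf
  best_conv <- FALSE
  for (i in seq_len(nrow(grid))) {
    p0 <- as.numeric(grid[i, ])
    res <- stats::optim(
      p0, rw_sse, method = "L-BFGS-B", lower = rep(0, k), upper = rep(1, k),
      control = list(factr = 1e3, pgtol = 1e-10, maxit = 500),
      self_esteem = obs, v_feedback = v_feedback, n_rates = n_rates
    )
    if (res$value < best_sse) {
      best_sse <- res$value
      best <- res$par
      best_conv <- res$convergence == 0
    }
  }
  finish(best, converged = best_conv, n_starts = nrow(grid))
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf("Asymmetric RW fit (%d-rate, %d observed trials)\n",
              x$n_rates, x$n_obs))
  cat(sprintf("  prior = %.4f, alpha_pos = %.4f, alpha_neg = %.4f\n",
              x$params$prior, x$params$alpha_pos, x$params$alpha_neg))
  cat(sprintf("  SSE = %.6g, BIC = %.3f%s\n", x$sse, x$bic,
              if (x$constant_series) " (constant rating series)" else ""))
  invisible(x)
}

#' Gaussian least-squares BIC
#'
#' `n * ln(SSE/n) + k * ln(n)`: the Bayesian Information Criterion for a
#' least-squares fit under Gaussian errors with the noise variance
#' profiled out. `k` counts the prior plus the learning rate(s); because
#' the profiled variance is excluded identically from both model variants,
#' only the comparison matters. Lower is better. A perfect fit
#' (`sse = 0`) returns `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @param sse Sum of squared errors (>= 0).
#' @param n_obs Number of observations (> k).
#' @param k Number of free parameters (>= 1).
#' @return BIC value (scalar).
#' @export
bic_sse <- function(sse, n_obs, k) {
  if (!is.numeric(sse) || length(sse) != 1L || sse < 0) {
    stop("sse must be a single non-negative number", call. = FALSE)
  }
  if (!is_count(k, 1L) || !is_count(n_obs, 1L) || n_obs <= k) {
    stop("need n_obs > k >= 1", call. = FALSE)
  }
  if (sse == 0) return(structure(-Inf, perfect_fit = TRUE))
  n_obs * log(sse / n_obs) + k * log(n_obs)
}

#' Affective updating bias of a two-rate fit
#'
#' `alpha_pos - alpha_neg`: positive values mean self-esteem is updated
#' more by positive than negative prediction errors.
#'
#' @param fit An `rw_fit` with `n_rates = 2`.
#' @return Signed rate difference in \[-1, 1\].
#' @export
updating_bias <- function(fit) {
  stopifnot(inherits(fit, "rw_fit"))
  if (fit$n_rates != 2L) {
    stop("updating bias is only defined for a two-rate fit", call. = FALSE)
  }
  fit$params$alpha_pos - fit$params$alpha_neg
}

#' Fit the updating model for every subject in a cohort
#'
#' Fits both the two-rate and one-rate variants per subject and reports
#' the BIC comparison at the subject level as well as the summed-BIC
#' comparison across the cohort (as attributes `bic_sum_1rate`,
#' `bic_sum_2rate`).
#'
#' @param cohort A `cohort` or long trial data.frame with columns
#'   `self_esteem`, `v_feedback`, `subject_id`.
#' @return data.frame, one row per subject: `subject_id`, `group`,
#'   `prior`, `alpha_pos`, `alpha_neg`, `updating_bias`, `sse`,
#'   `bic_2rate`, `bic_1rate`, `preferred` ("2rate"/"1rate").
#' @export
cohort_rw <- function(cohort) {
  subs <- split_subjects(cohort)
  rows <- lapply(names(subs), function(id) {
    s <- subs[[id]]
    f2 <- fit_rw(s$self_esteem, s$v_feedback, n_rates = 2)
    f1 <- fit_rw(s$self_esteem, s$v_feedback, n_rates = 1)
    data.frame(
      subject_id = id,
      group = if ("group" %in% names(s)) s$group[1] else NA_character_,
      prior = f2$params$prior, alpha_pos = f2$params$alpha_pos,
      alpha_neg = f2$params$alpha_neg, updating_bias = updating_bias(f2),
      sse = f2$sse, bic_2rate = as.numeric(f2$bic),
      bic_1rate = as.numeric(f1$bic),
      preferred = if (f2$bic < f1$bic) "2rate" else "1rate",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bic_sum_2rate") <- sum(out$bic_2rate)
  attr(out, "bic_sum_1rate") <- sum(out$bic_1rate)
  out
}
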