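#' Default mediator path strengths
#'
#' One `(a_strength, b_strength)` pair per synthetic brain region, in
#' standardized units. The default four regions span the design cells
#' needed for mediation testing: a full mediator (a and b), an a-only
#' region, a b-only region, and a null region.
#'
#' @param n_regions Number of regions.
#' @return A data.frame with columns `a_strength`, `b_strength`.
#' @export
default_region_paths <- function(n_regions = 4) {
  data.frame(
    a_strength = rep(c(0.5, 0.5, 0, 0), length.out = n_regions),
    b_strength = rep(c(0.5, 0, 0.5, 0), length.out = n_regions)
  )
}

#' Default group parameter distributions
#'
#' Per-group means and SDs for the ground-truth subject parameters.
#' The socially anxious (SAD-like) group has a lower prior self-esteem,
#' a negative affective-updating asymmetry (`alpha_neg > alpha_pos`) and a
#' negative social-influence asymmetry (`beta_neg > beta_pos`); the
#' control-like (HC) group shows the reverse pattern. Magnitudes are
#' configuration, not estimates.
#'
#' @return A named list (`SAD`, `HC`); each element is a list of
#'   `c(mean, sd)` pairs for `beta_pos`, `beta_neg`, `prior`, `alpha_pos`,
#'   `alpha_neg`, `trait_eval_mean`.
#' @export
default_group_params <- function() {
  list(
    SAD = list(
      beta_pos = c(mean = 0.40, sd = 0.15),
      beta_neg = c(mean = 0.55, sd = 0.15),
      prior = c(mean = 0.40, sd = 0.15),
      alpha_pos = c(mean = 0.25, sd = 0.15),
      alpha_neg = c(mean = 0.35, sd = 0.15),
      trait_eval_mean = c(mean = 0.45, sd = 0.10)
    ),
    HC = list(
      beta_pos = c(mean = 0.55, sd = 0.15),
      beta_neg = c(mean = 0.45, sd = 0.15),
      prior = c(mean = 0.55, sd = 0.15),
      alpha_pos = c(mean = 0.40, sd = 0.15),
      alpha_neg = c(mean = 0.25, sd = 0.15),
      trait_eval_mean = c(mean = 0.55, sd = 0.10)
    )
  )
}

#' Synthetic-cohort generator configuration
#'
#' Bundles every knob of the task emulation: trial counts, group sizes,
#' noise magnitudes (all in VAS units on the 0-1 scale unless noted),
#' mediator path strengths (standardized units) and the per-group
#' ground-truth parameter distributions.
#'
#' @param n_trials Trials per subject (default 52).
#' @param n_subjects_per_group Named integer vector, subjects per group
#'   (default `c(SAD = 21, HC = 23)`).
#' @param mismatch_sd SD of the feedback mismatch draw, VAS units.
#' @param rating_noise_sd Trial-to-trial SD of T1 self-evaluations around
#'   the subject's trait mean.
#' @param esteem_noise_sd Observation noise on the state self-esteem
#'   ratings around the model trajectory.
#' @param t2_noise_sd Noise on the T2 re-evaluation.
#' @param n_regions Number of synthetic mediator regions.
#' @param region_paths data.frame with `a_strength`, `b_strength` per
#'   region (standardized units); see [default_region_paths()].
#' @param mediator_noise_sd SD of region-specific mediator noise
#'   (standardized units).
#' @param mediator_outcome_scale VAS units gained by the T2 outcome per
#'   standardized unit of (b-weighted) mediator activity.
#' @param group_param_distributions Per-group parameter distributions;
#'   see [default_group_params()].
#' @param seed Master RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_trials = 52,
                             n_subjects_per_group = c(SAD = 21, HC = 23),
                             mismatch_sd = 0.15,
                             rating_noise_sd = 0.05,
                             esteem_noise_sd = 0.05,
                             t2_noise_sd = 0.05,
                             n_regions = 4,
                             region_paths = default_region_paths(n_regions),
                             mediator_noise_sd = 1,
                             mediator_outcome_scale = 0.05,
                             group_param_distributions = default_group_params(),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_trials = as.integer(n_trials),
      n_subjects_per_group = n_subjects_per_group,
      mismatch_sd = mismatch_sd,
      rating_noise_sd = rating_noise_sd,
      esteem_noise_sd = esteem_noise_sd,
      t2_noise_sd = t2_noise_sd,
      n_regions = as.integer(n_regions),
      region_paths = as.data.frame(region_paths),
      mediator_noise_sd = mediator_noise_sd,
      mediator_outcome_scale = mediator_outcome_scale,
      group_param_distributions = group_param_distributions,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  errs <- validate_generator_config(cfg)
  if (length(errs)) {
    stop("invalid generator configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Validate a generator configuration
#'
#' Collects every violation rather than failing on the first.
#'
#' @param config A `generator_config` (or a compatible list).
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_generator_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs[[length(errs) + 1L]] <<- msg
  chk(is_count(config$n_trials, 4L), "n_trials: must be an integer >= 4")
  nspg <- config$n_subjects_per_group
  chk(is.numeric(nspg) && length(nspg) == 2L && all(nspg >= 2) &&
        all(nspg == round(nspg)) && !is.null(names(nspg)) &&
        !anyDuplicated(names(nspg)),
      "n_subjects_per_group: must be two named group sizes, each >= 2")
  for (fld in c("mismatch_sd", "rating_noise_sd", "esteem_noise_sd",
                "t2_noise_sd", "mediator_noise_sd")) {
    v <- config[[fld]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0,
        paste0(fld, ": must be a single non-negative number"))
  }
  chk(is.numeric(config$mediator_outcome_scale) &&
        is.finite(config$mediator_outcome_scale),
      "mediator_outcome_scale: must be a finite number")
  chk(is_count(config$n_regions, 0L), "n_regions: must be a non-negative integer")
  rp <- config$region_paths
  chk(is.data.frame(rp) && all(c("a_strength", "b_strength") %in% names(rp)) &&
        nrow(rp) == config$n_regions,
      "region_paths: must have columns a_strength, b_strength and n_regions rows")
  gpd <- config$group_param_distributions
  if (is.list(gpd) && !is.null(names(gpd)) && is.numeric(nspg) &&
      !is.null(names(nspg)) && !all(names(nspg) %in% names(gpd))) {
    chk(FALSE, paste0("n_subjects_per_group: group labels must match ",
                      "group_param_distributions (",
                      paste(names(gpd), collapse = ", "), ")"))
  }
  if (is.list(gpd) && length(gpd) == 2L) {
    for (g in names(gpd)) {
      for (par in c("beta_pos", "beta_neg", "prior", "alpha_pos", "alpha_neg",
                    "trait_eval_mean")) {
        v <- gpd[[g]][[par]]
        ok <- is.numeric(v) && length(v) == 2L && all(is.finite(v)) && v[2] >= 0
        chk(ok, sprintf("group_param_distributions$%s$%s: need c(mean, sd), sd >= 0",
                        g, par))
        if (ok && par != "trait_eval_mean") {
          chk(v[1] >= 0 && v[1] <= 1,
              sprintf("group_param_distributions$%s$%s: mean must lie in [0, 1]",
                      g, par))
        }
      }
    }
  } else {
    chk(FALSE, "group_param_distributions: must be a list of two groups")
  }
  chk(is_count(config$seed, 0L), "seed: must be a non-negative integer")
  errs
}

#' Draw judge feedback around a self-evaluation
#'
#' Feedback is drawn from a zero-mean Gaussian mismatch distribution
#' centred on the (valence-coded) self-evaluation and clipped to the VAS
#' bounds. Mismatches that come out exactly zero (possible at the scale
#' bounds after clipping) are redrawn once so every trial remains
#' sign-classifiable; the guard is disabled when `mismatch_sd = 0`.
#' Uses the current R RNG state.
#'
#' @param self_eval_val Valence-coded self-evaluation(s) in \[0, 1\].
#' @param mismatch_sd Mismatch SD in VAS units (>= 0).
#' @return A list with `feedback_val` and `delta_eval`
#'   (`feedback_val - self_eval_val`), each the length of the input.
#' @export
draw_feedback <- function(self_eval_val, mismatch_sd) {
  if (!is.numeric(self_eval_val) || any(!is.finite(self_eval_val)) ||
      any(self_eval_val < 0 | self_eval_val > 1)) {
    stop("self_eval_val must lie in [0, 1]", call. = FALSE)
  }
  if (!(is.numeric(mismatch_sd) && length(mismatch_sd) == 1L && mismatch_sd >= 0)) {
    stop("mismatch_sd must be a single non-negative number", call. = FALSE)
  }
  n <- length(self_eval_val)
  m <- stats::rnorm(n, 0, mismatch_sd)
  fb <- clip01(self_eval_val + m)
  delta <- fb - self_eval_val
  if (mismatch_sd > 0 && any(delta == 0)) {
    zero <- which(delta == 0)
    m2 <- stats::rnorm(length(zero), 0, mismatch_sd)
    fb2 <- clip01(self_eval_val[zero] + m2)
    d2 <- fb2 - self_eval_val[zero]
    # still stuck at a bound: reflect the draw inward
    stuck <- d2 == 0
    if (any(stuck)) {
      fb2[stuck] <- clip01(self_eval_val[zero][stuck] - m2[stuck])
      d2 <- fb2 - self_eval_val[zero]
    }
    fb[zero] <- fb2
    delta[zero] <- d2
  }
  list(feedback_val = fb, delta_eval = delta)
}

# Sign-stratified feedback for cohort generation: exactly half the trials
# (shuffled) get a positive mismatch, magnitudes are half-normal, so the
# marginal mismatch distribution matches the plain Gaussian draw while the
# per-subject sign count is balanced by construction.
balanced_feedback <- function(self_eval_val, mismatch_sd) {
  n <- length(self_eval_val)
  sgn <- sample(rep(c(1, -1), c(ceiling(n / 2), floor(n / 2))))
  mag <- abs(stats::rnorm(n, 0, mismatch_sd))
  fb <- clip01(self_eval_val + sgn * mag)
  delta <- fb - self_eval_val
  if (mismatch_sd > 0 && any(delta == 0)) {
    zero <- which(delta == 0)
    mag2 <- abs(stats::rnorm(length(zero), 0, mismatch_sd))
    fb2 <- clip01(self_eval_val[zero] + sgn[zero] * mag2)
    d2 <- fb2 - self_eval_val[zero]
    stuck <- d2 == 0
    if (any(stuck)) {
      # bound-pinned rating: flip this trial's sign to point inward
      fb2[stuck] <- clip01(self_eval_val[zero][stuck] - sgn[zero][stuck] * mag2[stuck])
      d2 <- fb2 - self_eval_val[zero]
    }
    fb[zero] <- fb2
    delta[zero] <- d2
  }
  list(feedback_val = fb, delta_eval = delta)
}

#' Simulate one subject's task data
#'
#' Applies the generative model forward: T1 self-evaluations scatter
#' around the subject's trait mean; judge feedback is drawn around the
#' valence-coded T1 rating with balanced mismatch signs; state self-esteem
#' follows the asymmetric Rescorla-Wagner recursion
#' (via [predict_trajectory()]) plus observation noise; the T2
#' re-evaluation moves from T1 by `beta_pos` (positive mismatch) or
#' `beta_neg` (negative mismatch) times the mismatch, plus b-weighted
#' mediator activity and noise. Region mediators are
#' `a_r * z(delta_eval) + noise`. All ratings are clipped to \[0, 1\].
#'
#' Ratings of negatively worded cues are stored both raw and recoded to a
#' favorability scale (`1 - rating`), so that positive `delta_eval` always
#' means "judges viewed me more favorably than I viewed myself".
#'
#' @param params Named list with `subject_id`, `group`, `beta_pos`,
#'   `beta_neg`, `prior`, `alpha_pos`, `alpha_neg`, `trait_eval_mean`.
#' @param config A [generator_config()].
#' @param seed Optional integer seed for this subject's RNG substream.
#' @return A data.frame of `config$n_trials` trial records.
#' @export
simulate_subject <- function(params, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  n_pos_cue <- ceiling(n / 2)
  wording <- sample(rep(c("positive", "negative"), c(n_pos_cue, n - n_pos_cue)))
  t1_val <- clip01(stats::rnorm(n, params$trait_eval_mean, config$rating_noise_sd))
  fb <- balanced_feedback(t1_val, config$mismatch_sd)
  fb_val <- fb$feedback_val
  delta <- fb$delta_eval
  v_fb <- fb_val # valence of feedback: the recoded feedback value itself

  traj <- predict_trajectory(
    list(prior = params$prior, alpha_pos = params$alpha_pos,
         alpha_neg = params$alpha_neg),
    v_fb
  )
  esteem <- clip01(traj + stats::rnorm(n, 0, config$esteem_noise_sd))

  n_regions <- config$n_regions
  med_term <- 0
  mediators <- NULL
  if (n_regions > 0) {
    sd_d <- stats::sd(delta)
    z_delta <- if (sd_d > 0) (delta - mean(delta)) / sd_d else rep(0, n)
    eps <- matrix(stats::rnorm(n * n_regions, 0, config$mediator_noise_sd),
                  n, n_regions)
    mediators <- outer(z_delta, config$region_paths$a_strength) + eps
    colnames(mediators) <- paste0("mediator_", seq_len(n_regions))
    med_term <- config$mediator_outcome_scale *
      as.vector(mediators %*% config$region_paths$b_strength)
  }
  beta_term <- ifelse(delta > 0, params$beta_pos, params$beta_neg) * delta
  t2_val <- clip01(t1_val + beta_term + med_term +
                     stats::rnorm(n, 0, config$t2_noise_sd))

  neg <- wording == "negative"
  flip <- function(v) ifelse(neg, 1 - v, v)
  out <- data.frame(
    subject_id = params$subject_id,
    group = params$group,
    trial_index = seq_len(n),
    cue_id = sprintf("cue_%02d", seq_len(n)),
    cue_wording = wording,
    self_eval_t1 = flip(t1_val),
    feedback_raw = flip(fb_val),
    self_eval_t1_val = t1_val,
    feedback_val = fb_val,
    delta_eval = delta,
    v_feedback = v_fb,
    self_esteem = esteem,
    self_eval_t2 = flip(t2_val),
    self_eval_t2_val = t2_val,
    stringsAsFactors = FALSE
  )
  if (!is.null(mediators)) out <- cbind(out, as.data.frame(mediators))
  out
}

#' Generate a synthetic cohort
#'
#' Draws ground-truth parameters for every subject from the configured
#' group distributions (Gaussian, clipped to \[0, 1\]), then simulates each
#' subject on an independent RNG substream derived from the master seed,
#' so cohorts are reproducible even under subject-level parallelism.
#'
#' @param config A [generator_config()].
#' @return An object of class `cohort`: list with `trials` (long
#'   data.frame, one row per trial), `ground_truth` (one row per subject)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  errs <- validate_generator_config(config)
  if (length(errs)) {
    stop("invalid generator configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  set.seed(config$seed)
  groups <- rep(names(config$n_subjects_per_group), config$n_subjects_per_group)
  n_total <- length(groups)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  gt <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- groups[i]
    dist <- config$group_param_distributions[[g]]
    draw <- function(par) clip01(stats::rnorm(1, dist[[par]][1], dist[[par]][2]))
    gt[[i]] <- data.frame(
      subject_id = sprintf("%s_%02d", tolower(g), i),
      group = g,
      beta_pos = draw("beta_pos"),
      beta_neg = draw("beta_neg"),
      prior = draw("prior"),
      alpha_pos = draw("alpha_pos"),
      alpha_neg = draw("alpha_neg"),
      trait_eval_mean = draw("trait_eval_mean"),
      seed = subject_seeds[i],
      stringsAsFactors = FALSE
    )
  }
  ground_truth <- do.call(rbind, gt)

  trials <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    p <- as.list(ground_truth[i, ])
    simulate_subject(p, config, seed = subject_seeds[i])
  }))
  rownames(trials) <- NULL
  structure(list(trials = trials, ground_truth = ground_truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$ground_truth$group)
  cat("Synthetic feedback-task cohort\n")
  cat(sprintf("  %d subjects (%s), %d trials each\n",
              nrow(x$ground_truth),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              x$config$n_trials))
  cat(sprintf("  %d mediator regions, master seed %d\n",
              x$config$n_regions, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes the long trial table as a tidy CSV (`cohort_trials.csv`) and the
#' ground-truth parameters plus configuration as a sidecar JSON
#' (`cohort_ground_truth.json`). Round-trips losslessly through
#' [read_cohort()] up to double-precision printing (17 significant
#' digits).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  csv <- file.path(dir, "cohort_trials.csv")
  json <- file.path(dir, "cohort_ground_truth.json")
  utils::write.csv(format_full(cohort$trials), csv, row.names = FALSE,
                   quote = FALSE)
  cfg <- unclass(cohort$config)
  # named vectors serialize as nameless JSON arrays; keep the group names
  cfg$n_subjects_per_group <- as.list(cfg$n_subjects_per_group)
  jsonlite::write_json(
    list(config = cfg, ground_truth = cohort$ground_truth),
    json, digits = NA, auto_unbox = TRUE, dataframe = "columns"
  )
  invisible(c(trials = csv, ground_truth = json))
}

# print numerics at full double precision for lossless CSV round trips
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_trials.csv` and
#'   `cohort_ground_truth.json`.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cohort_trials.csv")
  json <- file.path(dir, "cohort_ground_truth.json")
  if (!file.exists(csv) || !file.exists(json)) {
    stop("not a cohort directory (missing cohort_trials.csv or ",
         "cohort_ground_truth.json): ", dir, call. = FALSE)
  }
  trials <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  cfg <- meta$config
  config <- generator_config(
    n_trials = cfg$n_trials,
    n_subjects_per_group = unlist(cfg$n_subjects_per_group),
    mismatch_sd = cfg$mismatch_sd,
    rating_noise_sd = cfg$rating_noise_sd,
    esteem_noise_sd = cfg$esteem_noise_sd,
    t2_noise_sd = cfg$t2_noise_sd,
    n_regions = cfg$n_regions,
    region_paths = as.data.frame(cfg$region_paths),
    mediator_noise_sd = cfg$mediator_noise_sd,
    mediator_outcome_scale = cfg$mediator_outcome_scale,
    group_param_distributions = lapply(cfg$group_param_distributions,
                                       function(g) lapply(g, unlist)),
    seed = cfg$seed
  )
  structure(list(trials = trials,
                 ground_truth = as.data.frame(meta$ground_truth),
                 config = config),
            class = "cohort")
}

#' Split a cohort's trials by subject
#'
#' @param cohort A `cohort` or its long trial data.frame.
#' @return Named list of per-subject data.frames, in order of appearance.
#' @export
split_subjects <- function(cohort) {
  trials <- if (inherits(cohort, "cohort")) cohort$trials else cohort
  split(trials, factor(trials$subject_id, levels = unique(trials$subject_id)))
}
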