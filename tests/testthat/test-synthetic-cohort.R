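test_that("default cohort has the study's dimensions and balanced cues", {
  co <- generate_cohort(generator_config(seed = 1))
  expect_equal(nrow(co$ground_truth), 44)
  expect_equal(nrow(co$trials), 44 * 52)
  expect_equal(as.vector(table(co$ground_truth$group)[c("SAD", "HC")]),
               c(21, 23))
  per_sub <- split_subjects(co)
  expect_true(all(vapply(per_sub, nrow, integer(1)) == 52))
  n_pos_cue <- vapply(per_sub, function(s) sum(s$cue_wording == "positive"),
                      integer(1))
  expect_true(all(n_pos_cue == 26))
  # mismatch signs balanced by construction
  n_pos_mm <- vapply(per_sub, function(s) sum(s$delta_eval > 0), integer(1))
  expect_true(all(abs(n_pos_mm - 26) <= 2))
})

test_that("cohorts are deterministic given the seed", {
  co1 <- generate_cohort(small_config(seed = 7))
  co2 <- generate_cohort(small_config(seed = 7))
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$ground_truth, co2$ground_truth)
  co3 <- generate_cohort(small_config(seed = 8))
  expect_false(identical(co1$trials, co3$trials))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(generator_config(n_trials = 2), "n_trials")
  expect_error(generator_config(mismatch_sd = -0.1), "mismatch_sd")
  expect_error(generator_config(n_subjects_per_group = c(SAD = 1, HC = 5)),
               "n_subjects_per_group")
  bad_groups <- default_group_params()
  bad_groups$SAD$alpha_pos <- c(mean = 1.5, sd = 0.1)
  expect_error(generator_config(group_param_distributions = bad_groups),
               "alpha_pos")
})

test_that("zero mismatch SD degenerates to zero mismatch everywhere", {
  co <- generate_cohort(small_config(mismatch_sd = 0))
  expect_true(all(co$trials$delta_eval == 0))
  expect_equal(co$trials$feedback_val, co$trials$self_eval_t1_val)
})

test_that("all VAS fields stay in [0, 1] even under extreme noise", {
  co <- generate_cohort(small_config(seed = 3, mismatch_sd = 0.6,
                                     rating_noise_sd = 0.5,
                                     esteem_noise_sd = 0.5, t2_noise_sd = 0.5))
  vas <- c("self_eval_t1", "feedback_raw", "self_eval_t1_val", "feedback_val",
           "v_feedback", "self_esteem", "self_eval_t2", "self_eval_t2_val")
  for (v in vas) {
    expect_true(all(co$trials[[v]] >= 0 & co$trials[[v]] <= 1), label = v)
  }
  expect_true(all(abs(co$trials$delta_eval) <= 1))
})

test_that("valence recoding flips ratings of negatively worded cues only", {
  co <- generate_cohort(small_config(seed = 2))
  tr <- co$trials
  neg <- tr$cue_wording == "negative"
  expect_equal(tr$self_eval_t1_val[neg], 1 - tr$self_eval_t1[neg])
  expect_equal(tr$feedback_val[neg], 1 - tr$feedback_raw[neg])
  expect_equal(tr$self_eval_t1_val[!neg], tr$self_eval_t1[!neg])
  expect_equal(tr$feedback_val[!neg], tr$feedback_raw[!neg])
  expect_equal(tr$delta_eval, tr$feedback_val - tr$self_eval_t1_val)
})

test_that("positive-mismatch fraction is near one half across many cohorts", {
  fracs <- vapply(1:100, function(s) {
    co <- generate_cohort(
      generator_config(n_subjects_per_group = c(SAD = 2, HC = 2), seed = s))
    mean(vapply(split_subjects(co), function(x) mean(x$delta_eval > 0),
                numeric(1)))
  }, numeric(1))
  expect_gte(mean(fracs), 0.45)
  expect_lte(mean(fracs), 0.55)
})

test_that("draw_feedback recovers the configured mismatch SD", {
  set.seed(42)
  fb <- draw_feedback(rep(0.5, 10000), mismatch_sd = 0.15)
  expect_gte(sd(fb$delta_eval), 0.14)
  expect_lte(sd(fb$delta_eval), 0.16)
  expect_true(all(fb$delta_eval != 0))
  # boundary clipping can only pull feedback inward
  set.seed(43)
  top <- draw_feedback(rep(1, 100), mismatch_sd = 0.2)
  expect_true(all(top$delta_eval <= 0))
  # degenerate sd: no redraw guard, exact zeros allowed
  quiet <- draw_feedback(0.5, mismatch_sd = 0)
  expect_equal(quiet$feedback_val, 0.5)
  expect_equal(quiet$delta_eval, 0)
  expect_error(draw_feedback(1.2, 0.1), "\\[0, 1\\]")
})

test_that("noise-free simulation follows both update equations exactly", {
  cfg <- zero_noise_config()
  # no learning at all: esteem pinned at the prior
  p0 <- subject_params(alpha_pos = 0, alpha_neg = 0, prior = 0.42)
  s0 <- simulate_subject(p0, cfg, seed = 5)
  expect_true(all(s0$self_esteem == 0.42))
  # full adoption of feedback at T2
  p1 <- subject_params(beta_pos = 1, beta_neg = 1)
  s1 <- simulate_subject(p1, cfg, seed = 5)
  expect_equal(s1$self_eval_t2_val, s1$feedback_val, tolerance = 1e-12)
  # full esteem update tracks the feedback valence
  p2 <- subject_params(alpha_pos = 1, alpha_neg = 1)
  s2 <- simulate_subject(p2, cfg, seed = 5)
  expect_equal(s2$self_esteem, s2$v_feedback, tolerance = 1e-12)
})

test_that("cohorts round-trip through CSV + JSON on disk", {
  co <- generate_cohort(small_config(seed = 4))
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort_trials.csv")))
  back <- read_cohort(dir)
  num <- vapply(co$trials, is.numeric, logical(1))
  for (v in names(co$trials)[num]) {
    expect_equal(back$trials[[v]], co$trials[[v]], tolerance = 1e-12, label = v)
  }
  for (v in names(co$trials)[!num]) {
    expect_identical(back$trials[[v]], co$trials[[v]], label = v)
  }
  expect_equal(back$ground_truth$beta_pos, co$ground_truth$beta_pos,
               tolerance = 1e-12)
  expect_equal(nrow(back$ground_truth), 4)
  # regenerating from the stored config reproduces the cohort
  expect_equal(generate_cohort(back$config)$trials$delta_eval,
               co$trials$delta_eval, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("row counts scale with subjects and trials", {
  co <- generate_cohort(
    generator_config(n_trials = 4, n_subjects_per_group = c(SAD = 2, HC = 2),
                     seed = 1))
  expect_equal(nrow(co$trials), 4 * 4)
  # group labels must match the parameter distributions
  expect_error(
    generator_config(n_subjects_per_group = c(A = 2, B = 2)),
    "group labels")
})
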