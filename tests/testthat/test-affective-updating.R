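test_that("trajectory follows the hand-computed recursion", {
  # alpha_pos = 0.5, alpha_neg = 0: 0.5 -> 0.75 -> 0.875 -> 0.875
  traj <- predict_trajectory(list(prior = 0.5, alpha_pos = 0.5, alpha_neg = 0),
                             c(1, 1, 0))
  expect_equal(traj, c(0.75, 0.875, 0.875))
  # zero rates freeze the prior
  expect_equal(predict_trajectory(list(prior = 0.5, alpha_pos = 0,
                                       alpha_neg = 0), runif(10)),
               rep(0.5, 10))
  # unit rates copy the feedback
  expect_equal(predict_trajectory(list(prior = 0.2, alpha_pos = 1,
                                       alpha_neg = 1), c(0.9, 0.1)),
               c(0.9, 0.1))
  expect_error(predict_trajectory(list(prior = 0.5, alpha_pos = 0.3,
                                       alpha_neg = 0.3), c(0.5, 1.2)),
               "\\[0, 1\\]")
})

test_that("trajectories stay in [0, 1] for any parameters in the unit box", {
  set.seed(99)
  for (i in 1:50) {
    params <- list(prior = runif(1), alpha_pos = runif(1),
                   alpha_neg = runif(1))
    traj <- predict_trajectory(params, runif(40))
    expect_true(all(traj >= 0 & traj <= 1))
  }
})

test_that("noise-free trajectories are recovered to high precision", {
  set.seed(17)
  fb <- runif(52)
  true <- list(prior = 0.6, alpha_pos = 0.7, alpha_neg = 0.1)
  obs <- predict_trajectory(true, fb)
  fit <- fit_rw(obs, fb, n_rates = 2)
  expect_lt(abs(fit$params$prior - 0.6), 1e-3)
  expect_lt(abs(fit$params$alpha_pos - 0.7), 1e-3)
  expect_lt(abs(fit$params$alpha_neg - 0.1), 1e-3)
  expect_lt(fit$sse, 1e-10)
  # an (almost) perfect fit has an extremely negative BIC
  expect_lt(fit$bic, bic_sse(1e-10, fit$n_obs, 3))
})

test_that("a constant rating series yields zero rates and zero SSE", {
  fit <- fit_rw(rep(0.4, 20), runif(20), n_rates = 2)
  expect_true(fit$constant_series)
  expect_equal(fit$params$prior, 0.4)
  expect_equal(fit$params$alpha_pos, 0)
  expect_equal(fit$params$alpha_neg, 0)
  expect_equal(fit$sse, 0)
})

test_that("input contracts are enforced", {
  expect_error(fit_rw(runif(10), runif(9), 2), "length")
  expect_error(fit_rw(runif(4), runif(4), 2), "at least 5")
  expect_error(fit_rw(c(0.5, 1.4, 0.5, 0.5, 0.5), runif(5), 2), "\\[0, 1\\]")
})

test_that("missing ratings drop from the SSE but the recursion advances", {
  set.seed(23)
  fb <- runif(52)
  true <- list(prior = 0.5, alpha_pos = 0.6, alpha_neg = 0.2)
  obs <- predict_trajectory(true, fb)
  obs[c(5, 20, 40)] <- NA
  fit <- fit_rw(obs, fb, n_rates = 2)
  expect_equal(fit$n_obs, 49)
  expect_lt(abs(fit$params$alpha_pos - 0.6), 1e-3)
  expect_lt(abs(fit$params$alpha_neg - 0.2), 1e-3)
})

test_that("the two-rate model nests the one-rate model", {
  set.seed(29)
  for (i in 1:10) {
    fb <- runif(30)
    obs <- pmin(1, pmax(0, predict_trajectory(
      list(prior = runif(1), alpha_pos = runif(1), alpha_neg = runif(1)),
      fb) + rnorm(30, 0, 0.05)))
    f2 <- fit_rw(obs, fb, n_rates = 2)
    f1 <- fit_rw(obs, fb, n_rates = 1)
    expect_lte(f2$sse, f1$sse + 1e-10)
  }
})

test_that("multi-start fit beats an exhaustive 0.02-step grid search", {
  set.seed(37)
  grid1 <- seq(0, 1, by = 0.02)
  grid <- as.matrix(expand.grid(prior = grid1, ap = grid1, an = grid1))
  for (rep in 1:20) {
    fb <- runif(10)
    obs <- pmin(1, pmax(0, predict_trajectory(
      list(prior = runif(1), alpha_pos = runif(1), alpha_neg = runif(1)),
      fb) + rnorm(10, 0, 0.1)))
    # vectorized oracle: run the recursion across all grid points at once
    f <- grid[, 1]
    sse <- numeric(nrow(grid))
    for (t in seq_along(fb)) {
      ape <- fb[t] - f
      f <- f + ifelse(ape > 0, grid[, 2], grid[, 3]) * ape
      sse <- sse + (obs[t] - f)^2
    }
    fit <- fit_rw(obs, fb, n_rates = 2)
    expect_lte(fit$sse, min(sse) + 1e-10)
  }
})

test_that("the fit is sequential: shuffling trials changes it", {
  set.seed(41)
  fb <- runif(52)
  obs <- pmin(1, pmax(0, predict_trajectory(
    list(prior = 0.5, alpha_pos = 0.7, alpha_neg = 0.1), fb) +
      rnorm(52, 0, 0.05)))
  f_orig <- fit_rw(obs, fb, n_rates = 2)
  perm <- sample(52)
  f_perm <- fit_rw(obs[perm], fb[perm], n_rates = 2)
  expect_false(isTRUE(all.equal(f_orig$params, f_perm$params,
                                tolerance = 1e-4)))
})

test_that("BIC arithmetic matches the least-squares Gaussian form", {
  expect_equal(bic_sse(52, 52, 2), 2 * log(52))
  expect_equal(bic_sse(52, 52, 3) - bic_sse(52, 52, 2), log(52))
  expect_equal(bic_sse(0.5, 52, 3), 52 * log(0.5 / 52) + 3 * log(52))
  perfect <- bic_sse(0, 52, 3)
  expect_true(is.infinite(perfect) && perfect < 0)
  expect_true(attr(perfect, "perfect_fit"))
  expect_error(bic_sse(1, 2, 2), "n_obs > k")
})

test_that("updating bias is the signed rate difference of a 2-rate fit", {
  set.seed(43)
  fb <- runif(20)
  obs <- predict_trajectory(list(prior = 0.5, alpha_pos = 0.8,
                                 alpha_neg = 0.2), fb)
  f2 <- fit_rw(obs, fb, n_rates = 2)
  expect_equal(updating_bias(f2), 0.6, tolerance = 1e-3)
  f1 <- fit_rw(obs, fb, n_rates = 1)
  expect_error(updating_bias(f1), "two-rate")
})

test_that("cohort_rw reports per-subject and summed BIC comparisons", {
  co <- generate_cohort(small_config(seed = 12))
  rw <- cohort_rw(co)
  expect_equal(nrow(rw), 4)
  # SSE_2rate <= SSE_1rate, so BIC_2rate exceeds BIC_1rate by at most the
  # extra-parameter penalty ln(n)
  expect_true(all(rw$bic_2rate <= rw$bic_1rate + log(12) + 1e-9))
  expect_equal(attr(rw, "bic_sum_2rate"), sum(rw$bic_2rate))
  expect_identical(rw$group, co$ground_truth$group)
  expect_equal(rw$updating_bias, rw$alpha_pos - rw$alpha_neg, tolerance = 1e-12)
})
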