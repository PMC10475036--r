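test_that("welch_t matches stats::t.test and the d conversion", {
  set.seed(1)
  x <- rnorm(21); y <- rnorm(23, 0.5)
  res <- welch_t(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$d, res$t * sqrt(1 / 21 + 1 / 23))
  expect_equal(sign(res$t), sign(res$mean_diff))
  # identical samples: zero statistic and effect
  z <- c(rnorm(10), rnorm(10))
  res0 <- welch_t(z, z)
  expect_equal(res0$t, 0)
  expect_equal(res0$d, 0)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("welch df never exceeds the pooled df and attains it when equal", {
  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    res <- welch_t(rnorm(n1), rnorm(n2, 0, runif(1, 0.2, 3)))
    expect_lte(res$df, n1 + n2 - 2 + 1e-9)
  }
  x <- c(-1, 0, 1, 2)
  y <- c(10, 11, 12, 13) # same spread, same n
  expect_equal(welch_t(x, y)$df, length(x) + length(y) - 2)
})

test_that("paired_t uses df = n - 1 and the d_z convention", {
  set.seed(3)
  x <- rnorm(23); y <- x + rnorm(23, 0.4, 0.5)
  res <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, 22)
  expect_equal(res$d, abs(res$t) / sqrt(23))
  expect_error(paired_t(x, x + 1), "zero variance")
})

test_that("printed effect-size conversions are reproduced to 2 decimals", {
  # between-group conversions at the study's group sizes
  expect_equal(round(cohen_d_from_welch_t(2.15, 21, 23), 2), 0.65)
  expect_equal(round(cohen_d_from_welch_t(1.54, 21, 23), 2), 0.46)
  # within-group conversions
  expect_equal(round(cohen_d_from_paired_t(3.91, 23), 2), 0.82)
  expect_equal(round(cohen_d_from_paired_t(-1.52, 21), 2), 0.33)
  # scanner-subsample network comparisons (16 per group)
  expect_equal(round(cohen_d_from_welch_t(2.23, 16, 16), 2), 0.79)
  expect_equal(round(cohen_d_from_welch_t(2.11, 16, 16), 2), 0.75)
})

test_that("paired d recovers a known standardized effect in simulation", {
  # pairs constructed so x - y has mean 0.5 and SD 1 (true d_z = 0.5)
  set.seed(5)
  d_hat <- replicate(2000, paired_t(rnorm(30, 0.5, 1), rep(0, 30))$d)
  expect_lt(abs(mean(d_hat) - 0.5), 0.05)
})

test_that("partial correlation matches the inverse-correlation-matrix identity", {
  set.seed(6)
  for (i in 1:10) {
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    X <- matrix(rnorm(50 * 3), 50) %*% chol(S)
    x <- X[, 1]; y <- X[, 2]; z <- X[, 3]
    res <- partial_correlation(x, y, z)
    omega <- solve(cor(cbind(x, y, z)))
    r_ref <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
    expect_equal(res$r, r_ref, tolerance = 1e-8)
  }
})

test_that("partial correlation limits: orthogonal and collinear covariates", {
  set.seed(7)
  n <- 64
  z <- rep(c(-1, 1), n / 2)
  x0 <- rnorm(n); y0 <- x0 + rnorm(n)
  # orthogonalize x and y against z exactly
  x <- resid(lm(x0 ~ z)); y <- resid(lm(y0 ~ z))
  expect_equal(partial_correlation(x, y, z)$r, cor(x, y), tolerance = 1e-10)
  # x fully explained by the covariate
  expect_lt(abs(partial_correlation(z, y0, z)$r), 1e-10)
  expect_error(partial_correlation(rep(1, 10), rnorm(10), rnorm(10)),
               "degenerate")
})

test_that("fisher_z is arctanh with its symmetries", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("spearman correlation is invariant under monotone transforms", {
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40)
  r0 <- correlation_test(x, y, "spearman")$r
  expect_equal(correlation_test(exp(x), y, "spearman")$r, r0)
  expect_equal(correlation_test(x, qlogis(plogis(y)), "spearman")$r, r0)
})

test_that("robust regression approaches OLS on clean data with unit weights", {
  set.seed(9)
  x <- rnorm(100)
  y <- 1 + 2 * x + rnorm(100, 0, 0.02)
  rob <- robust_regression(x, y)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(rob$coefficients - ols)), 1e-3)
  # points inside the Huber corner get unit weight
  inside <- abs(rob$residuals) <= 1.345 * rob$scale
  expect_true(all(rob$weights[inside] >= 0.99))
  expect_gt(mean(inside), 0.7)
  expect_true(rob$converged)
})

test_that("robust regression resists a gross outlier better than OLS", {
  set.seed(10)
  wins <- replicate(500, {
    x <- rnorm(50)
    y <- 1 + 2 * x + rnorm(50)
    # gross outlier (10x the residual SD) at the leverage point, where it
    # distorts the OLS slope the most
    y[which.max(abs(x))] <- y[which.max(abs(x))] + 10
    rob <- robust_regression(x, y)$coefficients[2]
    ols <- coef(lm(y ~ x))[2]
    abs(rob - 2) <= abs(ols - 2)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("p-values are uniform under the null (KS sanity check)", {
  set.seed(11)
  p_welch <- replicate(2000, welch_t(rnorm(12), rnorm(12))$p)
  expect_gt(ks.test(p_welch, "punif")$p.value, 0.01)
  p_paired <- replicate(2000, paired_t(rnorm(12), rnorm(12))$p)
  expect_gt(ks.test(p_paired, "punif")$p.value, 0.01)
})
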