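# Member assignment and inverse-variance fusion with variance propagation.

test_that("member assignment is uniform, deterministic and degenerate-safe", {
  expect_equal(assignMembers(7, 1, seed = 3), rep(1L, 7))
  expect_identical(assignMembers(20, 5, seed = 11), assignMembers(20, 5, seed = 11))
  expect_error(assignMembers(0, 5), ">= 1")

  draws <- assignMembers(1e5, 5, seed = 123)
  chisq <- stats::chisq.test(tabulate(draws, 5))
  expect_gt(chisq$p.value, 0.01)
})

test_that("fusion reproduces the hand-worked example and its reductions", {
  fu <- fuseEstimates(c(10, 20), c(1, 4))
  expect_equal(fu$weights[, 1], c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(fu$mean, 12, tolerance = 1e-9)
  expect_equal(fu$variance, 17.6, tolerance = 1e-9)

  # T = 1 collapse
  one <- fuseEstimates(matrix(7.5, 1, 3), matrix(2.25, 1, 3))
  expect_equal(one$mean, rep(7.5, 3))
  expect_equal(one$variance, rep(2.25, 3))

  # equal variances reduce to the arithmetic mean
  mu <- matrix(rnorm(5 * 10, 15), 5)
  eq <- fuseEstimates(mu, matrix(3, 5, 10))
  expect_equal(eq$mean, colMeans(mu), tolerance = 1e-12)

  expect_error(fuseEstimates(c(1, 2), c(1, -1)), "positive")
})

test_that("fusion matches a brute-force weighted-moment oracle", {
  set.seed(42)
  T <- 6; n <- 2000
  mu <- matrix(rnorm(T * n, 15, 8), T)
  s2 <- matrix(exp(rnorm(T * n, 0, 1)), T)
  valid <- matrix(runif(T * n) > 0.2, T)
  valid[, 1] <- TRUE
  fu <- fuseEstimates(mu, s2, valid)
  for (i in sample(which(colSums(valid) > 0), 200)) {
    v <- valid[, i]
    w <- (1 / s2[v, i]) / sum(1 / s2[v, i])
    m <- sum(w * mu[v, i])
    vv <- sum(w * mu[v, i]^2) - m^2 + sum(w * s2[v, i])
    expect_equal(fu$mean[i], m, tolerance = 1e-9)
    expect_equal(fu$variance[i], vv, tolerance = 1e-9)
  }
  ok <- colSums(valid) > 0
  expect_true(all(abs(colSums(fu$weights[, ok, drop = FALSE]) - 1) < 1e-12))
  # bounds and variance decomposition
  mn <- apply(ifelse(valid, mu, Inf), 2, min)
  mx <- apply(ifelse(valid, mu, -Inf), 2, max)
  expect_true(all(fu$mean >= mn - 1e-12 & fu$mean <= mx + 1e-12))
  within <- colSums(fu$weights * ifelse(valid, s2, 0))
  expect_true(all(fu$variance >= within - 1e-12))
})

test_that("inverse-variance fusion beats unweighted averaging in MSE", {
  set.seed(7)
  n <- 1e5; T <- 4
  truth <- runif(n, 0, 40)
  s2 <- matrix(exp(runif(T * n, log(0.25), log(25))), T)
  mu <- matrix(truth, T, n, byrow = TRUE) + matrix(rnorm(T * n), T) * sqrt(s2)
  fused <- fuseEstimates(mu, s2)$mean
  unweighted <- colMeans(mu)
  expect_lt(mean((fused - truth)^2), mean((unweighted - truth)^2))
})

test_that("grid fusion flags pixels with no valid date as nodata", {
  mu <- list(matrix(10, 2, 2), matrix(20, 2, 2))
  s2 <- list(matrix(1, 2, 2), matrix(4, 2, 2))
  va <- list(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
             matrix(c(TRUE, FALSE, TRUE, FALSE), 2))
  pm <- fuseAcquisitions(mu, s2, va)
  expect_s4_class(pm, "PredictiveMap")
  expect_equal(validMask(pm), matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
  expect_equal(predMean(pm)[1, 1], 12)           # both dates -> worked example
  expect_equal(predSd(pm)[1, 1], sqrt(17.6))
  expect_equal(predMean(pm)[2, 1], 10)           # single-date collapse
})
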