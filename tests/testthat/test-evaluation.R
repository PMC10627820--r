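# Accuracy metrics, balanced variants, calibration binning and
# uncertainty-based filtering.

test_that("point metrics match hand-evaluated values", {
  z <- pointMetrics(c(1, 2), c(1, 2))
  expect_equal(c(z@rmse, z@mae, z@me), c(0, 0, 0))

  m <- pointMetrics(c(1, 2), c(2, 2))
  expect_equal(m@me, -0.5)
  expect_equal(m@mae, 0.5)
  expect_equal(m@rmse, sqrt(0.5))
  expect_equal(m@nme, 100 * (-0.5) / 2)

  expect_error(pointMetrics(1:3, 1:2), "equal length")
  expect_error(pointMetrics(numeric(0), numeric(0)), "empty")
  expect_warning(pointMetrics(c(1, -1), c(1, -1)), "NME")
})

test_that("balanced metrics average per-interval metrics unweighted", {
  # all references in one interval: balanced == pointwise
  p <- c(1, 3, 4); r <- c(2, 2, 3)
  b <- balancedMetrics(p, r, interval = 5)
  expect_equal(b@aRMSE, b@rmse)
  expect_equal(b@aME, b@me)

  # two intervals with MEs 0 and -2 average to -1
  p2 <- c(3, 3, 12, 12); r2 <- c(3, 3, 14, 14)
  b2 <- balancedMetrics(p2, r2, interval = 5)
  expect_equal(b2@aME, -1)
  expect_equal(nrow(b2@intervalTable), 2)

  # equally populated intervals with identical errors: aRMSE == RMSE
  p3 <- c(1, 2, 11, 12); r3 <- c(2, 1, 12, 11)
  b3 <- balancedMetrics(p3, r3, interval = 10)
  expect_equal(b3@aRMSE, b3@rmse)
})

test_that("metrics agree with independent literal re-implementations", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:300, 1)
    p <- runif(n, 0, 45); r <- runif(n, 1, 45); u <- runif(n, 0.1, 30)
    m <- pointMetrics(p, r)
    expect_equal(m@rmse, oracle_rmse(p, r), tolerance = 1e-10)
    expect_equal(m@mae, oracle_mae(p, r), tolerance = 1e-10)
    expect_equal(m@me, oracle_me(p, r), tolerance = 1e-10)
    expect_equal(m@nme, oracle_nme(p, r), tolerance = 1e-10)
    K <- sample(1:8, 1)
    cal <- calibrationError(p, u, r, K)
    orc <- oracle_uce(p, u, r, K)
    expect_equal(cal$uce, orc$uce, tolerance = 1e-10)
    expect_equal(cal$auce, orc$auce, tolerance = 1e-10)
  }
})

test_that("calibration binning reductions hold", {
  set.seed(5)
  p <- rnorm(100, 20); r <- rnorm(100, 20); u <- runif(100, 0.5, 4)
  k1 <- calibrationError(p, u, r, K = 1)
  expect_equal(k1$uce, abs(k1$rmse - k1$rmv))
  expect_equal(k1$uce, k1$auce)

  k4 <- calibrationError(p, u, r, K = 4)  # 100 %% 4 == 0: equal bins
  expect_equal(k4$uce, k4$auce)
  expect_equal(sum(k4$bins$n), 100)
  expect_error(calibrationError(p, u, r, K = 101), "K")
})

test_that("calibrated predictions give small UCE; inflating noise raises it", {
  set.seed(31)
  n <- 3e4
  sd_true <- runif(n, 1, 5)
  mu <- runif(n, 0, 35)
  y <- rnorm(n, mu, sd_true)
  cal <- calibrationError(mu, sd_true^2, y, K = 10)
  expect_lt(cal$uce, 0.1)
  y2 <- rnorm(n, mu, 2 * sd_true)  # model now underestimates its variance
  mis <- calibrationError(mu, sd_true^2, y2, K = 10)
  expect_gt(mis$uce, cal$uce)
})

test_that("uncertainty filtering drops the requested fraction and lowers RMSE", {
  expect_equal(filterByUncertainty(1:10, 10:1, fraction = 0), rep(TRUE, 10))
  keep <- filterByUncertainty(1:10, runif(10), fraction = 0.2)
  expect_equal(sum(keep), 8)
  expect_error(filterByUncertainty(1:3, 1:3, fraction = 1.5), "fraction")

  set.seed(13)
  n <- 2e4
  sd_true <- runif(n, 0.5, 6)
  mu <- runif(n, 0, 35)
  y <- rnorm(n, mu, sd_true)
  keep <- filterByUncertainty(mu, sd_true^2, 0.2, mode = "fixed")
  expect_lte(oracle_rmse(mu[keep], y[keep]), oracle_rmse(mu, y))

  # adaptive mode keeps tall predictions in the retained set
  rel <- filterByUncertainty(mu, sd_true^2, 0.2, mode = "adaptive")
  expect_gt(max(mu[rel]), 0.95 * max(mu))
})
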