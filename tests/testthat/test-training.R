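# Sparse NLL loss, balance weights, normalization and the optimizer loop.

test_that("sparse NLL matches hand-evaluated values and ignores unlabelled pixels", {
  lab1 <- list(heights = matrix(2), valid = matrix(TRUE))
  expect_equal(sparseNllLoss(matrix(2), matrix(1), lab1), 0)
  expect_equal(sparseNllLoss(matrix(4), matrix(2), lab1), 1 + 0.5 * log(2))

  # appending unlabelled pixels leaves the loss unchanged
  mu <- matrix(c(4, 100, -3), 1); v <- matrix(c(2, 1e-8, 5), 1)
  lab3 <- list(heights = matrix(c(2, 0, 0), 1),
               valid = matrix(c(TRUE, FALSE, FALSE), 1))
  expect_equal(sparseNllLoss(mu, v, lab3), 1 + 0.5 * log(2))

  expect_error(sparseNllLoss(matrix(1), matrix(1),
                             list(heights = matrix(1), valid = matrix(FALSE))),
               "no labelled")
  expect_error(sparseNllLoss(matrix(1), matrix(-1), lab1), "positive")
})

test_that("NLL gradient w.r.t. the mean vanishes at the label", {
  lab <- list(heights = matrix(5), valid = matrix(TRUE))
  eps <- 1e-6
  fd <- (sparseNllLoss(matrix(5 + eps), matrix(2), lab) -
         sparseNllLoss(matrix(5 - eps), matrix(2), lab)) / (2 * eps)
  expect_lt(abs(fd), 1e-8)
})

test_that("balance weights follow sqrt inverse frequency", {
  bw <- computeBalanceWeights(c(0.5, rep(1.5, 4)))
  expect_equal(bw$q, c(2 / 3, 1 / 3))
  expect_equal(bw$counts, c(1L, 4L))

  unif <- computeBalanceWeights(seq(0.5, 9.5, by = 1))
  expect_equal(unif$q, rep(0.1, 10))

  set.seed(3)
  for (i in 1:10) {
    h <- runif(sample(5:200, 1), 0, 45)
    expect_equal(sum(computeBalanceWeights(h)$q), 1)
  }
  expect_error(computeBalanceWeights(numeric(0)), "at least one")

  # all labels in one bin: balanced loss equals unbalanced loss
  one <- computeBalanceWeights(runif(20, 3, 4))
  lab <- list(heights = matrix(runif(9, 3, 4), 3), valid = matrix(TRUE, 3, 3))
  mu <- matrix(rnorm(9, 3.5), 3); v <- matrix(runif(9, 0.5, 2), 3)
  expect_equal(sparseNllLoss(mu, v, lab, weights = one),
               sparseNllLoss(mu, v, lab))
})

test_that("normalization statistics round-trip and come from the training split", {
  cfg <- tiny_sim(nDates = 2L)
  scenes <- simulateScenes(4, cfg, nFootprints = 4, seed = 2)
  ts <- buildTrainingSet(scenes)
  nm <- normalizationStats(ts)
  expect_true(all(nm$chSd > 0) && nm$ySd > 0)
  y <- c(0, 3.7, 28.1)
  expect_equal(((y - nm$yMean) / nm$ySd) * nm$ySd + nm$yMean, y,
               tolerance = 1e-9)
})

test_that("learning-rate schedule decays at the milestone fractions", {
  tc <- trainConfig(iterations = 1000, baseLr = 1e-3)
  expect_equal(learningRateAt(tc, 100), 1e-3)
  expect_equal(learningRateAt(tc, 500), 1e-4)
  expect_equal(learningRateAt(tc, 900), 1e-5)  # past the second milestone
  expect_error(trainConfig(milestoneFractions = c(0.4, 1.2)), "between")
})

test_that("training reduces the loss and is seed-deterministic", {
  cfg <- tiny_sim(nDates = 2L)
  scenes <- simulateScenes(30, cfg, nFootprints = 4, seed = 21)
  ts <- buildTrainingSet(scenes)
  tc <- trainConfig(iterations = 200, batchSize = 16, seed = 9)
  net <- canopyNet(networkConfig(filters = 16L, seed = 4))
  r1 <- trainNetwork(net, ts, tc)
  expect_lt(mean(tail(r1$trace$loss, 20)), mean(head(r1$trace$loss, 20)))
  r2 <- trainNetwork(net, ts, tc)
  expect_identical(r1$trace$loss, r2$trace$loss)
  expect_identical(r1$net@params, r2$net@params)
})

test_that("mean-head fine-tuning touches only the mean head", {
  cfg <- tiny_sim(nDates = 2L)
  scenes <- simulateScenes(20, cfg, nFootprints = 4, seed = 31)
  ts <- buildTrainingSet(scenes)
  tc <- trainConfig(iterations = 60, finetuneIterations = 40, batchSize = 8,
                    seed = 2)
  ncfg <- networkConfig(filters = 16L, seed = 6)
  trained <- trainNetwork(canopyNet(ncfg), ts, tc)$net
  bw <- computeBalanceWeights(unlist(lapply(ts$samples, `[[`, "y")))
  tuned <- finetuneMeanHead(trained, ts, bw, tc)$net
  lay <- paramLayout(ncfg)
  head_idx <- c(lay$Wm, lay$bm)
  expect_identical(trained@params[-head_idx], tuned@params[-head_idx])
  expect_identical(trained@params[c(lay$Wv, lay$bv)],
                   tuned@params[c(lay$Wv, lay$bv)])
  expect_false(identical(trained@params[head_idx], tuned@params[head_idx]))
  expect_error(finetuneMeanHead(trained, ts, NULL, tc), "required")
})
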