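# Synthetic-scene generator: height-field marginals, rendering, footprint
# sampling and rasterization.

test_that("degenerate mixtures and determinism behave as specified", {
  all0 <- generateHeightField(tiny_sim(zeroProb = 1))
  expect_true(all(heights(all0) == 0))

  f1 <- generateHeightField(tiny_sim(seed = 7))
  f2 <- generateHeightField(tiny_sim(seed = 7))
  f3 <- generateHeightField(tiny_sim(seed = 8))
  expect_identical(heights(f1), heights(f2))
  expect_false(identical(heights(f1), heights(f3)))
})

test_that("config validation rejects invalid settings", {
  expect_error(simConfig(gridSize = 0), "gridSize")
  expect_error(simConfig(corrLength = 15, gridSize = 15), "corrLength")
  expect_error(simConfig(zeroProb = 1.2), "probabilities")
  expect_error(simConfig(lowSd = -1), "deviations")
  expect_error(renderAcquisitions(generateHeightField(tiny_sim()),
                                  tiny_sim(nDates = 0)), "nDates")
})

test_that("field marginal matches a direct mixture-sampling oracle", {
  # spatially independent pixels so the binomial s.e. applies
  cfg <- simConfig(gridSize = 400L, corrLength = 0, tallProb = 0.05,
                   tallMean = 35, tallSd = 8, seed = 31)
  fld <- heights(generateHeightField(cfg))
  frac_field <- mean(fld > 30)
  oracle <- withr::with_seed(99, sampleHeightMixture(1e6, cfg))
  frac_mc <- mean(oracle > 30)
  se <- sqrt(frac_mc * (1 - frac_mc) * (1 / length(fld) + 1 / 1e6))
  expect_lt(abs(frac_field - frac_mc), 2 * se)
  # zero inflation shows up as an exact point mass
  expect_gt(mean(fld == 0), 0.5 * cfg$zeroProb)
})

test_that("rendering links, clouds and noise match their contracts", {
  links <- defaultBandLinks(12)
  links$type[1] <- "identity"; links$a[1] <- 0; links$s[1] <- 1
  cfg <- tiny_sim(links = links, noiseSd = 0, textureSd = 0)
  fld <- generateHeightField(cfg)
  st <- renderAcquisitions(fld, cfg)
  expect_equal(st@images[[1]][, , 1], heights(fld))
  expect_equal(dim(st@images[[1]])[3], 15)

  cloudy <- renderAcquisitions(fld, tiny_sim(cloudFraction = 1))
  expect_false(any(cloudy@valid[[1]]))

  # across-date per-pixel variance of a band ~ configured noise variance
  cfg2 <- simConfig(gridSize = 8L, nDates = 500L, cloudFraction = 0,
                    noiseSd = 0.02, textureSd = 0, seed = 5)
  st2 <- renderAcquisitions(generateHeightField(cfg2), cfg2)
  band <- sapply(st2@images, function(im) as.vector(im[, , 3]))
  vbar <- mean(apply(band, 1, stats::var))
  expect_lt(abs(vbar - 0.02^2) / 0.02^2, 0.05)
})

test_that("footprint labels are disc maxima at the true centre", {
  fld <- const_field(17)
  fps <- sampleFootprints(fld, 50, tiny_sim())
  expect_equal(footprintRecords(fps)$rh98_m, rep(17, 50))

  expect_equal(nrow(footprintRecords(sampleFootprints(fld, 0, tiny_sim()))), 0)
  expect_error(sampleFootprints(fld, -1, tiny_sim()), ">= 0")

  # single spike: label 30 iff the true centre is within the footprint
  # radius of the spike pixel centre (brute-force disc-scan oracle)
  h <- matrix(0, 12, 12); h[5, 7] <- 30
  fld2 <- methods::new("HeightField", heights = h, geo = geoRefGrid(0, 0, 10),
                       maxHeight = 60)
  cfg <- tiny_sim()
  fps2 <- sampleFootprints(fld2, 300, cfg)
  rec <- footprintRecords(fps2)
  xy <- canopyfuse:::.lonlat_to_xy(fld2@geo, rec$lon_true, rec$lat_true)
  oracle <- vapply(seq_len(300), function(i) {
    best <- 0
    for (rr in 1:12) for (cc in 1:12) {
      d2 <- ((cc - 0.5) * 10 - xy$x[i])^2 + ((rr - 0.5) * 10 - xy$y[i])^2
      if (d2 <= cfg$footprintRadius^2 && h[rr, cc] > best) best <- h[rr, cc]
    }
    best
  }, numeric(1))
  expect_identical(rec$rh98_m, oracle)
  expect_true(any(oracle == 30) && any(oracle == 0))
})

test_that("rasterization uses the reported centre with last-write-wins", {
  geo <- geoRefGrid(0, 0, 10)
  # one footprint exactly at the centre of pixel (2, 3)
  one <- fps_at_xy(25, 15, 12)
  lab <- rasterizeFootprints(one, c(12L, 12L), geo)
  expect_equal(sum(validMask(lab)), 1)
  expect_equal(heights(lab)[2, 3], 12)

  # two footprints in one pixel: one valid pixel, one collision, last wins
  two <- fps_at_xy(c(24, 26), c(14, 16), c(5, 9))
  lab2 <- rasterizeFootprints(two, c(12L, 12L), geo)
  expect_equal(sum(validMask(lab2)), 1)
  expect_equal(heights(lab2)[2, 3], 9)
  expect_equal(rasterizeDiagnostics(lab2)[["collisions"]], 1L)

  # 1 cm outside the east edge: dropped
  off <- fps_at_xy(120.01, 50, 7)
  lab3 <- rasterizeFootprints(off, c(12L, 12L), geo)
  expect_equal(sum(validMask(lab3)), 0)
  expect_equal(rasterizeDiagnostics(lab3)[["dropped"]], 1L)
})

test_that("scene-class zeroing forces bare/water labels to 0 m", {
  geo <- geoRefGrid(0, 0, 10)
  fps <- fps_at_xy(c(25, 55), c(15, 15), c(12, 12))
  lab <- rasterizeFootprints(fps, c(12L, 12L), geo)
  classes <- matrix("vegetated", 12, 12)
  classes[2, 3] <- "water"
  out <- applySceneClassZeroing(lab, classes)
  expect_equal(heights(out)[2, 3], 0)
  expect_equal(heights(out)[2, 6], 12)  # vegetated pixel unchanged
  expect_true(validMask(out)[2, 3])     # stays a valid label

  allbare <- applySceneClassZeroing(lab, matrix("not_vegetated", 12, 12))
  expect_true(all(heights(allbare)[validMask(allbare)] == 0))
  expect_error(applySceneClassZeroing(lab, matrix("water", 5, 5)), "aligned")
})

test_that("noise-free labels reproduce the disc-max distribution of the field", {
  cfg <- simConfig(gridSize = 120L, corrLength = 3, labelNoiseSd = 0,
                   jitterSd = 0, seed = 17)
  fld <- generateHeightField(cfg)
  fps <- sampleFootprints(fld, 1e4, cfg)
  labels <- footprintRecords(fps)$rh98_m
  # oracle: brute-force disc max at independently drawn centres
  h <- heights(fld)
  brute_disc_max <- function(x, y) {
    best <- -Inf
    for (cc in max(1, floor((x - 13) / 10)):min(120, ceiling((x + 13) / 10)))
      for (rr in max(1, floor((y - 13) / 10)):min(120, ceiling((y + 13) / 10))) {
        d2 <- ((cc - 0.5) * 10 - x)^2 + ((rr - 0.5) * 10 - y)^2
        if (d2 <= cfg$footprintRadius^2 && h[rr, cc] > best) best <- h[rr, cc]
      }
    best
  }
  oracle <- withr::with_seed(4242, {
    x <- runif(1e4, 0, 120 * 10); y <- runif(1e4, 0, 120 * 10)
    vapply(seq_len(1e4), function(i) brute_disc_max(x[i], y[i]), numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(labels, oracle))
  expect_gt(ks$p.value, 0.01)
})
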