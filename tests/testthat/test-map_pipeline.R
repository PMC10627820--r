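# Acquisition selection, tiled ensemble inference, masking and map export.

test_that("acquisition selection orders by cloud cover with stable tie-breaks", {
  cat <- data.frame(date = as.Date("2020-06-01") + c(0, 10, 20),
                    cloud_fraction = c(0.3, 0.1, 0.2),
                    path = c("a.tif", "b.tif", "c.tif"))
  sel <- selectImages(cat, count = 2)
  expect_equal(sel$cloud_fraction, c(0.1, 0.2))

  expect_warning(all3 <- selectImages(cat, count = 10), "3 of the requested 10")
  expect_equal(nrow(all3), 3)

  ties <- data.frame(date = as.Date(c("2020-07-01", "2020-06-01")),
                     cloud_fraction = c(0.2, 0.2), path = c("x", "y"))
  expect_equal(selectImages(ties, count = 1)$date, as.Date("2020-06-01"))

  expect_error(selectImages(cat, window = as.Date(c("2019-01-01",
                                                    "2019-12-31"))),
               "no acquisitions")
})

test_that("single-date prediction is the fusion identity", {
  cfg <- tiny_sim(nDates = 1L)
  fld <- generateHeightField(cfg)
  st <- renderAcquisitions(fld, cfg)
  net <- tiny_net(seed = 21)
  ens <- methods::new("CanopyEnsemble", members = list(net), seeds = 21L)
  pm <- predictTile(st, ens, seed = 1)
  direct <- predictGrid(net, st@images[[1]])
  expect_equal(predMean(pm), direct$mean, tolerance = 1e-12)
  expect_equal(predSd(pm), sqrt(direct$variance), tolerance = 1e-12)
})

test_that("fully cloudy stacks give an all-nodata map with a warning", {
  cfg <- tiny_sim(nDates = 2L, cloudFraction = 1)
  st <- renderAcquisitions(generateHeightField(cfg), cfg)
  ens <- methods::new("CanopyEnsemble", members = list(tiny_net()), seeds = 1L)
  expect_warning(pm <- predictTile(st, ens), "all-nodata")
  expect_false(any(validMask(pm)))
  tmp <- withr::local_tempdir()
  writeMap(pm, file.path(tmp, "cloudy"))
  bands <- readMapBands(file.path(tmp, "cloudy"))
  expect_true(all(bands$height == 255))
})

test_that("land-cover masking sets listed classes to nodata", {
  pm <- methods::new("PredictiveMap", mean = matrix(18, 2, 2),
                     sd = matrix(1, 2, 2), valid = matrix(TRUE, 2, 2),
                     geo = geoRefGrid())
  classes <- matrix(c("water", "vegetated", "built_up", "snow_ice"), 2)
  out <- applyLandcoverMask(pm, classes)
  expect_equal(validMask(out), matrix(c(FALSE, TRUE, FALSE, FALSE), 2))
  tmp <- withr::local_tempdir()
  writeMap(out, file.path(tmp, "masked"))
  bands <- readMapBands(file.path(tmp, "masked"))
  expect_equal(bands$height[1, 1], 255)  # water -> sentinel
  expect_equal(bands$height[2, 1], 18)   # vegetated kept
  expect_error(applyLandcoverMask(pm, matrix("water", 3, 3)), "aligned")
})

test_that("map export quantizes, clips and round-trips bit-identically", {
  mean_m <- matrix(c(12.4, 12.5, 11.5, 300), 2)
  pm <- methods::new("PredictiveMap", mean = mean_m,
                     sd = matrix(c(1.234, 0, 2.5, 60), 2),
                     valid = matrix(TRUE, 2, 2), geo = geoRefGrid(5, 6, 10))
  tmp <- withr::local_tempdir()
  expect_warning(writeMap(pm, file.path(tmp, "m"), lossless = TRUE),
                 "clipped")
  bands <- readMapBands(file.path(tmp, "m"))
  expect_equal(bands$height[1, 1], 12)  # round half to even
  expect_equal(bands$height[2, 1], 12)
  expect_equal(bands$height[1, 2], 12)
  expect_equal(bands$height[2, 2], 254)  # pathological clip
  expect_equal(bands$sd_cm[1, 1], 123)

  back <- readMap(file.path(tmp, "m"))
  expect_equal(geoRef(back)@lat0, 5)
  # second write/read round-trip is bit-identical
  writeMap(back, file.path(tmp, "m2"))
  expect_identical(readMapBands(file.path(tmp, "m2"))$height, bands$height)
  expect_identical(readMapBands(file.path(tmp, "m2"))$sd_cm, bands$sd_cm)
  # lossless float export
  lossless <- as.matrix(read.table(file.path(tmp, "m_height_m.tsv")))
  expect_equal(unname(lossless), unname(mean_m))
})

test_that("scene, footprint and config files round-trip", {
  cfg <- tiny_sim(nDates = 2L, cloudFraction = 0.3)
  fld <- generateHeightField(cfg)
  st <- renderAcquisitions(fld, cfg)
  fps <- sampleFootprints(fld, 8, cfg)
  tmp <- withr::local_tempdir()

  writeAcquisitionStack(st, file.path(tmp, "scene"))
  st2 <- readAcquisitionStack(file.path(tmp, "scene"))
  expect_equal(nDates(st2), 2)
  expect_identical(st2@valid, st@valid)
  b <- st@images[[1]][, , 1:12]
  expect_equal(st2@images[[1]][, , 1:12], pmax(b, 0), tolerance = 2e-4)
  expect_equal(st2@images[[1]][, , 13:15], st@images[[1]][, , 13:15],
               tolerance = 1e-12)

  writeFootprints(fps, file.path(tmp, "fps.tsv"))
  fps2 <- readFootprints(file.path(tmp, "fps.tsv"))
  expect_equal(footprintRecords(fps2)$rh98_m, footprintRecords(fps)$rh98_m,
               tolerance = 1e-9)

  writeSimConfig(cfg, file.path(tmp, "cfg.yaml"))
  cfg2 <- readSimConfig(file.path(tmp, "cfg.yaml"))
  expect_equal(cfg2$gridSize, cfg$gridSize)
  expect_equal(cfg2$links$s, cfg$links$s)
  expect_identical(heights(generateHeightField(cfg2)), heights(fld))
})

test_that("checkpoints restore networks and ensembles exactly", {
  tmp <- withr::local_tempdir()
  net <- tiny_net(seed = 9)
  saveCheckpoint(net, file.path(tmp, "net.ckpt"))
  net2 <- loadCheckpoint(file.path(tmp, "net.ckpt"))
  expect_identical(net2@params, net@params)

  ens <- methods::new("CanopyEnsemble",
                      members = list(tiny_net(seed = 1), tiny_net(seed = 2)),
                      seeds = c(1L, 2L))
  saveCheckpoint(ens, file.path(tmp, "ens.ckpt"))
  ens2 <- loadCheckpoint(file.path(tmp, "ens.ckpt"))
  expect_identical(ens2@members[[2]]@params, ens@members[[2]]@params)
})
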