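# External interfaces of the simulator: multiband TIFF per acquisition date
# (+ JSON sidecar), delimited footprint tables, YAML configs and network
# checkpoints.

#' Simulate a batch of scenes
#'
#' Generates `nScenes` independent scenes (height field, acquisition stack,
#' footprints, rasterized labels) from one [simConfig()], with per-scene
#' seeds and geographic origins derived deterministically from `seed`.
#' Scene-class zeroing is applied with a class grid derived from the true
#' field (bare ground where the true height is 0).
#'
#' @param nScenes number of scenes.
#' @param config a [simConfig()] template.
#' @param nFootprints footprints sampled per scene.
#' @param seed integer master seed.
#' @return list of scenes, each a list with `field`, `stack`, `footprints`,
#'   `labels`.
#' @export
simulateScenes <- function(nScenes, config = simConfig(), nFootprints = 5L,
                           seed = 1L) {
  origins <- .with_seed(seed, data.frame(
    lat0 = stats::runif(nScenes, -50, 50),
    lon0 = stats::runif(nScenes, -179, 179)))
  lapply(seq_len(nScenes), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + 101L * i)
    cfg$lat0 <- origins$lat0[i]
    cfg$lon0 <- origins$lon0[i]
    field <- generateHeightField(cfg)
    stack <- renderAcquisitions(field, cfg)
    fps <- sampleFootprints(field, nFootprints, cfg)
    labels <- rasterizeFootprints(fps, dim(field@heights), field@geo)
    classes <- matrix(ifelse(field@heights <= 0, "not_vegetated", "vegetated"),
                      nrow(field@heights))
    labels <- applySceneClassZeroing(labels, classes)
    list(field = field, stack = stack, footprints = fps, labels = labels)
  })
}

#' Write an acquisition stack to TIFF files
#'
#' One multi-page TIFF per date (`<prefix>_<date>.tif`): the reflectance
#' bands as unsigned 16-bit digital numbers (DN = 1e4 x reflectance, clipped
#' to [0, 6.5535], the usual L2A convention) followed by one 0/1 validity
#' page. The georeference, dates and band count go to `<prefix>.json`; the
#' three coordinate channels are recomputed from the georeference on read.
#'
#' @param stack an [AcquisitionStack-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeAcquisitionStack <- function(stack, prefix) {
  stopifnot(methods::is(stack, "AcquisitionStack"))
  d <- dim(stack@images[[1]])
  for (t in seq_len(nDates(stack))) {
    mats <- lapply(seq_len(stack@nBands),
                   function(b) stack@images[[t]][, , b])
    mats[[stack@nBands + 1L]] <- (stack@valid[[t]] * 1) / 1e4
    .write_uint16_tiff(mats, sprintf("%s_%s.tif", prefix,
                                     format(stack@dates[t], "%Y%m%d")),
                       scale = 1e4)
  }
  .write_sidecar(prefix, stack@geo, d[1:2],
                 list(nBands = stack@nBands,
                      dates = format(stack@dates, "%Y-%m-%d")))
  invisible(prefix)
}

#' Read an acquisition stack written by [writeAcquisitionStack()]
#'
#' @param prefix the path prefix.
#' @return an [AcquisitionStack-class] (reflectances at 1e-4 resolution).
#' @export
readAcquisitionStack <- function(prefix) {
  meta <- .read_sidecar(prefix)
  geo <- .geo_from_list(meta)
  dates <- as.Date(unlist(meta$dates))
  nb <- meta$nBands
  H <- meta$nrow; W <- meta$ncol
  ll <- pixelLatLon(geo, c(H, W))
  enc <- array(encodeCoordinates(as.vector(ll$lat), as.vector(ll$lon)),
               c(H, W, 3L))
  images <- vector("list", length(dates))
  valid <- vector("list", length(dates))
  for (t in seq_along(dates)) {
    pages <- .read_uint16_tiff(sprintf("%s_%s.tif", prefix,
                                       format(dates[t], "%Y%m%d")),
                               scale = 1e4)
    img <- array(0, c(H, W, nb + 3L))
    for (b in seq_len(nb)) img[, , b] <- pages[[b]]
    img[, , nb + (1:3)] <- enc
    images[[t]] <- img
    valid[[t]] <- pages[[nb + 1L]] * 1e4 > 0.5
  }
  methods::new("AcquisitionStack", images = images, valid = valid,
               dates = dates, geo = geo, nBands = as.integer(nb))
}

#' Write footprints as a delimited table
#'
#' Tab-separated text with header `lon`, `lat`, `rh98_m` (the reported
#' centre and the footprint-level canopy-top label).
#'
#' @param fps a [FootprintSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFootprints <- function(fps, path) {
  stopifnot(methods::is(fps, "FootprintSet"))
  utils::write.table(fps@records[, c("lon", "lat", "rh98_m")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a footprint table
#'
#' Reads a delimited `lon, lat, rh98_m` table; true centres are unknown for
#' external data and set equal to the reported centres.
#'
#' @param path input file.
#' @return a [FootprintSet-class].
#' @export
readFootprints <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t")
  rec$lon_true <- rec$lon
  rec$lat_true <- rec$lat
  rec$off_grid <- FALSE
  methods::new("FootprintSet",
               records = rec[, c("lon_true", "lat_true", "lon", "lat",
                                 "rh98_m", "off_grid")])
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [simConfig()].
#' @param path file path.
#' @return `writeSimConfig`: `path`, invisibly. `readSimConfig`: the
#'   [simConfig()].
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(inherits(config, "SimConfig"))
  out <- unclass(config)
  out$links <- as.list(out$links)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$links <- as.data.frame(raw$links)
  do.call(simConfig, raw)
}

#' Save / load a network or ensemble checkpoint
#'
#' A single checkpoint file holding the architecture configuration, the flat
#' parameter vector and the normalization statistics (for an ensemble: one
#' entry per member plus the member seeds).
#'
#' @param object a [CanopyNet-class] or [CanopyEnsemble-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint`: `path`, invisibly. `loadCheckpoint`: the
#'   restored object.
#' @export
saveCheckpoint <- function(object, path) {
  if (methods::is(object, "CanopyNet")) {
    saveRDS(list(kind = "net", config = object@config,
                 params = object@params, norm = object@norm), path)
  } else if (methods::is(object, "CanopyEnsemble")) {
    saveRDS(list(kind = "ensemble", seeds = object@seeds,
                 members = lapply(object@members, function(m)
                   list(config = m@config, params = m@params,
                        norm = m@norm))), path)
  } else stop("object must be a CanopyNet or CanopyEnsemble")
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  mknet <- function(m) methods::new("CanopyNet", config = m$config,
                                    params = m$params, norm = m$norm)
  if (identical(ck$kind, "net")) return(mknet(ck))
  methods::new("CanopyEnsemble", members = lapply(ck$members, mknet),
               seeds = ck$seeds)
}
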