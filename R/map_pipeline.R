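# Tiled ensemble inference over acquisition stacks, acquisition selection,
# land-cover masking and map export with nodata conventions.

#' Select least-cloudy acquisitions from a catalog
#'
#' Orders catalog entries by ascending cloud fraction (ties broken by date,
#' then path — deterministic) within an optional date window and returns up
#' to `count` of them; the deployment protocol uses the ten least-cloudy
#' images of the mapping season.
#'
#' @param catalog data.frame with columns `date` (Date), `cloud_fraction`
#'   (in [0, 1]) and `path`.
#' @param window optional `c(from, to)` Date range (inclusive).
#' @param count maximum number of entries.
#' @return the ordered subset of `catalog`; warns if fewer than `count`
#'   remain.
#' @export
selectImages <- function(catalog, window = NULL, count = 10L) {
  stopifnot(all(c("date", "cloud_fraction", "path") %in% names(catalog)),
            count >= 1)
  if (any(catalog$cloud_fraction < 0 | catalog$cloud_fraction > 1))
    stop("cloud_fraction must lie in [0, 1]")
  if (!is.null(window))
    catalog <- catalog[catalog$date >= window[1] & catalog$date <= window[2], ]
  if (!nrow(catalog)) stop("no acquisitions available in the requested window")
  catalog <- catalog[order(catalog$cloud_fraction, catalog$date,
                           catalog$path), ]
  if (nrow(catalog) < count)
    warning(sprintf("only %d of the requested %d acquisitions available",
                    nrow(catalog), count))
  utils::head(catalog, count)
}

#' Ensemble prediction over an acquisition stack
#'
#' Assigns one ensemble member to each acquisition date (uniformly at random,
#' deterministic given `seed`), runs the per-date forward passes (windowed
#' for large tiles, see [predictGrid()]) and fuses the per-date estimates by
#' inverse-variance weighting over the valid dates per pixel. Pixels with no
#' valid observation on any date become nodata.
#'
#' @param stack an [AcquisitionStack-class].
#' @param ens a [CanopyEnsemble-class].
#' @param seed seed for the member assignment.
#' @param window optional window side length for tiled inference.
#' @return a [PredictiveMap-class].
#' @export
predictTile <- function(stack, ens, seed = 1L, window = NULL) {
  stopifnot(methods::is(stack, "AcquisitionStack"),
            methods::is(ens, "CanopyEnsemble"))
  T <- nDates(stack)
  members <- assignMembers(T, ensembleSize(ens), seed)
  if (!any(vapply(stack@valid, any, logical(1)))) {
    warning("no valid observation on any date; returning an all-nodata map")
    d <- dim(stack@images[[1]])
    return(methods::new("PredictiveMap",
                        mean = matrix(0, d[1], d[2]),
                        sd = matrix(0, d[1], d[2]),
                        valid = matrix(FALSE, d[1], d[2]), geo = stack@geo))
  }
  muList <- vector("list", T); varList <- vector("list", T)
  for (t in seq_len(T)) {
    out <- predictGrid(ens@members[[members[t]]], stack@images[[t]],
                       window = window)
    muList[[t]] <- out$mean
    varList[[t]] <- out$variance
  }
  fuseAcquisitions(muList, varList, stack@valid, geo = stack@geo)
}

#' Mask non-vegetation land cover in a predictive map
#'
#' Sets pixels classed as built-up, snow/ice or permanent water to nodata,
#' so they carry the 255 sentinel in the exported height band.
#'
#' @param map a [PredictiveMap-class].
#' @param classGrid character matrix of land-cover classes aligned with the
#'   map grid.
#' @param maskClasses classes to mask.
#' @return the masked [PredictiveMap-class].
#' @export
applyLandcoverMask <- function(map, classGrid,
                               maskClasses = c("built_up", "snow_ice",
                                               "water")) {
  stopifnot(methods::is(map, "PredictiveMap"))
  if (!all(dim(classGrid) == dim(map@mean)))
    stop("classGrid must be aligned with the map grid")
  map@valid <- map@valid & !matrix(classGrid %in% maskClasses,
                                   nrow(classGrid))
  map
}

#' Write a predictive map
#'
#' Writes `<path>_height.tif` (unsigned 8-bit whole metres, round-half-even,
#' clipped to [0, 254] with a warning, 255 = nodata), `<path>_sd.tif`
#' (unsigned 16-bit whole centimetres, 65535 = nodata) and `<path>_geo.json`
#' (georeference + format metadata). With `lossless = TRUE`, the float bands
#' are additionally written as tab-separated text (`<path>_height_m.tsv`,
#' `<path>_sd_m.tsv`) for analysis. Reading the files back with [readMap()]
#' returns bit-identical quantized bands.
#'
#' @param map a [PredictiveMap-class].
#' @param path output path prefix.
#' @param lossless also write float TSV bands.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path, lossless = FALSE) {
  stopifnot(methods::is(map, "PredictiveMap"))
  h <- round(map@mean)  # round half to even
  nclip <- sum(h[map@valid] > 254)
  if (nclip > 0) {
    warning(sprintf("%d height value(s) above 254 m clipped", nclip))
    h[h > 254] <- 254
  }
  h[h < 0] <- 0
  h[!map@valid] <- 255
  sd_cm <- round(map@sd * 100)
  sd_cm[sd_cm > 65534] <- 65534
  sd_cm[sd_cm < 0] <- 0
  sd_cm[!map@valid] <- 65535
  tiff::writeTIFF(h / 255, paste0(path, "_height.tif"), bits.per.sample = 8)
  tiff::writeTIFF(sd_cm / 65535, paste0(path, "_sd.tif"),
                  bits.per.sample = 16)
  jsonlite::write_json(
    c(.geo_to_list(map@geo, dim(map@mean)),
      list(nodata = 255, height_units = "m", sd_units = "cm")),
    paste0(path, "_geo.json"), auto_unbox = TRUE, digits = NA)
  if (lossless) {
    utils::write.table(map@mean, paste0(path, "_height_m.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(map@sd, paste0(path, "_sd_m.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a predictive map written by [writeMap()]
#'
#' @param path the path prefix passed to [writeMap()].
#' @return a [PredictiveMap-class] with the quantized bands (whole metres /
#'   centimetres); nodata pixels have `validMask()` FALSE.
#' @export
readMap <- function(path) {
  g <- jsonlite::read_json(paste0(path, "_geo.json"))
  h <- round(tiff::readTIFF(paste0(path, "_height.tif")) * 255)
  sd_cm <- round(tiff::readTIFF(paste0(path, "_sd.tif")) * 65535)
  valid <- h != 255 & sd_cm != 65535
  hm <- h; hm[!valid] <- 0
  sdm <- sd_cm / 100; sdm[!valid] <- 0
  methods::new("PredictiveMap", mean = hm, sd = sdm, valid = valid,
               geo = .geo_from_list(g))
}

#' Raw quantized bands of a written map
#'
#' Reads the two exported bands without sentinel handling, for round-trip
#' checks: the uint8 height band (with 255 sentinels) and the uint16
#' standard-deviation band in centimetres (with 65535 sentinels).
#'
#' @param path the path prefix passed to [writeMap()].
#' @return list with integer matrices `height` and `sd_cm`.
#' @export
readMapBands <- function(path) {
  list(height = round(tiff::readTIFF(paste0(path, "_height.tif")) * 255),
       sd_cm = round(tiff::readTIFF(paste0(path, "_sd.tif")) * 65535))
}
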