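# Coordinate handling and raster I/O.
#
# Rasters are exchanged as plain TIFF files (one page per band) plus a JSON
# sidecar carrying the georeference, because all bands are stored as scaled
# integers with exact round trips:
#   reflectance  uint16, DN = round(1e4 * reflectance)   (L2A convention)
#   height       uint8,  whole metres, 255 = nodata
#   pred. sd     uint16, whole centimetres, 65535 = nodata

EARTH_M_PER_DEG <- 111320  # metres per degree of latitude

#' Cyclic encoding of geographic coordinates
#'
#' Maps (lat, lon) to the three bounded channels fed to the network alongside
#' the reflectance bands: `(sin(pi*lat/180), sin(pi*lon/180), cos(pi*lon/180))`.
#' Latitude on [-90, 90] is already injective under the sine; longitude needs
#' the sin/cos pair to be continuous (and exactly periodic) across the
#' antimeridian. Longitudes are wrapped to [-180, 180) first, so -180 and
#' +180 encode identically.
#'
#' @param lat,lon numeric vectors of degrees; lat in [-90, 90], lon in
#'   [-180, 180].
#' @return a numeric matrix with `length(lat)` rows and columns
#'   `sin_lat`, `sin_lon`, `cos_lon`, all in [-1, 1].
#' @export
#' @examples
#' encodeCoordinates(0, 0)        # c(0, 0, 1)
#' encodeCoordinates(45, -180) == encodeCoordinates(45, 180)
encodeCoordinates <- function(lat, lon) {
  if (length(lat) != length(lon))
    stop("lat and lon must have equal length")
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop("lat must be finite and within [-90, 90]")
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180))
    stop("lon must be finite and within [-180, 180]")
  lon <- lon - 360 * floor((lon + 180) / 360)  # wrap to [-180, 180)
  cbind(sin_lat = sin(pi * lat / 180),
        sin_lon = sin(pi * lon / 180),
        cos_lon = cos(pi * lon / 180))
}

#' Pixel-centre coordinates of a grid
#'
#' @param geo a [GeoRef-class].
#' @param dims integer c(H, W).
#' @return list with H x W matrices `lat` and `lon` (degrees).
#' @export
pixelLatLon <- function(geo, dims) {
  h <- dims[1]; w <- dims[2]
  dlat <- geo@gsd / EARTH_M_PER_DEG
  dlon <- geo@gsd / (EARTH_M_PER_DEG * cos(geo@lat0 * pi / 180))
  lat <- geo@lat0 - (seq_len(h) - 0.5) * dlat
  lon <- geo@lon0 + (seq_len(w) - 0.5) * dlon
  list(lat = matrix(lat, h, w), lon = matrix(lon, h, w, byrow = TRUE))
}

# Inverse of pixelLatLon for point coordinates: local metre offsets from the
# grid origin (x east, y south).
.lonlat_to_xy <- function(geo, lon, lat) {
  x <- (lon - geo@lon0) * EARTH_M_PER_DEG * cos(geo@lat0 * pi / 180)
  y <- (geo@lat0 - lat) * EARTH_M_PER_DEG
  list(x = x, y = y)
}

.xy_to_lonlat <- function(geo, x, y) {
  list(lon = geo@lon0 + x / (EARTH_M_PER_DEG * cos(geo@lat0 * pi / 180)),
       lat = geo@lat0 - y / EARTH_M_PER_DEG)
}

#' Bicubic raster upsampling
#'
#' Separable Catmull-Rom cubic interpolation to an integer upsampling factor,
#' with pixel-centre alignment and edge clamping. Used to bring coarser bands
#' (20-m or 60-m GSD) onto the 10-m analysis grid.
#'
#' @param m numeric matrix.
#' @param factor integer upsampling factor (>= 1).
#' @return matrix with dimensions `dim(m) * factor`.
#' @export
upsampleCubic <- function(m, factor) {
  stopifnot(is.matrix(m), factor >= 1, factor == round(factor))
  if (factor == 1) return(m)
  w_axis <- function(n_in, n_out) {
    # output pixel centres in input pixel coordinates
    s <- ((seq_len(n_out) - 0.5) / factor) + 0.5
    i0 <- floor(s)
    t <- s - i0
    # Catmull-Rom weights for neighbours i0-1 .. i0+2
    w <- cbind(((-t + 2 * t^2 - t^3) / 2),
               ((2 - 5 * t^2 + 3 * t^3) / 2),
               ((t + 4 * t^2 - 3 * t^3) / 2),
               ((-t^2 + t^3) / 2))
    W <- matrix(0, n_out, n_in)
    for (k in 1:4) {
      idx <- pmin(pmax(i0 + k - 2L, 1L), n_in)  # clamp at edges
      W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w[, k]
    }
    W
  }
  Wr <- w_axis(nrow(m), nrow(m) * factor)
  Wc <- w_axis(ncol(m), ncol(m) * factor)
  Wr %*% m %*% t(Wc)
}

# ---- TIFF + JSON sidecar I/O ----------------------------------------------

.geo_to_list <- function(geo, dims) {
  list(lat0 = geo@lat0, lon0 = geo@lon0, gsd = geo@gsd,
       nrow = dims[1], ncol = dims[2])
}

.geo_from_list <- function(g) geoRefGrid(lat0 = g$lat0, lon0 = g$lon0, gsd = g$gsd)

.write_sidecar <- function(path, geo, dims, extra = list()) {
  jsonlite::write_json(c(.geo_to_list(geo, dims), extra),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

.read_sidecar <- function(path) jsonlite::read_json(paste0(path, ".json"))

# Write a list of matrices as a multi-page uint16 TIFF with DN scaling.
.write_uint16_tiff <- function(mats, path, scale) {
  pages <- lapply(mats, function(m) {
    dn <- round(m * scale)
    dn[dn < 0] <- 0
    dn[dn > 65535] <- 65535
    dn / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

.read_uint16_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) round(p * 65535) / scale)
}
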