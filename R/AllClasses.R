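# S4 containers for the canopy-height retrieval pipeline.

#' @include AllGenerics.R
NULL

#' Grid georeference
#'
#' Minimal georeference for a north-up raster grid: geographic coordinates of
#' the top-left corner and the ground sampling distance in metres. Pixel
#' centres are laid out row-by-row southwards from the origin on a local
#' equirectangular approximation (adequate for the patch / tile scales this
#' package operates at).
#'
#' @slot lat0 latitude of the top-left grid corner (degrees, in [-90, 90]).
#' @slot lon0 longitude of the top-left grid corner (degrees, in [-180, 180]).
#' @slot gsd ground sampling distance (metres, > 0).
#' @export
setClass("GeoRef",
  representation(lat0 = "numeric", lon0 = "numeric", gsd = "numeric"),
  prototype(lat0 = 0, lon0 = 0, gsd = 10))

setValidity("GeoRef", function(object) {
  msg <- NULL
  if (length(object@gsd) != 1 || !is.finite(object@gsd) || object@gsd <= 0)
    msg <- c(msg, "gsd must be a single positive number")
  if (length(object@lat0) != 1 || object@lat0 < -90 || object@lat0 > 90)
    msg <- c(msg, "lat0 must be in [-90, 90]")
  if (length(object@lon0) != 1 || object@lon0 < -180 || object@lon0 > 180)
    msg <- c(msg, "lon0 must be in [-180, 180]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn GeoRef constructor.
#' @param lat0,lon0,gsd see slots.
#' @export
geoRefGrid <- function(lat0 = 0, lon0 = 0, gsd = 10) {
  methods::new("GeoRef", lat0 = lat0, lon0 = lon0, gsd = gsd)
}

#' True canopy-top height field
#'
#' The latent ground-truth canopy-top height grid (metres) used by the scene
#' simulator and as the recovery target in end-to-end experiments. Heights are
#' non-negative and bounded by `maxHeight`.
#'
#' @slot heights numeric matrix of canopy-top heights (m).
#' @slot geo a [GeoRef-class].
#' @slot maxHeight upper bound on heights (m).
#' @export
setClass("HeightField",
  representation(heights = "matrix", geo = "GeoRef", maxHeight = "numeric"))

setValidity("HeightField", function(object) {
  h <- object@heights
  if (!is.numeric(h)) return("heights must be numeric")
  if (any(!is.finite(h))) return("heights must be finite")
  if (any(h < 0)) return("heights must be >= 0")
  if (any(h > object@maxHeight + 1e-9)) return("heights exceed maxHeight")
  TRUE
})

#' Multi-date acquisition stack
#'
#' T dated multi-channel image grids over one scene, each with a per-pixel
#' validity mask (FALSE where the view is cloud- or snow-obstructed). The
#' channel axis holds the reflectance bands followed by the three cyclically
#' encoded coordinate channels, so `nBands + 3` channels in total.
#'
#' @slot images list of H x W x C numeric arrays, one per date.
#' @slot valid list of H x W logical matrices, one per date.
#' @slot dates a `Date` vector of acquisition dates.
#' @slot geo a [GeoRef-class] shared by all dates.
#' @slot nBands number of reflectance bands (channels 1..nBands).
#' @export
setClass("AcquisitionStack",
  representation(images = "list", valid = "list", dates = "Date",
                 geo = "GeoRef", nBands = "integer"))

setValidity("AcquisitionStack", function(object) {
  tn <- length(object@images)
  if (tn < 1) return("at least one acquisition date is required")
  if (length(object@valid) != tn || length(object@dates) != tn)
    return("images, valid and dates must have equal length")
  d1 <- dim(object@images[[1]])
  for (t in seq_len(tn)) {
    di <- dim(object@images[[t]])
    if (length(di) != 3 || !all(di == d1))
      return("all dates must share identical array dimensions")
    if (!all(dim(object@valid[[t]]) == d1[1:2]))
      return("validity masks must match the image grid")
    img <- object@images[[t]]
    if (any(!is.finite(img[rep(object@valid[[t]], d1[3])])))
      return("valid pixels must not contain non-finite values")
  }
  if (d1[3] != object@nBands + 3L)
    return("channel count must equal nBands + 3 coordinate channels")
  TRUE
})

#' Sparse reference-height raster
#'
#' Per-pixel reference canopy-top heights rasterized from LiDAR footprints.
#' Only pixels flagged in `valid` carry a label; everything else is excluded
#' from losses and metrics. `collisions` counts footprints that overwrote an
#' already-labelled pixel, `dropped` counts footprints whose reported centre
#' fell outside the grid.
#'
#' @slot heights numeric matrix (m); meaningful only where `valid`.
#' @slot valid logical matrix of labelled pixels.
#' @slot collisions integer collision count.
#' @slot dropped integer off-grid count.
#' @slot geo a [GeoRef-class].
#' @export
setClass("SparseLabelRaster",
  representation(heights = "matrix", valid = "matrix",
                 collisions = "integer", dropped = "integer", geo = "GeoRef"))

setValidity("SparseLabelRaster", function(object) {
  if (!all(dim(object@heights) == dim(object@valid)))
    return("heights and valid must share dimensions")
  if (!is.logical(object@valid)) return("valid must be logical")
  hv <- object@heights[object@valid]
  if (any(!is.finite(hv)) || any(hv < 0))
    return("valid labels must be finite and >= 0")
  if (object@collisions < 0 || object@dropped < 0)
    return("counters must be non-negative")
  TRUE
})

#' LiDAR footprint set
#'
#' Simulated large-footprint LiDAR shots: the true centre, the reported
#' (geolocation-jittered) centre and the footprint-level canopy-top height
#' label (disc-maximum of the true field plus label noise, clipped at 0).
#'
#' @slot records data.frame with columns `lon_true`, `lat_true`, `lon`,
#'   `lat`, `rh98_m`, `off_grid`.
#' @export
setClass("FootprintSet", representation(records = "data.frame"))

setValidity("FootprintSet", function(object) {
  need <- c("lon_true", "lat_true", "lon", "lat", "rh98_m", "off_grid")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@records) && any(object@records$rh98_m < 0))
    return("labels must be >= 0")
  TRUE
})

#' Mean/variance regression network
#'
#' A fully convolutional residual network with separable convolutions and two
#' 1x1 heads predicting, per pixel, the mean canopy-top height and its
#' log-variance. Parameters live in a single flat numeric vector (see
#' [paramLayout()]); `norm` holds the channel and target standardization
#' statistics fitted on the training split (or `NULL` for a raw-space net).
#'
#' @slot config list with `channels`, `blocks`, `filters`, `seed`.
#' @slot params flat numeric parameter vector.
#' @slot norm `NULL` or list with `chMean`, `chSd`, `yMean`, `ySd`.
#' @export
setClass("CanopyNet",
  representation(config = "list", params = "numeric", norm = "ANY"))

setValidity("CanopyNet", function(object) {
  cf <- object@config
  need <- c("channels", "blocks", "filters")
  if (!all(need %in% names(cf))) return("config must list channels/blocks/filters")
  if (cf$blocks < 1 || cf$filters < 1 || cf$channels < 1)
    return("channels, blocks and filters must be >= 1")
  if (length(object@params) !=
      .cf_n_params(cf$channels, cf$filters, cf$blocks))
    return("parameter vector length does not match the architecture")
  if (!is.null(object@norm)) {
    if (any(object@norm$chSd <= 0) || object@norm$ySd <= 0)
      return("normalization sds must be > 0")
  }
  TRUE
})

#' Deep ensemble of canopy-height networks
#'
#' Independently initialized (and trained) [CanopyNet-class] members sharing
#' one architecture. At inference each acquisition date is processed by one
#' member picked at random, and the per-date estimates are fused by
#' inverse-variance weighting.
#'
#' @slot members list of [CanopyNet-class] objects.
#' @slot seeds integer initialization seeds, one per member, all distinct.
#' @export
setClass("CanopyEnsemble",
  representation(members = "list", seeds = "integer"))

setValidity("CanopyEnsemble", function(object) {
  if (length(object@members) < 1) return("ensemble must have >= 1 member")
  if (length(object@seeds) != length(object@members))
    return("one seed per member required")
  if (anyDuplicated(object@seeds)) return("member seeds must be distinct")
  cfg <- lapply(object@members, function(m) m@config[c("channels", "blocks", "filters")])
  if (!all(vapply(cfg, identical, logical(1), cfg[[1]])))
    return("all members must share one architecture")
  TRUE
})

#' Fused predictive canopy-height map
#'
#' Per-pixel fused mean canopy-top height and predictive standard deviation
#' (square root of the total variance from the weighted law of total
#' variance). Pixels with no valid observation are flagged in `valid` and
#' exported with the nodata sentinel.
#'
#' @slot mean numeric matrix of fused heights (m).
#' @slot sd numeric matrix of predictive standard deviations (m).
#' @slot valid logical matrix; FALSE = nodata.
#' @slot geo a [GeoRef-class].
#' @export
setClass("PredictiveMap",
  representation(mean = "matrix", sd = "matrix", valid = "matrix",
                 geo = "GeoRef"))

setValidity("PredictiveMap", function(object) {
  if (!all(dim(object@mean) == dim(object@sd)) ||
      !all(dim(object@mean) == dim(object@valid)))
    return("mean, sd and valid must share dimensions")
  sv <- object@sd[object@valid]
  if (any(!is.finite(sv)) || any(sv < 0))
    return("sd must be finite and >= 0 where valid")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
setMethod("heights", "HeightField", function(x) x@heights)

#' @rdname accessors
setMethod("heights", "SparseLabelRaster", function(x) x@heights)

#' @rdname accessors
setMethod("validMask", "SparseLabelRaster", function(x) x@valid)

#' @rdname accessors
setMethod("validMask", "PredictiveMap", function(x) x@valid)

#' @rdname accessors
setMethod("geoRef", "HeightField", function(x) x@geo)

#' @rdname accessors
setMethod("geoRef", "AcquisitionStack", function(x) x@geo)

#' @rdname accessors
setMethod("geoRef", "SparseLabelRaster", function(x) x@geo)

#' @rdname accessors
setMethod("geoRef", "PredictiveMap", function(x) x@geo)

#' @rdname accessors
setMethod("predMean", "PredictiveMap", function(x) x@mean)

#' @rdname accessors
setMethod("predSd", "PredictiveMap", function(x) x@sd)

#' @rdname accessors
setMethod("nDates", "AcquisitionStack", function(x) length(x@images))

#' @rdname accessors
setMethod("ensembleSize", "CanopyEnsemble", function(x) length(x@members))

#' Footprint records as a data.frame
#' @param x a [FootprintSet-class].
#' @return the records data.frame.
#' @export
footprintRecords <- function(x) {
  stopifnot(methods::is(x, "FootprintSet"))
  x@records
}

#' Collision / drop diagnostics of a rasterized label set
#' @param x a [SparseLabelRaster-class].
#' @return named integer vector with `collisions` and `dropped`.
#' @export
rasterizeDiagnostics <- function(x) {
  stopifnot(methods::is(x, "SparseLabelRaster"))
  c(collisions = x@collisions, dropped = x@dropped)
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "GeoRef", function(object) {
  cat(sprintf("GeoRef: origin (%.5f, %.5f) deg, gsd %.1f m\n",
              object@lat0, object@lon0, object@gsd))
})

setMethod("show", "HeightField", function(object) {
  h <- object@heights
  cat(sprintf("HeightField: %d x %d px, heights %.1f-%.1f m (mean %.1f)\n",
              nrow(h), ncol(h), min(h), max(h), mean(h)))
})

setMethod("show", "AcquisitionStack", function(object) {
  d <- dim(object@images[[1]])
  clear <- mean(vapply(object@valid, mean, numeric(1)))
  cat(sprintf("AcquisitionStack: %d dates, %d x %d px, %d channels (%d bands + 3 geo), %.0f%% clear\n",
              length(object@images), d[1], d[2], d[3], object@nBands, 100 * clear))
})

setMethod("show", "SparseLabelRaster", function(object) {
  cat(sprintf("SparseLabelRaster: %d x %d px, %d labelled, %d collisions, %d dropped\n",
              nrow(object@heights), ncol(object@heights), sum(object@valid),
              object@collisions, object@dropped))
})

setMethod("show", "FootprintSet", function(object) {
  r <- object@records
  cat(sprintf("FootprintSet: %d footprints (%d off-grid)\n",
              nrow(r), sum(r$off_grid)))
})

setMethod("show", "CanopyNet", function(object) {
  cf <- object@config
  cat(sprintf("CanopyNet: %d channels, %d residual blocks x %d filters, %d parameters%s\n",
              cf$channels, cf$blocks, cf$filters, length(object@params),
              if (is.null(object@norm)) " (no normalization fitted)" else ""))
})

setMethod("show", "CanopyEnsemble", function(object) {
  cat(sprintf("CanopyEnsemble: %d members\n", length(object@members)))
  show(object@members[[1]])
})

setMethod("show", "PredictiveMap", function(object) {
  v <- object@valid
  cat(sprintf("PredictiveMap: %d x %d px, %.0f%% valid", nrow(v), ncol(v),
              100 * mean(v)))
  if (any(v))
    cat(sprintf(", mean height %.1f m, mean sd %.1f m",
                mean(object@mean[v]), mean(object@sd[v])))
  cat("\n")
})
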