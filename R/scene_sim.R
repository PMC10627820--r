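# Synthetic-scene generator.
#
# Emulates the statistical structure the retrieval method assumes: a
# long-tailed, zero-inflated canopy-height distribution with spatial
# correlation; multi-band reflectance stacks whose bands are monotone links
# of height plus texture and date noise; coherent cloud occlusion; and
# large-footprint LiDAR labels (disc maximum) with geolocation jitter and
# label noise, rasterized to the pixel containing the reported centre.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-scene generator. Heights are drawn
#' from a zero-inflated two-component Gaussian mixture (a dominant low mode
#' and a rare tall mode), clipped to `[0, maxHeight]`; spatial correlation is
#' imposed by a Gaussian copula over a Gaussian-smoothed white-noise field.
#'
#' @param gridSize grid side length in pixels.
#' @param gsd ground sampling distance (m).
#' @param nBands number of reflectance bands.
#' @param zeroProb zero-inflation probability (bare ground).
#' @param lowMean,lowSd mean/sd (m) of the dominant low-height mode.
#' @param tallProb probability of the tall mode among vegetated pixels.
#' @param tallMean,tallSd mean/sd (m) of the tall mode.
#' @param maxHeight upper clip (m).
#' @param corrLength spatial correlation length in pixels (Gaussian filter
#'   sigma); 0 = spatially independent pixels. Must be < gridSize.
#' @param links data.frame of per-band link parameters with columns
#'   `type` ("saturating" or "identity"), `a`, `s`, `hscale`; see
#'   [defaultBandLinks()].
#' @param noiseSd per-band per-date reflectance noise sd (recycled to nBands).
#' @param textureSd sd of the shared spatially correlated texture component.
#' @param cloudFraction fraction of cloud-obstructed pixels per date (scalar
#'   or length-nDates vector).
#' @param nDates number of repeated acquisitions T.
#' @param footprintRadius LiDAR footprint disc radius (m); 12.5 m gives the
#'   25-m footprint of a spaceborne large-footprint lidar.
#' @param labelNoiseSd sd (m) of the footprint label noise.
#' @param jitterSd sd (m) of the isotropic geolocation jitter applied to the
#'   reported footprint centre.
#' @param lat0,lon0 geographic origin of the scene (degrees).
#' @param seed integer; fixes all randomness of the generator ops.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(gridSize = 15L, gsd = 10, nBands = 12L,
                      zeroProb = 0.30, lowMean = 8, lowSd = 5,
                      tallProb = 0.05, tallMean = 35, tallSd = 8,
                      maxHeight = 60, corrLength = 3,
                      links = defaultBandLinks(nBands),
                      noiseSd = 0.015, textureSd = 0.01,
                      cloudFraction = 0.2, nDates = 10L,
                      footprintRadius = 12.5, labelNoiseSd = 2,
                      jitterSd = 8, lat0 = 0, lon0 = 0, seed = 1L) {
  cfg <- list(gridSize = as.integer(gridSize), gsd = gsd,
              nBands = as.integer(nBands), zeroProb = zeroProb,
              lowMean = lowMean, lowSd = lowSd, tallProb = tallProb,
              tallMean = tallMean, tallSd = tallSd, maxHeight = maxHeight,
              corrLength = corrLength, links = links,
              noiseSd = rep_len(noiseSd, nBands), textureSd = textureSd,
              cloudFraction = cloudFraction, nDates = as.integer(nDates),
              footprintRadius = footprintRadius, labelNoiseSd = labelNoiseSd,
              jitterSd = jitterSd, lat0 = lat0, lon0 = lon0,
              seed = as.integer(seed))
  probs <- c(zeroProb, tallProb, cloudFraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(c(lowSd, tallSd, cfg$noiseSd, textureSd, labelNoiseSd, jitterSd) < 0))
    stop("standard deviations must be >= 0")
  if (gridSize < 1) stop("gridSize must be positive")
  if (corrLength < 0 || corrLength >= gridSize)
    stop("corrLength must be in [0, gridSize)")
  if (maxHeight <= 0 || tallMean > maxHeight || lowMean > maxHeight)
    stop("mode means must not exceed maxHeight")
  if (!all(c("type", "a", "s", "hscale") %in% names(links)) ||
      nrow(links) != nBands)
    stop("links must have one row per band with columns type/a/s/hscale")
  class(cfg) <- "SimConfig"
  cfg
}

#' Default per-band reflectance links
#'
#' Monotone saturating links `r = a + s * (1 - exp(-h / hscale))` with
#' band-dependent sign and scale: visible bands darken with canopy cover,
#' near-infrared bands brighten strongly, shortwave-infrared bands darken.
#' Values are on the 0-1 surface-reflectance scale.
#'
#' @param nBands number of bands.
#' @return data.frame with columns `type`, `a`, `s`, `hscale`.
#' @export
defaultBandLinks <- function(nBands = 12L) {
  # cycle through visible / red-edge / NIR / SWIR behaviours
  base <- data.frame(
    type = "saturating",
    a = c(0.10, 0.09, 0.08, 0.12, 0.16, 0.22, 0.26, 0.28, 0.30, 0.24, 0.26, 0.20),
    s = c(-0.06, -0.05, -0.05, -0.07, 0.08, 0.14, 0.18, 0.20, 0.22, -0.10, -0.14, -0.11),
    hscale = c(12, 14, 10, 12, 18, 20, 22, 25, 28, 16, 18, 20))
  base[rep_len(seq_len(nrow(base)), nBands), , drop = FALSE]
}

# ---- internals -------------------------------------------------------------

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generator ops do not perturb user code.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Gaussian-smoothed standard-normal field: circular (wrap-around) separable
# convolution of white noise with a Gaussian kernel normalized to unit L2
# norm per axis, so the marginal stays exactly N(0, 1) at every pixel.
.smooth_normal_field <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma <= 0) return(z)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sqrt(sum(k^2))
  conv_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- ((seq_len(n) - 1L + off) %% n) + 1L
      acc <- acc + k[j] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    acc
  }
  conv_axis(conv_axis(z, TRUE), FALSE)
}

# CDF of the clipped zero-inflated height mixture at h >= 0.
.height_cdf <- function(h, cfg) {
  mixcdf <- (1 - cfg$tallProb) * stats::pnorm(h, cfg$lowMean, cfg$lowSd) +
    cfg$tallProb * stats::pnorm(h, cfg$tallMean, cfg$tallSd)
  cfg$zeroProb + (1 - cfg$zeroProb) * mixcdf
}

# Quantile function of the mixture (numeric inversion on a fine grid; point
# masses at 0 and maxHeight from clipping are handled exactly).
.height_quantile <- function(p, cfg) {
  hgrid <- seq(0, cfg$maxHeight, length.out = 4097L)
  Fgrid <- .height_cdf(hgrid, cfg)
  out <- numeric(length(p))
  lo <- p <= Fgrid[1]
  hi <- p >= Fgrid[length(Fgrid)]
  mid <- !(lo | hi)
  out[lo] <- 0
  out[hi] <- cfg$maxHeight
  if (any(mid))
    out[mid] <- stats::approx(Fgrid, hgrid, xout = p[mid],
                              ties = "ordered")$y
  out
}

#' Direct draws from the configured height mixture
#'
#' Samples the pixelwise marginal height distribution of
#' [generateHeightField()] directly (no spatial structure): with probability
#' `zeroProb` a height of 0, otherwise the low or tall Gaussian mode, clipped
#' to `[0, maxHeight]`. Used as an independent sampling oracle for the
#' generator's marginal.
#'
#' @param n number of draws.
#' @param config a [simConfig()].
#' @return numeric vector of heights (m).
#' @export
sampleHeightMixture <- function(n, config) {
  comp <- stats::runif(n)
  tall <- stats::runif(n) < config$tallProb
  h <- ifelse(tall, stats::rnorm(n, config$tallMean, config$tallSd),
              stats::rnorm(n, config$lowMean, config$lowSd))
  h[comp < config$zeroProb] <- 0
  pmin(pmax(h, 0), config$maxHeight)
}

# ---- operations ------------------------------------------------------------

#' Generate a spatially correlated canopy-height field
#'
#' Draws a Gaussian-smoothed standard-normal field and pushes it through the
#' quantile function of the zero-inflated height mixture (a Gaussian copula),
#' so the pixelwise marginal is exactly the configured mixture while spatial
#' correlation produces contiguous bare patches, stands and tall groves.
#' Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return a [HeightField-class].
#' @export
generateHeightField <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$gridSize
  h <- .with_seed(config$seed, {
    g <- .smooth_normal_field(n, n, config$corrLength)
    matrix(.height_quantile(stats::pnorm(g), config), n, n)
  })
  methods::new("HeightField", heights = h,
               geo = geoRefGrid(config$lat0, config$lon0, config$gsd),
               maxHeight = config$maxHeight)
}

#' Render multi-date acquisitions of a height field
#'
#' Produces `nDates` multi-band images: each band is a monotone link of
#' height (see [defaultBandLinks()]) plus a shared spatially correlated
#' texture component and date-specific per-band Gaussian noise. Per date, a
#' spatially coherent cloud mask obstructs `cloudFraction` of the pixels
#' (obstructed pixels are overwritten with a bright cloud deck and flagged
#' invalid). The three cyclic coordinate channels are appended per pixel.
#' Deterministic given `config$seed`.
#'
#' @param field a [HeightField-class].
#' @param config the [simConfig()] used to generate it.
#' @return an [AcquisitionStack-class] with `nBands + 3` channels.
#' @export
renderAcquisitions <- function(field, config) {
  stopifnot(methods::is(field, "HeightField"), inherits(config, "SimConfig"))
  if (config$nDates < 1) stop("nDates must be >= 1")
  h <- field@heights
  H <- nrow(h); W <- ncol(h)
  cloud_frac <- rep_len(config$cloudFraction, config$nDates)
  ll <- pixelLatLon(field@geo, c(H, W))
  enc <- encodeCoordinates(as.vector(ll$lat), as.vector(ll$lon))
  geo_ch <- array(enc, c(H, W, 3L))

  link_band <- function(b) {
    lk <- config$links[b, ]
    if (lk$type == "identity") lk$a + lk$s * h
    else lk$a + lk$s * (1 - exp(-h / lk$hscale))
  }
  base_bands <- lapply(seq_len(config$nBands), link_band)

  out <- .with_seed(config$seed + 10007L, {
    texture <- config$textureSd *
      .smooth_normal_field(H, W, max(config$corrLength, 1))
    images <- vector("list", config$nDates)
    valid <- vector("list", config$nDates)
    for (t in seq_len(config$nDates)) {
      img <- array(0, c(H, W, config$nBands + 3L))
      if (cloud_frac[t] >= 1) {
        clear <- matrix(FALSE, H, W)
      } else if (cloud_frac[t] <= 0) {
        clear <- matrix(TRUE, H, W)
      } else {
        cf <- .smooth_normal_field(H, W, max(config$corrLength, 1))
        thr <- stats::quantile(cf, cloud_frac[t], type = 1)
        clear <- cf > thr
      }
      for (b in seq_len(config$nBands)) {
        band <- base_bands[[b]] + texture +
          matrix(stats::rnorm(H * W, sd = config$noiseSd[b]), H, W)
        band[!clear] <- 0.85 + stats::rnorm(sum(!clear), sd = 0.02)
        img[, , b] <- band
      }
      img[, , config$nBands + (1:3)] <- geo_ch
      images[[t]] <- img
      valid[[t]] <- clear
    }
    list(images = images, valid = valid)
  })
  dates <- as.Date("2020-05-01") + round(seq(0, 150, length.out = config$nDates))
  methods::new("AcquisitionStack", images = out$images, valid = out$valid,
               dates = dates, geo = field@geo, nBands = config$nBands)
}

# Disc maximum of the field around a metric point (x east, y south from the
# grid origin): max over pixels whose centre lies within `radius` metres.
.disc_max <- function(h, gsd, x, y, radius) {
  H <- nrow(h); W <- ncol(h)
  c0 <- max(1L, ceiling((x - radius) / gsd + 0.5))
  c1 <- min(W, floor((x + radius) / gsd + 0.5))
  r0 <- max(1L, ceiling((y - radius) / gsd + 0.5))
  r1 <- min(H, floor((y + radius) / gsd + 0.5))
  best <- -Inf
  if (c1 >= c0 && r1 >= r0) {
    for (cc in c0:c1) {
      dx2 <- ((cc - 0.5) * gsd - x)^2
      for (rr in r0:r1) {
        if (dx2 + ((rr - 0.5) * gsd - y)^2 <= radius^2 && h[rr, cc] > best)
          best <- h[rr, cc]
      }
    }
  }
  if (!is.finite(best)) {
    # radius smaller than half a pixel diagonal: fall back to nearest pixel
    rr <- min(max(1L, floor(y / gsd) + 1L), H)
    cc <- min(max(1L, floor(x / gsd) + 1L), W)
    best <- h[rr, cc]
  }
  best
}

#' Sample LiDAR-like footprints over a height field
#'
#' Footprint centres are uniform over the scene. The label is the maximum of
#' the true field over the disc of `footprintRadius` centred at the TRUE
#' position (pixel-centre distance, inclusive), plus Gaussian label noise,
#' clipped at 0. The REPORTED centre is displaced by isotropic Gaussian
#' geolocation jitter; reported centres outside the grid are flagged
#' `off_grid`. Deterministic given `config$seed`.
#'
#' @param field a [HeightField-class].
#' @param n number of footprints (>= 0).
#' @param config the [simConfig()].
#' @return a [FootprintSet-class].
#' @export
sampleFootprints <- function(field, n, config) {
  stopifnot(methods::is(field, "HeightField"), inherits(config, "SimConfig"))
  if (n < 0) stop("n must be >= 0")
  n <- as.integer(n)
  h <- field@heights
  H <- nrow(h); W <- ncol(h); gsd <- field@geo@gsd
  if (n == 0L) {
    rec <- data.frame(lon_true = numeric(0), lat_true = numeric(0),
                      lon = numeric(0), lat = numeric(0),
                      rh98_m = numeric(0), off_grid = logical(0))
    return(methods::new("FootprintSet", records = rec))
  }
  rec <- .with_seed(config$seed + 20011L, {
    x <- stats::runif(n, 0, W * gsd)
    y <- stats::runif(n, 0, H * gsd)
    lab <- vapply(seq_len(n), function(i)
      .disc_max(h, gsd, x[i], y[i], config$footprintRadius), numeric(1))
    lab <- pmax(lab + stats::rnorm(n, sd = config$labelNoiseSd), 0)
    xr <- x + stats::rnorm(n, sd = config$jitterSd)
    yr <- y + stats::rnorm(n, sd = config$jitterSd)
    off <- xr < 0 | xr >= W * gsd | yr < 0 | yr >= H * gsd
    tru <- .xy_to_lonlat(field@geo, x, y)
    rep_ <- .xy_to_lonlat(field@geo, xr, yr)
    data.frame(lon_true = tru$lon, lat_true = tru$lat,
               lon = rep_$lon, lat = rep_$lat, rh98_m = lab, off_grid = off)
  })
  methods::new("FootprintSet", records = rec)
}

#' Rasterize footprints to the analysis grid
#'
#' Sets the pixel containing each REPORTED footprint centre to the footprint
#' label. Footprints outside the grid are dropped and counted. When several
#' footprints land in one pixel the last-written label wins and the collision
#' counter is incremented (deterministic and auditable).
#'
#' @param fps a [FootprintSet-class].
#' @param dims integer c(H, W) of the target grid.
#' @param geo the grid [GeoRef-class].
#' @return a [SparseLabelRaster-class].
#' @export
rasterizeFootprints <- function(fps, dims, geo) {
  stopifnot(methods::is(fps, "FootprintSet"), methods::is(geo, "GeoRef"))
  H <- dims[1]; W <- dims[2]; gsd <- geo@gsd
  hmat <- matrix(NA_real_, H, W)
  vmat <- matrix(FALSE, H, W)
  collisions <- 0L; dropped <- 0L
  rec <- fps@records
  if (nrow(rec)) {
    xy <- .lonlat_to_xy(geo, rec$lon, rec$lat)
    cc <- floor(xy$x / gsd) + 1L
    rr <- floor(xy$y / gsd) + 1L
    for (i in seq_len(nrow(rec))) {
      if (rec$off_grid[i] || rr[i] < 1 || rr[i] > H || cc[i] < 1 || cc[i] > W) {
        dropped <- dropped + 1L
        next
      }
      if (vmat[rr[i], cc[i]]) collisions <- collisions + 1L
      hmat[rr[i], cc[i]] <- rec$rh98_m[i]
      vmat[rr[i], cc[i]] <- TRUE
    }
  }
  hmat[!vmat] <- 0
  methods::new("SparseLabelRaster", heights = hmat, valid = vmat,
               collisions = collisions, dropped = dropped, geo = geo)
}

#' Zero labels on non-vegetated and water surfaces
#'
#' Applies the scene-classification correction for geolocation noise: labels
#' whose pixel is classed as bare ground or open water are forced to 0 m
#' canopy height (the pixel stays a valid training label).
#'
#' @param labels a [SparseLabelRaster-class].
#' @param classGrid character matrix of surface classes, aligned with the
#'   label grid.
#' @param zeroClasses classes whose labels are set to 0.
#' @return the corrected [SparseLabelRaster-class].
#' @export
applySceneClassZeroing <- function(labels, classGrid,
                                   zeroClasses = c("not_vegetated", "water")) {
  stopifnot(methods::is(labels, "SparseLabelRaster"))
  if (!all(dim(classGrid) == dim(labels@heights)))
    stop("classGrid must be aligned with the label grid")
  zero <- labels@valid & matrix(classGrid %in% zeroClasses, nrow(classGrid))
  labels@heights[zero] <- 0
  labels
}
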