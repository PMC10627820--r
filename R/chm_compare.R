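# GEDI-like canopy-top derivation from high-resolution canopy height models:
# circular max-pooling at the source resolution (stride 1), then aggregation
# to the target grid.

#' Circular max-pooling of a canopy height model
#'
#' Per source pixel, the maximum over the circular neighbourhood of pixels
#' whose CENTRE lies within `radius` metres (inclusive); neighbourhoods are
#' clipped at the grid boundary (no padding values enter the max).
#' Implemented as a shift-and-max sweep over the disc offsets.
#'
#' @param chm numeric matrix of canopy heights (m).
#' @param radius disc radius in metres.
#' @param gsd source ground sampling distance (m).
#' @return matrix of the same dimensions.
#' @export
circularMaxPool <- function(chm, radius, gsd = 1) {
  stopifnot(is.matrix(chm), radius > 0, gsd > 0)
  r <- floor(radius / gsd)
  H <- nrow(chm); W <- ncol(chm)
  out <- matrix(-Inf, H, W)
  for (di in -r:r) for (dj in -r:r) {
    if ((di * gsd)^2 + (dj * gsd)^2 > radius^2) next
    ri <- max(1L, 1L - di):min(H, H - di)
    cj <- max(1L, 1L - dj):min(W, W - dj)
    out[ri, cj] <- pmax(out[ri, cj], chm[ri + di, cj + dj])
  }
  out
}

# Aggregate an H x W matrix by integer blocks.
.block_aggregate <- function(m, factor, agg = c("mean", "nearest", "max")) {
  agg <- match.arg(agg)
  H <- nrow(m); W <- ncol(m)
  if (H %% factor != 0 || W %% factor != 0)
    stop("grid dimensions must be multiples of the aggregation factor")
  Ho <- H %/% factor; Wo <- W %/% factor
  if (agg == "nearest") {
    pick <- (seq_len(Ho) - 1L) * factor + (factor + 1L) %/% 2L
    pickc <- (seq_len(Wo) - 1L) * factor + (factor + 1L) %/% 2L
    return(m[pick, pickc, drop = FALSE])
  }
  a <- array(m, c(factor, Ho, factor, Wo))
  if (agg == "mean") apply(a, c(2, 4), base::mean)
  else apply(a, c(2, 4), max)
}

#' GEDI-like canopy-top raster from a high-resolution CHM
#'
#' Emulates a large-footprint LiDAR canopy-top metric from a fine-grained
#' canopy height model: circular max-pooling with `radius` (default 12 m) at
#' the source resolution with stride 1, followed by aggregation to the
#' target grid (default 10 m; block mean by default, `nearest` and `max`
#' also available). The max-pooling step makes the product comparable to
#' footprint-level canopy-top heights, which depend on the footprint size.
#'
#' @param chm numeric matrix, the source CHM (heights >= 0, m).
#' @param radius pooling radius (m).
#' @param sourceGsd source GSD (m); must be finer than `targetGsd`.
#' @param targetGsd target GSD (m); must be an integer multiple of
#'   `sourceGsd`.
#' @param agg aggregation operator: `"mean"`, `"nearest"` or `"max"`.
#' @return matrix at the target GSD.
#' @export
gediLikeCanopyTop <- function(chm, radius = 12, sourceGsd = 1,
                              targetGsd = 10,
                              agg = c("mean", "nearest", "max")) {
  agg <- match.arg(agg)
  stopifnot(is.matrix(chm), radius > 0)
  if (any(chm < 0)) stop("CHM heights must be >= 0")
  factor <- targetGsd / sourceGsd
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("targetGsd must be an integer multiple of sourceGsd")
  pooled <- circularMaxPool(chm, radius, sourceGsd)
  .block_aggregate(pooled, as.integer(round(factor)), agg)
}
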