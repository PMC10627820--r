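# Shared fixtures: tiny configurations and hand-built objects used across
# test files. Everything is generated in code; no stored data.

# A small, fully deterministic simulation configuration for structural tests.
tiny_sim <- function(...) {
  args <- utils::modifyList(list(gridSize = 12L, nDates = 3L,
                                 cloudFraction = 0, labelNoiseSd = 0,
                                 jitterSd = 0, seed = 1L),
                            list(...))
  do.call(simConfig, args)
}

# Constant-height field on an n x n grid.
const_field <- function(h, n = 12L, gsd = 10, maxHeight = 60) {
  methods::new("HeightField", heights = matrix(h, n, n),
               geo = geoRefGrid(0, 0, gsd), maxHeight = maxHeight)
}

# Footprint set from explicit metre offsets (x east, y south) on a grid with
# origin (0, 0); labels in metres.
fps_at_xy <- function(x, y, labels, geo = geoRefGrid(0, 0, 10)) {
  ll <- canopyfuse:::.xy_to_lonlat(geo, x, y)
  methods::new("FootprintSet", records = data.frame(
    lon_true = ll$lon, lat_true = ll$lat, lon = ll$lon, lat = ll$lat,
    rh98_m = labels, off_grid = FALSE))
}

# A small untrained network with a fixed seed.
tiny_net <- function(channels = 15L, blocks = 2L, filters = 8L, seed = 1L) {
  canopyNet(networkConfig(channels = channels, blocks = blocks,
                          filters = filters, seed = seed))
}

# Literal, independent re-implementations of the evaluation formulas used as
# oracles (simple loops, no shared code with the package internals).
oracle_rmse <- function(p, r) sqrt(sum((p - r)^2) / length(p))
oracle_mae <- function(p, r) sum(abs(p - r)) / length(p)
oracle_me <- function(p, r) sum(p - r) / length(p)
oracle_nme <- function(p, r) 100 / (mean(r) * length(p)) * sum(p - r)
oracle_uce <- function(p, u, r, K) {
  ord <- order(u, seq_along(u))
  size <- length(u) %/% K
  uce <- 0; auce <- 0
  for (k in seq_len(K)) {
    sel <- if (k < K) ord[((k - 1) * size + 1):(k * size)]
           else ord[((K - 1) * size + 1):length(u)]
    err <- sqrt(mean((p[sel] - r[sel])^2))
    rmv <- sqrt(mean(u[sel]))
    uce <- uce + length(sel) / length(u) * abs(err - rmv)
    auce <- auce + abs(err - rmv) / K
  }
  list(uce = uce, auce = auce)
}

# Brute-force disc-scan canopy-top oracle on a 1-m CHM: per source pixel the
# max over centres within `radius`, then block aggregation.
oracle_gedi_like <- function(chm, radius, factor) {
  H <- nrow(chm); W <- ncol(chm)
  pooled <- matrix(NA_real_, H, W)
  r <- ceiling(radius)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    best <- -Inf
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      if (di^2 + dj^2 > radius^2) next
      if (chm[ii, jj] > best) best <- chm[ii, jj]
    }
    pooled[i, j] <- best
  }
  out <- matrix(0, H / factor, W / factor)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- mean(pooled[((i - 1) * factor + 1):(i * factor),
                             ((j - 1) * factor + 1):(j * factor)])
  }
  out
}
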