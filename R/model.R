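# Mean/variance fully convolutional network: configuration, initialization
# and inference. The compiled kernel lives in src/canopynet.cpp.
#
# Block structure (documented contract): with x the incoming F-channel
# activation,
#   out = ReLU(x + P2 %*% DW2(ReLU(P1 %*% DW1(x) + c1)) + c2)
# where DWk is a depthwise 3x3 convolution (zero padding) and Pk a pointwise
# 1x1 convolution. The entry layer is a pointwise projection of the input
# channels to F filters followed by ReLU; the two heads are 1x1 convolutions
# on the shared trunk. The variance head predicts log-variance and is
# exponentiated, so the predicted variance is strictly positive for any
# finite weights. There is no downsampling anywhere: output dims equal input
# dims, and each depthwise layer grows the receptive field by one pixel per
# side (margin = 2 * blocks).

#' Network architecture configuration
#'
#' @param profile `"small"` (2 blocks x 32 filters, the desk-scale default)
#'   or `"paper"` (8 blocks x 256 filters, the deployment-scale profile).
#'   Explicit `blocks` / `filters` override the profile.
#' @param channels number of input channels (bands + 3 coordinate channels).
#' @param blocks number of residual blocks.
#' @param filters filters per block.
#' @param seed initialization seed.
#' @return a list of class `NetworkConfig`.
#' @export
networkConfig <- function(profile = c("small", "paper"), channels = 15L,
                          blocks = NULL, filters = NULL, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(blocks)) blocks <- if (profile == "small") 2L else 8L
  if (is.null(filters)) filters <- if (profile == "small") 32L else 256L
  if (blocks < 1 || filters < 1 || channels < 1)
    stop("channels, blocks and filters must be >= 1")
  structure(list(channels = as.integer(channels), blocks = as.integer(blocks),
                 filters = as.integer(filters), seed = as.integer(seed)),
            class = "NetworkConfig")
}

#' Flat parameter-vector layout
#'
#' Index ranges of each parameter tensor inside the flat vector of a
#' [CanopyNet-class]; mirrors the compiled kernel's layout. Used for
#' head-scoped fine-tuning and for verifying that fine-tuning leaves the
#' trunk and the variance head untouched.
#'
#' @param config a [networkConfig()].
#' @return named list of integer index vectors (`W0`, `b0`,
#'   `block<k>.D1/P1/c1/D2/P2/c2`, `Wm`, `bm`, `Wv`, `bv`).
#' @export
paramLayout <- function(config) {
  Cin <- config$channels; F <- config$filters; B <- config$blocks
  out <- list()
  pos <- 0L
  take <- function(n) {
    idx <- pos + seq_len(n)
    pos <<- pos + as.integer(n)
    idx
  }
  out$W0 <- take(F * Cin)
  out$b0 <- take(F)
  for (b in seq_len(B)) {
    out[[sprintf("block%d.D1", b)]] <- take(9L * F)
    out[[sprintf("block%d.P1", b)]] <- take(F * F)
    out[[sprintf("block%d.c1", b)]] <- take(F)
    out[[sprintf("block%d.D2", b)]] <- take(9L * F)
    out[[sprintf("block%d.P2", b)]] <- take(F * F)
    out[[sprintf("block%d.c2", b)]] <- take(F)
  }
  out$Wm <- take(F)
  out$bm <- take(1L)
  out$Wv <- take(F)
  out$bv <- take(1L)
  stopifnot(pos == .cf_n_params(Cin, F, B))
  out
}

#' Initialize a canopy-height network
#'
#' He-style initialization: weights drawn N(0, 2/fan_in), biases 0. The
#' variance-head bias starts at 0, i.e. unit variance in normalized target
#' space. Deterministic given `config$seed`.
#'
#' @param config a [networkConfig()].
#' @return an untrained [CanopyNet-class] (no normalization fitted).
#' @export
canopyNet <- function(config) {
  stopifnot(inherits(config, "NetworkConfig"))
  lay <- paramLayout(config)
  npar <- .cf_n_params(config$channels, config$filters, config$blocks)
  params <- numeric(npar)
  fan_in <- function(name) {
    if (name == "W0") config$channels
    else if (grepl("\\.D[12]$", name)) 9
    else if (grepl("\\.P[12]$", name)) config$filters
    else if (name %in% c("Wm", "Wv")) config$filters
    else 0  # biases
  }
  params <- .with_seed(config$seed, {
    for (name in names(lay)) {
      fi <- fan_in(name)
      if (fi > 0)
        params[lay[[name]]] <- stats::rnorm(length(lay[[name]]),
                                            sd = sqrt(2 / fi))
    }
    # damp the head weights so initial outputs are near (0, unit variance)
    params[lay$Wm] <- params[lay$Wm] * 0.1
    params[lay$Wv] <- params[lay$Wv] * 0.1
    params
  })
  methods::new("CanopyNet", config = unclass(config), params = params,
               norm = NULL)
}

#' Receptive-field margin of a network
#'
#' Number of pixels per side over which zero padding can influence an output
#' pixel: two depthwise 3x3 layers per residual block, one pixel each.
#'
#' @param net a [CanopyNet-class] (or a [networkConfig()]).
#' @return integer margin in pixels.
#' @export
receptiveFieldMargin <- function(net) {
  cf <- if (methods::is(net, "CanopyNet")) net@config else net
  2L * cf$blocks
}

# Convert an H x W x C array into the Cin x (H*W) matrix the kernel expects
# (pixels in R column-major order), applying channel normalization if fitted.
.image_to_input <- function(net, img) {
  d <- dim(img)
  stopifnot(length(d) == 3)
  if (d[3] != net@config$channels)
    stop(sprintf("input has %d channels but the network expects %d",
                 d[3], net@config$channels))
  x <- matrix(aperm(img, c(3, 1, 2)), nrow = d[3])
  if (!is.null(net@norm))
    x <- (x - net@norm$chMean) / net@norm$chSd
  x
}

# Single forward pass over a full grid; returns normalized-space mu / logvar
# matrices.
.forward_raw <- function(net, x, H, W) {
  cf <- net@config
  out <- .cf_forward(net@params, cf$channels, cf$filters, cf$blocks, x, H, W)
  list(mu = matrix(out$mu, H, W), logvar = matrix(out$logvar, H, W))
}

#' Dense mean/variance prediction for one acquisition
#'
#' Runs the fully convolutional network over a single multi-channel image and
#' returns dense mean and variance grids at input resolution, in metres
#' (denormalized with the network's fitted target statistics). Arbitrary
#' input sizes are accepted; for grids larger than `window`, inference is
#' windowed with an overlap of the receptive-field margin and centre-cropped
#' stitching, which reproduces whole-grid inference exactly on interiors.
#'
#' @param net a trained [CanopyNet-class].
#' @param image an H x W x C array (C = `channels`).
#' @param window `NULL` for a single pass, or an integer window side length
#'   (> 2 * margin) for tiled inference.
#' @return list with numeric H x W matrices `mean` (m) and `variance` (m^2).
#' @export
predictGrid <- function(net, image, window = NULL) {
  stopifnot(methods::is(net, "CanopyNet"))
  d <- dim(image)
  H <- d[1]; W <- d[2]
  margin <- receptiveFieldMargin(net)
  if (is.null(window) || (window >= H && window >= W)) {
    x <- .image_to_input(net, image)
    out <- .forward_raw(net, x, H, W)
  } else {
    if (window <= 2 * margin)
      stop("window must exceed twice the receptive-field margin")
    mu <- matrix(NA_real_, H, W)
    lv <- matrix(NA_real_, H, W)
    starts <- function(n) {
      if (n <= window) return(1L)
      s <- seq(1L, n - window + 1L, by = window - 2L * margin)
      if (s[length(s)] != n - window + 1L) s <- c(s, n - window + 1L)
      s
    }
    for (r0 in starts(H)) for (c0 in starts(W)) {
      r1 <- min(r0 + window - 1L, H)
      c1 <- min(c0 + window - 1L, W)
      sub <- image[r0:r1, c0:c1, , drop = FALSE]
      o <- .forward_raw(net, .image_to_input(net, sub), r1 - r0 + 1L,
                        c1 - c0 + 1L)
      # keep the centre crop; extend to the tile edge at the boundary
      kr0 <- if (r0 == 1L) 1L else margin + 1L
      kr1 <- (r1 - r0 + 1L) - if (r1 == H) 0L else margin
      kc0 <- if (c0 == 1L) 1L else margin + 1L
      kc1 <- (c1 - c0 + 1L) - if (c1 == W) 0L else margin
      mu[(r0 + kr0 - 1L):(r0 + kr1 - 1L), (c0 + kc0 - 1L):(c0 + kc1 - 1L)] <-
        o$mu[kr0:kr1, kc0:kc1]
      lv[(r0 + kr0 - 1L):(r0 + kr1 - 1L), (c0 + kc0 - 1L):(c0 + kc1 - 1L)] <-
        o$logvar[kr0:kr1, kc0:kc1]
    }
    out <- list(mu = mu, logvar = lv)
  }
  v <- exp(out$logvar)
  if (!is.null(net@norm)) {
    out$mu <- out$mu * net@norm$ySd + net@norm$yMean
    v <- v * net@norm$ySd^2
  }
  list(mean = out$mu, variance = v)
}
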