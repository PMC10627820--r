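# Sparse-supervision training: Gaussian NLL at labelled pixels only,
# channel/target standardization fitted on the training split, Adam with a
# two-milestone step-decay schedule, inverse-frequency balanced reweighting
# and mean-head-only fine-tuning.

#' Training configuration
#'
#' The deployment-scale schedule (5,000,000 iterations, batch 64, base
#' learning rate 1e-4, decay by 0.1 after 2/5 and 7/10 of the run) is scaled
#' down by keeping the milestone fractions and batch size while shortening
#' the run; the desk-scale default raises the base learning rate to 1e-3,
#' appropriate for short schedules on small synthetic sets.
#'
#' @param iterations number of optimizer steps.
#' @param batchSize patches per step.
#' @param baseLr initial Adam learning rate.
#' @param milestoneFractions fractions of `iterations` after which the
#'   learning rate is multiplied by `decayFactor`.
#' @param decayFactor multiplicative decay at each milestone.
#' @param finetuneIterations steps for mean-head fine-tuning.
#' @param seed seed for batch sampling.
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(iterations = 2000L, batchSize = 64L, baseLr = 1e-3,
                        milestoneFractions = c(0.4, 0.7), decayFactor = 0.1,
                        finetuneIterations = 500L, seed = 1L) {
  if (iterations < 1 || batchSize < 1 || finetuneIterations < 0)
    stop("iterations, batchSize and finetuneIterations must be positive")
  if (any(milestoneFractions <= 0) || any(milestoneFractions >= 1))
    stop("milestone fractions must lie strictly between 0 and 1")
  structure(list(iterations = as.integer(iterations),
                 batchSize = as.integer(batchSize), baseLr = baseLr,
                 milestoneFractions = sort(milestoneFractions),
                 decayFactor = decayFactor,
                 finetuneIterations = as.integer(finetuneIterations),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given iteration
#'
#' @param cfg a [trainConfig()].
#' @param iteration 1-based iteration index.
#' @param iterations total run length (defaults to `cfg$iterations`).
#' @return the step-decayed learning rate.
#' @export
learningRateAt <- function(cfg, iteration, iterations = cfg$iterations) {
  passed <- sum(iteration > cfg$milestoneFractions * iterations)
  cfg$baseLr * cfg$decayFactor^passed
}

#' Build a training set from simulated scenes
#'
#' One training sample per (scene, date) pair that has at least one labelled
#' pixel with a clear view on that date; labelled pixels that are
#' cloud-obstructed on a given date are excluded from that sample's loss.
#'
#' @param scenes list of scenes, each a list with elements `stack`
#'   ([AcquisitionStack-class]) and `labels` ([SparseLabelRaster-class]).
#' @return a list of class `TrainingSet`: samples with raw input matrices,
#'   0-based labelled pixel indices and labels in metres.
#' @export
buildTrainingSet <- function(scenes) {
  samples <- list()
  for (sc in scenes) {
    stack <- sc$stack; labels <- sc$labels
    stopifnot(methods::is(stack, "AcquisitionStack"),
              methods::is(labels, "SparseLabelRaster"))
    d <- dim(stack@images[[1]])
    for (t in seq_len(nDates(stack))) {
      usable <- labels@valid & stack@valid[[t]]
      if (!any(usable)) next
      idx0 <- which(usable) - 1L
      samples[[length(samples) + 1L]] <- list(
        x = matrix(aperm(stack@images[[t]], c(3, 1, 2)), nrow = d[3]),
        idx = idx0,
        y = labels@heights[usable],
        H = d[1], W = d[2])
    }
  }
  if (!length(samples)) stop("no usable (scene, date) samples")
  structure(list(samples = samples), class = "TrainingSet")
}

#' Channel and target standardization statistics
#'
#' Per-channel mean/sd over all pixels of the training samples and mean/sd of
#' the training labels (metres). Computed on the training split only and
#' stored inside the network so inference denormalizes consistently.
#'
#' @param ts a [buildTrainingSet()] result.
#' @return list with `chMean`, `chSd` (length channels) and `yMean`, `ySd`.
#' @export
normalizationStats <- function(ts) {
  stopifnot(inherits(ts, "TrainingSet"))
  xs <- do.call(cbind, lapply(ts$samples, `[[`, "x"))
  y <- unlist(lapply(ts$samples, `[[`, "y"))
  chSd <- apply(xs, 1, stats::sd)
  chSd[chSd < 1e-12] <- 1  # constant channels (e.g. geo channels of one site)
  ySd <- stats::sd(y)
  if (!is.finite(ySd) || ySd < 1e-12) ySd <- 1
  list(chMean = rowMeans(xs), chSd = chSd, yMean = mean(y), ySd = ySd)
}

#' Sparse Gaussian negative log likelihood
#'
#' Mean over labelled pixels of `(mu - y)^2 / (2 sigma^2) + log(sigma^2) / 2`,
#' optionally multiplied per sample by the balance weight of the label's 1-m
#' height bin. Unlabelled pixels contribute nothing.
#'
#' @param mean,variance numeric matrices (or vectors) of predicted means and
#'   variances; `variance` must be > 0 at labelled pixels.
#' @param labels a [SparseLabelRaster-class], or a list with `heights` and
#'   `valid` of matching shape.
#' @param weights optional [computeBalanceWeights()] result.
#' @return scalar loss.
#' @export
sparseNllLoss <- function(mean, variance, labels, weights = NULL) {
  if (methods::is(labels, "SparseLabelRaster"))
    labels <- list(heights = labels@heights, valid = labels@valid)
  if (length(mean) != length(labels$heights) ||
      length(variance) != length(labels$heights))
    stop("mean/variance dims must match the label grid")
  v <- labels$valid
  if (!any(v)) stop("no labelled pixels: loss is undefined")
  mu <- mean[v]; s2 <- variance[v]; y <- labels$heights[v]
  if (any(s2 <= 0)) stop("variance must be strictly positive")
  terms <- (mu - y)^2 / (2 * s2) + 0.5 * log(s2)
  if (!is.null(weights)) terms <- terms * balanceWeightFor(weights, y)
  base::mean(terms)
}

#' Square-root inverse-frequency balance weights
#'
#' Bins labels into 1-m height intervals `[k, k+1)` and assigns each bin the
#' normalized square root of its inverse count,
#' `q_k = sqrt(1/N_k) / sum_j sqrt(1/N_j)`, the moderated reweighting used to
#' counter the long-tailed height distribution. Empty bins are excluded from
#' the normalization and carry weight 0.
#'
#' @param heights numeric vector of labels (m).
#' @param binWidth bin width (m).
#' @param maxHeight optional upper clip; labels above it fall into the final
#'   bin.
#' @return list of class `BalanceWeights` with `edges`, `counts`, `q`, `K`.
#' @export
computeBalanceWeights <- function(heights, binWidth = 1, maxHeight = NULL) {
  if (!length(heights)) stop("at least one label is required")
  if (any(heights < 0)) stop("labels must be >= 0")
  if (!is.null(maxHeight)) heights <- pmin(heights, maxHeight)
  k <- floor(heights / binWidth)
  K <- as.integer(max(k)) + 1L
  counts <- tabulate(k + 1L, nbins = K)
  q <- numeric(K)
  ne <- counts > 0
  q[ne] <- sqrt(1 / counts[ne])
  q <- q / sum(q)
  structure(list(edges = seq(0, K * binWidth, by = binWidth), counts = counts,
                 q = q, K = K, binWidth = binWidth),
            class = "BalanceWeights")
}

#' Balance weight of each label
#'
#' @param weights a [computeBalanceWeights()] result.
#' @param heights labels (m); heights beyond the last bin are clipped into it.
#' @return numeric vector of per-label weights `q_k`.
#' @export
balanceWeightFor <- function(weights, heights) {
  stopifnot(inherits(weights, "BalanceWeights"))
  k <- pmin(pmax(floor(heights / weights$binWidth), 0), weights$K - 1L)
  weights$q[k + 1L]
}

# Shared Adam loop. updateIdx = NULL updates all parameters; otherwise only
# the listed indices (head-scoped fine-tuning). balance = NULL gives the
# unweighted loss.
.train_loop <- function(net, ts, cfg, iterations, updateIdx = NULL,
                        balance = NULL, seed = cfg$seed) {
  stopifnot(methods::is(net, "CanopyNet"), inherits(ts, "TrainingSet"))
  if (is.null(net@norm)) net@norm <- normalizationStats(ts)
  nm <- net@norm
  cf <- net@config
  H <- ts$samples[[1]]$H; W <- ts$samples[[1]]$W
  xs <- lapply(ts$samples, function(s) (s$x - nm$chMean) / nm$chSd)
  idx <- lapply(ts$samples, `[[`, "idx")
  yn <- lapply(ts$samples, function(s) (s$y - nm$yMean) / nm$ySd)
  wts <- if (is.null(balance)) {
    lapply(ts$samples, function(s) rep(1, length(s$y)))
  } else {
    lapply(ts$samples, function(s) balanceWeightFor(balance, s$y))
  }
  params <- net@params
  if (iterations < 1)
    return(list(net = net, trace = data.frame(iteration = integer(0),
                                              lr = numeric(0),
                                              loss = numeric(0))))
  m <- numeric(length(params)); v <- numeric(length(params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- data.frame(iteration = seq_len(iterations), lr = NA_real_,
                      loss = NA_real_)
  .with_seed(seed, {
    for (it in seq_len(iterations)) {
      lr <- learningRateAt(cfg, it, iterations)
      batch <- sample.int(length(xs), cfg$batchSize, replace = TRUE)
      g <- .cf_batch_grad(params, cf$channels, cf$filters, cf$blocks,
                          xs[batch], idx[batch], yn[batch], wts[batch], H, W)
      if (!is.finite(g$loss))
        stop(sprintf("non-finite loss at iteration %d (lr %.2g); aborting",
                     it, lr))
      grad <- g$grad
      if (!is.null(updateIdx)) {
        upd <- updateIdx
      } else {
        upd <- seq_along(params)
      }
      m[upd] <- b1 * m[upd] + (1 - b1) * grad[upd]
      v[upd] <- b2 * v[upd] + (1 - b2) * grad[upd]^2
      mhat <- m[upd] / (1 - b1^it)
      vhat <- v[upd] / (1 - b2^it)
      params[upd] <- params[upd] - lr * mhat / (sqrt(vhat) + eps)
      trace$lr[it] <- lr
      trace$loss[it] <- g$loss
    }
  })
  net@params <- params
  list(net = net, trace = trace)
}

#' Train a network with sparse supervision
#'
#' Adam on the sparse Gaussian NLL in normalized space, with the step-decay
#' schedule of [trainConfig()]. Fits and stores normalization statistics from
#' the training set if the network has none. Deterministic given `cfg$seed`.
#' A non-finite loss aborts with diagnostics.
#'
#' @param net a [canopyNet()].
#' @param ts a [buildTrainingSet()] result.
#' @param cfg a [trainConfig()].
#' @param balance optional [computeBalanceWeights()] result for a balanced
#'   loss throughout training (fine-tuning normally uses
#'   [finetuneMeanHead()] instead).
#' @return list with the trained `net` and the loss `trace`
#'   (iteration, lr, loss).
#' @export
trainNetwork <- function(net, ts, cfg = trainConfig(), balance = NULL) {
  .train_loop(net, ts, cfg, cfg$iterations, updateIdx = NULL,
              balance = balance)
}

#' Height-balanced fine-tuning of the mean head
#'
#' Continues training with the balance-weighted loss, updating ONLY the
#' final mean-regression layer (`Wm`, `bm`); the trunk and the variance head
#' are bit-identical before and after, which preserves the uncertainty
#' calibration.
#'
#' @param net a trained [CanopyNet-class].
#' @param ts the training set.
#' @param weights a [computeBalanceWeights()] result (required).
#' @param cfg a [trainConfig()]; `finetuneIterations` steps are run.
#' @return list with the fine-tuned `net` and the loss `trace`.
#' @export
finetuneMeanHead <- function(net, ts, weights, cfg = trainConfig()) {
  if (missing(weights) || is.null(weights))
    stop("balance weights are required for fine-tuning")
  if (is.null(net@norm))
    stop("net must have been trained (normalization statistics missing)")
  lay <- paramLayout(structure(net@config, class = "NetworkConfig"))
  .train_loop(net, ts, cfg, cfg$finetuneIterations,
              updateIdx = c(lay$Wm, lay$bm), balance = weights,
              seed = cfg$seed + 1L)
}
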