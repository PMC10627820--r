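# Deep-ensemble construction, random member-per-acquisition assignment and
# inverse-variance fusion with full variance propagation.

#' Train a deep ensemble
#'
#' Trains `nMembers` networks of identical architecture from independent
#' random initializations (distinct member seeds derived deterministically
#' from `seed`) on the same training set. The deployment-scale ensemble size
#' is five.
#'
#' @param netConfig a [networkConfig()] (its seed is overridden per member).
#' @param ts a [buildTrainingSet()] result.
#' @param cfg a [trainConfig()].
#' @param nMembers ensemble size.
#' @param seed base seed for member initialization and batch sampling.
#' @param balance optional [computeBalanceWeights()] passed to training.
#' @return a [CanopyEnsemble-class].
#' @export
trainEnsemble <- function(netConfig, ts, cfg = trainConfig(), nMembers = 5L,
                          seed = 1L, balance = NULL) {
  memberSeeds <- as.integer(seed + 7919L * seq_len(nMembers))
  members <- vector("list", nMembers)
  for (i in seq_len(nMembers)) {
    mc <- networkConfig(channels = netConfig$channels,
                        blocks = netConfig$blocks,
                        filters = netConfig$filters, seed = memberSeeds[i])
    mcfg <- cfg
    mcfg$seed <- as.integer(cfg$seed + 104729L * i)
    members[[i]] <- trainNetwork(canopyNet(mc), ts, mcfg,
                                 balance = balance)$net
  }
  methods::new("CanopyEnsemble", members = members, seeds = memberSeeds)
}

#' Fine-tune the mean head of every ensemble member
#'
#' @param ens a [CanopyEnsemble-class].
#' @param ts the training set.
#' @param weights a [computeBalanceWeights()] result.
#' @param cfg a [trainConfig()].
#' @return the fine-tuned [CanopyEnsemble-class].
#' @export
finetuneEnsemble <- function(ens, ts, weights, cfg = trainConfig()) {
  stopifnot(methods::is(ens, "CanopyEnsemble"))
  for (i in seq_along(ens@members)) {
    mcfg <- cfg
    mcfg$seed <- as.integer(cfg$seed + 104729L * i + 1L)
    ens@members[[i]] <- finetuneMeanHead(ens@members[[i]], ts, weights,
                                         mcfg)$net
  }
  ens
}

#' Random member-per-acquisition assignment
#'
#' Each acquisition date is processed by one ensemble member drawn uniformly
#' and independently; deterministic given `seed` and side-effect free on the
#' caller's RNG state.
#'
#' @param T number of acquisition dates.
#' @param K ensemble size.
#' @param seed integer seed.
#' @return integer vector of length `T` with member indices in `1..K`.
#' @export
assignMembers <- function(T, K, seed = 1L) {
  if (T < 1 || K < 1) stop("T and K must be >= 1")
  .with_seed(seed, sample.int(K, T, replace = TRUE))
}

#' Inverse-variance fusion of per-date estimates
#'
#' Per pixel, over the valid dates: weights `p_t = (1/s2_t) / sum_j (1/s2_j)`,
#' fused mean `sum_t p_t mu_t`, and total variance by the weighted law of
#' total variance,
#' `Var = sum_t p_t mu_t^2 - (sum_t p_t mu_t)^2 + sum_t p_t s2_t`
#' (between-date disagreement plus weighted aleatoric variance). Pixels with
#' no valid date get `nValid = 0` and NA outputs. Variances are floored at
#' `varFloor` before inversion to avoid overflow; the number of floored
#' values is reported.
#'
#' @param mu,s2 T x n matrices (rows = dates) of means (m) and variances
#'   (m^2); vectors are treated as a single pixel.
#' @param valid optional T x n logical matrix of usable observations
#'   (default: all).
#' @param varFloor numeric floor applied to `s2` (m^2).
#' @return list with numeric n-vectors `mean`, `variance`, the T x n weight
#'   matrix `weights` (columns sum to 1 where any date is valid), integer
#'   `nValid`, and `nFloored`.
#' @export
fuseEstimates <- function(mu, s2, valid = NULL, varFloor = 1e-6) {
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 1)
  if (is.null(dim(s2))) s2 <- matrix(s2, ncol = 1)
  stopifnot(all(dim(mu) == dim(s2)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(mu), ncol(mu))
  stopifnot(all(dim(valid) == dim(mu)))
  if (any(s2[valid] <= 0)) stop("variances must be strictly positive")
  nFloored <- sum(s2[valid] < varFloor)
  s2 <- pmax(s2, varFloor)
  w <- ifelse(valid, 1 / s2, 0)
  wsum <- colSums(w)
  nValid <- colSums(valid)
  p <- sweep(w, 2, ifelse(wsum > 0, wsum, 1), "/")
  mu0 <- ifelse(valid, mu, 0)
  s20 <- ifelse(valid, s2, 0)
  ybar <- colSums(p * mu0)
  vtot <- colSums(p * mu0^2) - ybar^2 + colSums(p * s20)
  # guard tiny negative round-off in the between-date term
  vtot <- pmax(vtot, 0)
  ybar[nValid == 0] <- NA_real_
  vtot[nValid == 0] <- NA_real_
  list(mean = ybar, variance = vtot, weights = p,
       nValid = as.integer(nValid), nFloored = as.integer(nFloored))
}

#' Fuse per-date prediction grids into a predictive map
#'
#' Grid-level wrapper around [fuseEstimates()]: takes per-date mean and
#' variance grids with their validity masks and returns the fused
#' [PredictiveMap-class] (mean in metres, predictive standard deviation
#' `sqrt(Var)`); pixels with no valid date become nodata.
#'
#' @param muList,varList lists (length T) of H x W matrices.
#' @param validList list (length T) of H x W logical matrices.
#' @param geo a [GeoRef-class].
#' @return a [PredictiveMap-class].
#' @export
fuseAcquisitions <- function(muList, varList, validList, geo = geoRefGrid()) {
  T <- length(muList)
  stopifnot(T >= 1, length(varList) == T, length(validList) == T)
  d <- dim(muList[[1]])
  mu <- do.call(rbind, lapply(muList, as.vector))
  s2 <- do.call(rbind, lapply(varList, as.vector))
  va <- do.call(rbind, lapply(validList, as.vector))
  fu <- fuseEstimates(mu, s2, va)
  ok <- fu$nValid > 0
  mn <- matrix(ifelse(ok, fu$mean, 0), d[1], d[2])
  sd_ <- matrix(ifelse(ok, sqrt(fu$variance), 0), d[1], d[2])
  methods::new("PredictiveMap", mean = mn, sd = sd_,
               valid = matrix(ok, d[1], d[2]), geo = geo)
}
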