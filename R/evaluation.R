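# Accuracy and uncertainty-calibration metrics, height-balanced variants and
# uncertainty-based filtering protocols.

#' Metrics report
#'
#' Point metrics (RMSE, MAE, ME, NME) and/or height-balanced metrics
#' (aRMSE, aMAE, aME with the per-interval table). A negative ME means the
#' predictions are systematically lower than the reference.
#'
#' @slot rmse,mae,me,nme point metrics; NME is in percent.
#' @slot n number of samples.
#' @slot aRMSE,aMAE,aME unweighted means of the per-interval metrics over
#'   nonempty reference-height intervals.
#' @slot intervalTable data.frame of the per-interval metrics.
#' @slot interval interval width (m) of the balanced metrics.
#' @export
setClass("MetricsReport",
  representation(rmse = "numeric", mae = "numeric", me = "numeric",
                 nme = "numeric", n = "integer", aRMSE = "numeric",
                 aMAE = "numeric", aME = "numeric",
                 intervalTable = "data.frame", interval = "numeric"))

setValidity("MetricsReport", function(object) {
  if (object@n < 1) return("n must be > 0")
  if (is.finite(object@rmse) && is.finite(object@mae) &&
      object@rmse < object@mae - 1e-9)
    return("RMSE cannot be smaller than MAE")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n = %d)\n", object@n))
  if (is.finite(object@rmse))
    cat(sprintf("  RMSE %.3f m  MAE %.3f m  ME %+.3f m  NME %+.2f%%\n",
                object@rmse, object@mae, object@me, object@nme))
  if (is.finite(object@aRMSE))
    cat(sprintf("  aRMSE %.3f m  aMAE %.3f m  aME %+.3f m (%g-m intervals, %d nonempty)\n",
                object@aRMSE, object@aMAE, object@aME, object@interval,
                nrow(object@intervalTable)))
})

.point <- function(pred, ref) {
  d <- pred - ref
  list(rmse = sqrt(base::mean(d^2)), mae = base::mean(abs(d)),
       me = base::mean(d))
}

#' Point accuracy metrics
#'
#' RMSE, MAE, ME (bias) and the normalized mean error
#' `NME = 100 * ME / mean(ref)` in percent.
#'
#' @param pred,ref numeric vectors of equal length >= 1 (m).
#' @return a [MetricsReport-class] with the point slots filled.
#' @export
pointMetrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (!length(pred)) stop("empty input")
  p <- .point(pred, ref)
  ybar <- base::mean(ref)
  nme <- if (abs(ybar) < 1e-12) {
    warning("mean reference height is 0; NME undefined")
    NA_real_
  } else 100 * p$me / ybar
  methods::new("MetricsReport", rmse = p$rmse, mae = p$mae, me = p$me,
               nme = nme, n = length(pred), aRMSE = NA_real_,
               aMAE = NA_real_, aME = NA_real_,
               intervalTable = data.frame(), interval = NA_real_)
}

#' Height-balanced accuracy metrics
#'
#' Computes RMSE, MAE and ME separately within each reference-height interval
#' (default 5 m, `[k*interval, (k+1)*interval)`), then averages them
#' unweighted over the nonempty intervals (aRMSE, aMAE, aME). Empty intervals
#' are skipped, not imputed.
#'
#' @param pred,ref numeric vectors (m).
#' @param interval interval width in metres.
#' @return a [MetricsReport-class] with both point and balanced slots filled.
#' @export
balancedMetrics <- function(pred, ref, interval = 5) {
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (!length(pred)) stop("empty input")
  bin <- floor(ref / interval)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(k) {
    sel <- bin == k
    p <- .point(pred[sel], ref[sel])
    data.frame(lower = k * interval, upper = (k + 1) * interval,
               n = sum(sel), rmse = p$rmse, mae = p$mae, me = p$me)
  }))
  p <- .point(pred, ref)
  ybar <- base::mean(ref)
  methods::new("MetricsReport", rmse = p$rmse, mae = p$mae, me = p$me,
               nme = if (abs(ybar) < 1e-12) NA_real_ else 100 * p$me / ybar,
               n = length(pred), aRMSE = base::mean(tab$rmse),
               aMAE = base::mean(tab$mae), aME = base::mean(tab$me),
               intervalTable = tab, interval = interval)
}

#' Uncertainty calibration: binned error vs predicted uncertainty
#'
#' Sorts samples by predicted variance `uncert` (stable: ties broken by
#' sample index) into `K` equal-count bins (remainder samples go to the last
#' bin). Per bin, the empirical error `err(B_k)` is the RMSE of the
#' predictions and the predicted uncertainty `uncert(B_k)` is the root mean
#' variance `RMV = sqrt(mean(uncert))`. The uncertainty calibration error
#' weights bins by occupancy, `UCE = sum_k (N_k / N) |err_k - RMV_k|`, and
#' its balanced version averages them, `AUCE = mean_k |err_k - RMV_k|`; with
#' exactly equal bin counts the two coincide.
#'
#' @param pred predicted heights (m).
#' @param uncert predicted variances (m^2), >= 0.
#' @param ref reference heights (m).
#' @param K number of bins (1 <= K <= n).
#' @return list with `bins` (data.frame: bin, n, err, rmv), `uce`, `auce`,
#'   `rmse`, `rmv`, `n`, `K`.
#' @export
calibrationError <- function(pred, uncert, ref, K = 10L) {
  n <- length(pred)
  if (length(uncert) != n || length(ref) != n)
    stop("pred, uncert and ref must have equal length")
  if (!n) stop("empty input")
  if (any(uncert < 0)) stop("uncert must be >= 0 (variances)")
  if (K < 1 || K > n) stop("K must be in [1, n]")
  ord <- order(uncert, seq_len(n))  # stable
  size <- n %/% K
  binof <- pmin((seq_len(n) - 1L) %/% size + 1L, K)  # remainder -> last bin
  bins <- do.call(rbind, lapply(seq_len(K), function(k) {
    sel <- ord[binof == k]
    data.frame(bin = k, n = length(sel),
               err = sqrt(base::mean((pred[sel] - ref[sel])^2)),
               rmv = sqrt(base::mean(uncert[sel])))
  }))
  dev <- abs(bins$err - bins$rmv)
  list(bins = bins, uce = sum(bins$n / n * dev), auce = base::mean(dev),
       rmse = sqrt(base::mean((pred - ref)^2)),
       rmv = sqrt(base::mean(uncert)), n = n, K = as.integer(K))
}

#' Filter predictions by predictive uncertainty
#'
#' `mode = "fixed"` drops the `fraction` most uncertain samples by predicted
#' variance. `mode = "adaptive"` drops the `fraction` samples with the
#' highest relative standard deviation `sqrt(uncert) / max(pred, eps)`, an
#' adaptive threshold that depends on the predicted canopy height and so
#' preserves the full height range in the retained set. Exactly
#' `floor(fraction * n)` samples are dropped; ties are broken by sample
#' index (stable).
#'
#' @param pred predicted heights (m).
#' @param uncert predicted variances (m^2).
#' @param fraction fraction to drop, in [0, 1].
#' @param mode `"fixed"` or `"adaptive"`.
#' @param eps floor (m) for the predicted height in the relative criterion.
#' @return logical vector: TRUE = retained.
#' @export
filterByUncertainty <- function(pred, uncert, fraction = 0.2,
                                mode = c("fixed", "adaptive"), eps = 0.1) {
  mode <- match.arg(mode)
  n <- length(pred)
  if (length(uncert) != n) stop("pred and uncert must have equal length")
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  crit <- switch(mode, fixed = uncert,
                 adaptive = sqrt(uncert) / pmax(pred, eps))
  ndrop <- floor(fraction * n)
  keep <- rep(TRUE, n)
  if (ndrop > 0)
    keep[order(-crit, seq_len(n))[seq_len(ndrop)]] <- FALSE
  keep
}
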