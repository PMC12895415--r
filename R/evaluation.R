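# Evaluation: regression metric suite, binned median errors,
# visible-range screening summary and oscillator-strength
# classification.

#' Regression metric report
#'
#' Pearson r, MAE, RMSE, median and 95th-percentile absolute error of
#' the prediction errors `pred - true`, plus the sample size. When
#' either vector has zero variance the correlation is undefined and
#' reported as `NA` with a flag.
#'
#' @param pred,true numeric vectors of equal nonzero length.
#' @return list of class `EvalReport` with fields `pearson_r`, `mae`,
#'   `rmse`, `median_abs_err`, `p95_abs_err`, `n`, `r_defined`.
#' @export
regressionMetrics <- function(pred, true) {
  if (length(pred) != length(true) || !length(pred))
    stop("regressionMetrics: equal nonzero lengths required")
  err <- pred - true
  rDefined <- stats::sd(pred) > 0 && stats::sd(true) > 0
  out <- list(
    pearson_r = if (rDefined) stats::cor(pred, true) else NA_real_,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    median_abs_err = stats::median(abs(err)),
    p95_abs_err = unname(stats::quantile(abs(err), 0.95)),
    n = length(pred),
    r_defined = rDefined)
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (n = %d): r = %s, MAE = %.4f eV, RMSE = %.4f eV\n",
              x$n, if (x$r_defined) sprintf("%.4f", x$pearson_r) else "NA",
              x$mae, x$rmse))
  cat(sprintf("  median |err| = %.4f eV, 95%% of errors below %.4f eV\n",
              x$median_abs_err, x$p95_abs_err))
  invisible(x)
}

#' Median absolute error binned by the true energy
#'
#' Assigns each point to a bin of the true value (half-open bins
#' `[e_i, e_{i+1})`, last bin closed) and reports the median absolute
#' error and count per bin. Points outside the edge range are counted in
#' an overflow bucket and reported, not dropped silently; empty bins
#' report `NA` medians, not zero.
#'
#' @param pred,true numeric vectors.
#' @param edges strictly increasing bin edges (eV).
#' @return list with `edges`, `median_abs_err`, `counts`, `overflow`.
#' @export
binnedMedianErrors <- function(pred, true, edges) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  nb <- length(edges) - 1L
  err <- abs(pred - true)
  idx <- findInterval(true, edges, rightmost.closed = TRUE)
  inRange <- idx >= 1L & idx <= nb
  med <- rep(NA_real_, nb)
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- inRange & idx == b
    counts[b] <- sum(sel)
    if (counts[b]) med[b] <- stats::median(err[sel])
  }
  list(edges = edges, median_abs_err = med, counts = counts,
       overflow = sum(!inRange))
}

#' Default bin edges spanning the observed true-energy range
#'
#' 0.5 eV bins covering the data (used by the binned-error analysis when
#' no explicit edges are given).
#'
#' @param true numeric vector of true energies.
#' @param width bin width in eV.
#' @return numeric edge vector.
#' @export
defaultEnergyBins <- function(true, width = 0.5) {
  lo <- floor(min(true) / width) * width
  hi <- ceiling(max(true) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

#' Visible-range screening summary
#'
#' For the visible window (default 1.7 to 3.3 eV, exclusive bounds):
#' (a) range recall, the fraction of truly-in-range molecules also
#' predicted in range; (b) among those, the fraction predicted within a
#' relative error tolerance (relative to the true energy); and (c) the
#' in-range prevalence. Nonpositive true energies are excluded from the
#' relative-error count and flagged.
#'
#' @param pred,true numeric vectors (eV).
#' @param lo,hi window bounds (eV).
#' @param relTol relative-error tolerance (default 0.10).
#' @return list with `range_recall`, `within_tol`, `prevalence`,
#'   `n_in_range`, `n_flagged_nonpositive`.
#' @export
visibleRangeScreen <- function(pred, true, lo = 1.7, hi = 3.3,
                               relTol = 0.10) {
  if (relTol <= 0) stop("relTol must be > 0")
  inTrue <- true > lo & true < hi
  inPred <- pred > lo & pred < hi
  nIn <- sum(inTrue)
  recall <- if (nIn) mean(inPred[inTrue]) else NA_real_
  both <- inTrue & inPred
  ok <- both & true > 0
  within <- if (sum(both)) mean(abs(pred[ok] - true[ok]) / true[ok] < relTol)
            else NA_real_
  list(range_recall = recall, within_tol = within,
       prevalence = mean(inTrue), n_in_range = nIn,
       n_flagged_nonpositive = sum(both & true <= 0))
}

#' Oscillator-strength emitter classification
#'
#' Classifies predicted and true oscillator strengths as emissive with
#' the strict threshold `f > threshold` (a value exactly at the
#' threshold is negative) and reports the confusion matrix with derived
#' rates.
#'
#' @param predF,trueF oscillator strengths (>= 0).
#' @param threshold decision threshold (default 0.4).
#' @return list of class `ConfusionCounts`: `tp`, `fp`, `fn`, `tn`,
#'   `recall`, `precision`, `specificity`, `accuracy`.
#' @export
oscillatorClassification <- function(predF, trueF, threshold = 0.4) {
  if (any(predF < 0) || any(trueF < 0))
    stop("oscillator strengths must be >= 0")
  pp <- predF > threshold
  tt <- trueF > threshold
  tp <- sum(pp & tt); fp <- sum(pp & !tt)
  fn <- sum(!pp & tt); tn <- sum(!pp & !tt)
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              recall = if (tp + fn) tp / (tp + fn) else NA_real_,
              precision = if (tp + fp) tp / (tp + fp) else NA_real_,
              specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
              accuracy = (tp + tn) / (tp + fp + fn + tn))
  class(out) <- "ConfusionCounts"
  out
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  recall %.3f  precision %.3f  specificity %.3f  accuracy %.3f\n",
              x$recall, x$precision, x$specificity, x$accuracy))
  invisible(x)
}
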