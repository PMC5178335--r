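## Pairwise cepstral-coefficient distributions per class: 2-D histograms
## with max normalized to 1, overlap isolines, and attribution of
## extreme-value regions to classes. A vocalization "hits" a region if
## ANY of its frames falls inside — a small extreme portion of a call is
## enough to place it.

poolFramesByClass <- function(featureSet, labels) {
  labels <- factor(labels)
  feats <- vocFeatures(featureSet)
  lapply(setNames(levels(labels), levels(labels)), function(cl) {
    idx <- which(labels == cl)
    if (!length(idx)) stop("empty class: ", cl)
    do.call(rbind, feats[idx])
  })
}

#' Per-class 2-D histograms of a coefficient pair
#'
#' All frames of each class are binned over a common grid (by default 50
#' bins per axis over the pooled 1st--99th percentile range) and each
#' class histogram is scaled so its maximum bin equals 1.
#'
#' @param featureSet a [FeatureSet-class].
#' @param labels class label per vocalization.
#' @param pair integer pair (i, j) of coefficient indices, i != j.
#' @param bins bins per axis.
#' @param limits optional list(x = c(lo, hi), y = c(lo, hi)); computed
#'   from pooled percentiles if NULL.
#' @return list with `histograms` (named list of bins x bins matrices,
#'   max 1), `counts` (raw counts), `xBreaks`, `yBreaks`.
#' @export
classHistogram2D <- function(featureSet, labels, pair, bins = 50L,
                             limits = NULL) {
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("pair must be two distinct coefficient indices")
  d <- featureDim(featureSet)
  if (any(pair < 1L) || any(pair > d))
    stop("coefficient indices out of range")
  byClass <- poolFramesByClass(featureSet, labels)
  pooled <- do.call(rbind, byClass)
  if (is.null(limits)) {
    qx <- stats::quantile(pooled[, pair[1L]], c(0.01, 0.99), names = FALSE)
    qy <- stats::quantile(pooled[, pair[2L]], c(0.01, 0.99), names = FALSE)
    limits <- list(x = qx, y = qy)
  }
  xb <- seq(limits$x[1L], limits$x[2L], length.out = bins + 1L)
  yb <- seq(limits$y[1L], limits$y[2L], length.out = bins + 1L)
  counts <- lapply(byClass, function(m) {
    ix <- findInterval(m[, pair[1L]], xb, rightmost.closed = TRUE)
    iy <- findInterval(m[, pair[2L]], yb, rightmost.closed = TRUE)
    ok <- ix >= 1L & ix <= bins & iy >= 1L & iy <= bins
    h <- matrix(0, bins, bins)
    if (any(ok)) {
      t2 <- table(factor(ix[ok], levels = seq_len(bins)),
                  factor(iy[ok], levels = seq_len(bins)))
      h <- matrix(as.numeric(t2), bins, bins)
    }
    h
  })
  hists <- lapply(counts, function(h) {
    mx <- max(h)
    if (mx > 0) h / mx else h
  })
  list(histograms = hists, counts = counts, xBreaks = xb, yBreaks = yb)
}

#' Isolines of a normalized 2-D histogram
#'
#' Contour lines of a max-normalized class histogram at a given level
#' (0.5 for the feature-distribution overlap figures, 0.3 for the
#' score-projection density views).
#'
#' @param histogram bins x bins matrix with max 1.
#' @param xBreaks,yBreaks bin edges from [classHistogram2D()].
#' @param level isoline level in (0, 1).
#' @return list of contour paths (x, y), as from
#'   [grDevices::contourLines()].
#' @importFrom grDevices contourLines
#' @export
histogramIsolines <- function(histogram, xBreaks, yBreaks, level = 0.5) {
  if (level <= 0 || level >= 1) stop("isoline level must be in (0, 1)")
  xc <- (xBreaks[-1L] + xBreaks[-length(xBreaks)]) / 2
  yc <- (yBreaks[-1L] + yBreaks[-length(yBreaks)]) / 2
  grDevices::contourLines(xc, yc, histogram, levels = level)
}

#' Attribute an extreme-value region to classes
#'
#' For a rectangle in a coefficient-pair plane, finds the vocalizations
#' with at least one frame inside it and returns, for each class, the
#' fraction of those hitting vocalizations that belong to the class.
#' Fractions sum to 1. Duplicating non-hitting frames of a vocalization
#' never changes the attribution.
#'
#' @param featureSet a [FeatureSet-class].
#' @param labels class label per vocalization.
#' @param pair coefficient index pair (i, j).
#' @param xlim,ylim rectangle bounds in coefficient units.
#' @return named numeric vector of per-class fractions, with attribute
#'   `nHits` (number of hitting vocalizations).
#' @export
regionAttribution <- function(featureSet, labels, pair, xlim, ylim) {
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("pair must be two distinct coefficient indices")
  if (diff(range(xlim)) <= 0 || diff(range(ylim)) <= 0)
    stop("degenerate rectangle")
  labels <- factor(labels)
  hits <- vapply(vocFeatures(featureSet), function(m) {
    any(m[, pair[1L]] >= xlim[1L] & m[, pair[1L]] <= xlim[2L] &
        m[, pair[2L]] >= ylim[1L] & m[, pair[2L]] <= ylim[2L])
  }, TRUE)
  if (!any(hits))
    stop("region hit by zero vocalizations; attribution undefined")
  frac <- table(labels[hits]) / sum(hits)
  out <- setNames(as.numeric(frac), names(frac))
  attr(out, "nHits") <- sum(hits)
  out
}
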