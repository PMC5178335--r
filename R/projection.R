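## Score-space visualization: each test vocalization is its C-dimensional
## vector of class scores; linear discriminant analysis projects those to
## two dimensions. The projection is for visualization only and plays no
## part in any accuracy computation.

#' Project score vectors to two discriminant dimensions
#'
#' Solves the generalized eigenproblem of between-class versus
#' within-class scatter (within-class scatter regularized by a small
#' trace-scaled ridge) and keeps the top two discriminant directions.
#' The result is deterministic up to sign, fixed by making the
#' largest-magnitude loading of each direction positive. Only
#' cross-validated ("loo") scores may be projected — scores produced
#' while a vocalization was in its own training set would leak.
#'
#' @param scores N x C score matrix, or a [LooResult-class].
#' @param labels class labels, one per row (taken from the LooResult if
#'   omitted).
#' @param nDims output dimensions (default 2).
#' @param ridge ridge factor relative to mean(diag(Sw)).
#' @return a [ProjectionResult-class].
#' @export
ldaProject <- function(scores, labels = NULL, nDims = 2L, ridge = 1e-6) {
  vocIds <- NULL
  if (is(scores, "LooResult")) {
    if (!identical(scores@provenance, "loo"))
      stop("refusing to project scores that are not cross-validated")
    if (is.null(labels)) labels <- trueLabels(scores)
    vocIds <- scores@vocIds
    scores <- scoreMatrix(scores)
  }
  scores <- as.matrix(scores)
  labels <- factor(labels)
  N <- nrow(scores); C <- ncol(scores)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (N <= C) stop("need more vocalizations than score dimensions")
  if (is.null(vocIds)) vocIds <- sprintf("voc_%05d", seq_len(N))

  mu <- colMeans(scores)
  Sw <- matrix(0, C, C)
  Sb <- matrix(0, C, C)
  for (cl in levels(labels)) {
    xc <- scores[labels == cl, , drop = FALSE]
    muc <- colMeans(xc)
    xcc <- sweep(xc, 2L, muc)
    Sw <- Sw + crossprod(xcc)
    Sb <- Sb + nrow(xc) * tcrossprod(muc - mu)
  }
  Sw <- Sw + ridge * mean(diag(Sw)) * diag(C)
  Ch <- tryCatch(chol(Sw), error = function(e)
    stop("within-class scatter is singular despite the ridge"))
  ## whiten: M = Ch^-T Sb Ch^-1 is symmetric; v = Ch^-1 u
  M <- backsolve(Ch, t(backsolve(Ch, Sb, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  nDims <- min(nDims, C)
  V <- backsolve(Ch, eig$vectors[, seq_len(nDims), drop = FALSE])
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(scores)
  coords <- sweep(scores, 2L, mu) %*% V
  colnames(coords) <- paste0("LD", seq_len(ncol(coords)))
  cent <- do.call(rbind, lapply(levels(labels), function(cl)
    colMeans(coords[labels == cl, , drop = FALSE])))
  rownames(cent) <- levels(labels)
  new("ProjectionResult", vocIds = as.character(vocIds), labels = labels,
      coordinates = coords, discriminantVectors = V,
      classCentroids2d = cent)
}

#' Write projection coordinates as delimited text
#'
#' @param projection a [ProjectionResult-class].
#' @param path file path.
#' @param delim field delimiter.
#' @export
writeProjection <- function(projection, path, delim = "\t") {
  df <- data.frame(voc_id = projection@vocIds,
                   label = as.character(projection@labels),
                   dim1 = projection@coordinates[, 1L],
                   dim2 = projection@coordinates[, 2L])
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a 2-D score-space projection
#'
#' @param x a [ProjectionResult-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics plot points legend
#' @export
setMethod("plot", signature("ProjectionResult", "missing"),
  function(x, y, ...) {
    cols <- seq_len(nlevels(x@labels))
    graphics::plot(x@coordinates, col = cols[as.integer(x@labels)],
                   pch = 16, cex = 0.6, xlab = "LD1", ylab = "LD2", ...)
    graphics::points(x@classCentroids2d, pch = 3, cex = 1.5, lwd = 2,
                     col = cols)
    graphics::legend("topright", legend = levels(x@labels), col = cols,
                     pch = 16, bty = "n", cex = 0.8)
    invisible(x)
  })
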