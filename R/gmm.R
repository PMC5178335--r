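## GMM-UBM classifier core.
##
## The universal background model (UBM) is a diagonal-covariance Gaussian
## mixture fitted by EM to a held-out background pool. Each class model
## is derived from the UBM by MAP adaptation of the component means (the
## canonical speaker-verification recipe; weights/variances adaptation is
## available by configuration). A vocalization's score for a class is the
## per-frame mean log-likelihood under the class model minus that under
## the UBM; the per-frame mean (rather than the sum) removes duration
## confounds between classes.

## T x K matrix of per-frame, per-component log densities (diagonal
## Gaussians), from raw parameter matrices. Shared workhorse for EM,
## posteriors and likelihoods; kept free of S4 dispatch for the
## permutation-test hot path.
componentLogDensitiesRaw <- function(means, variances, x, x2 = NULL) {
  d <- ncol(means)
  const <- -0.5 * (d * log(2 * pi) + rowSums(log(variances)))   # length K
  iv <- 1 / variances
  if (is.null(x2)) x2 <- x^2
  ## -0.5 * sum((x - mu)^2 / v) expanded into three matrix products
  q <- x2 %*% t(iv) - 2 * (x %*% t(means * iv))
  q <- sweep(q, 2L, rowSums(means^2 * iv), "+")
  sweep(-0.5 * q, 2L, const, "+")
}

componentLogDensities <- function(model, x) {
  componentLogDensitiesRaw(model@means, model@variances, x)
}

frameLogLikRaw <- function(weights, means, variances, x, x2 = NULL) {
  ld <- componentLogDensitiesRaw(means, variances, x, x2)
  logSumExpRows(sweep(ld, 2L, log(weights), "+"))
}

## per-frame log mixture density, length T
frameLogLik <- function(model, x) {
  frameLogLikRaw(model@weights, model@means, model@variances, x)
}

#' Fit a diagonal-covariance GMM by EM
#'
#' K-means-seeded expectation-maximization with a variance floor applied
#' at every M-step (default 1e-3 of the global per-dimension variance of
#' the training data). Components that collapse (soft count near 0) are
#' re-seeded from the data point with the lowest likelihood; persistent
#' failure is reported as a warning. The per-iteration training
#' log-likelihood is recorded in the returned object and is non-decreasing.
#'
#' @param x frames matrix (N x d), pooled training vectors.
#' @param K number of components (the classifier uses 16).
#' @param seed seed for the k-means initialization.
#' @param maxIter maximum EM iterations.
#' @param tol stop when the total log-likelihood gain drops below this.
#' @param varianceFloorFactor floor = factor * global per-dimension
#'   variance.
#' @return a [GmmParams-class] with `logLikTrace` filled in.
#' @examples
#' x <- matrix(rnorm(600), 300, 2)
#' m <- fitGmmEM(x, K = 2, seed = 1)
#' nComponents(m)
#' @export
fitGmmEM <- function(x, K, seed = 1L, maxIter = 100L, tol = 1e-6,
                     varianceFloorFactor = 1e-3) {
  x <- as.matrix(x)
  N <- nrow(x); d <- ncol(x)
  if (N < K) stop("need at least K frames to fit K components")
  gv <- apply(x, 2L, stats::var)
  if (any(gv == 0)) gv[gv == 0] <- 1e-12
  floorV <- varianceFloorFactor * gv

  init <- withSeed(seed, {
    if (K == 1L) {
      list(centers = matrix(colMeans(x), 1L), cluster = rep(1L, N))
    } else {
      km <- tryCatch(
        stats::kmeans(x, centers = K, nstart = 3L, iter.max = 25L),
        error = function(e) NULL)
      if (is.null(km)) {
        ctr <- x[sample.int(N, K), , drop = FALSE]
        list(centers = ctr,
             cluster = max.col(-as.matrix(stats::dist(rbind(ctr, x)))[
               -(seq_len(K)), seq_len(K), drop = FALSE]))
      } else list(centers = km$centers, cluster = km$cluster)
    }
  })
  w <- tabulate(init$cluster, K) / N
  w[w == 0] <- 1 / N
  w <- w / sum(w)
  mu <- init$centers
  v <- matrix(0, K, d)
  for (k in seq_len(K)) {
    xk <- x[init$cluster == k, , drop = FALSE]
    v[k, ] <- if (nrow(xk) > 1L) apply(xk, 2L, stats::var) else gv
  }
  v <- pmax(v, rep(floorV, each = K))

  model <- new("GmmParams", weights = w, means = mu, variances = v,
               varianceFloor = floorV, logLikTrace = numeric(0))
  trace <- numeric(0)
  reseeds <- 0L
  for (it in seq_len(maxIter)) {
    ld <- sweep(componentLogDensities(model, x), 2L, log(model@weights), "+")
    fll <- logSumExpRows(ld)
    ll <- sum(fll)
    trace <- c(trace, ll)
    resp <- exp(ld - fll)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {
      ## re-seed collapsed components from the worst-explained frame
      for (k in which(nk < 1e-8)) {
        worst <- which.min(fll)
        model@means[k, ] <- x[worst, ]
        model@variances[k, ] <- pmax(gv, floorV)
        model@weights[k] <- 1 / N
        reseeds <- reseeds + 1L
      }
      model@weights <- model@weights / sum(model@weights)
      if (reseeds > 2L * K) {
        warning("persistent degenerate components during EM")
        break
      }
      next
    }
    wNew <- nk / N
    muNew <- (t(resp) %*% x) / nk
    vNew <- (t(resp) %*% x^2) / nk - muNew^2
    vNew <- pmax(vNew, rep(floorV, each = K))
    model <- new("GmmParams", weights = wNew / sum(wNew), means = muNew,
                 variances = vNew, varianceFloor = floorV,
                 logLikTrace = numeric(0))
    if (it > 1L && trace[it] - trace[it - 1L] < tol) break
  }
  initialize(model, logLikTrace = trace)
}

#' Accumulate UBM sufficient statistics for a vocalization
#'
#' Component posteriors are computed against the fixed UBM only, which
#' makes the statistics additive across vocalizations: stats of a pooled
#' set equal the elementwise sum of the stats of its members. The soft
#' counts always sum to the frame count.
#'
#' @param ubm the [GmmParams-class] background model.
#' @param x frames matrix (T x d) of one vocalization.
#' @return a [SufficientStats-class].
#' @export
accumulateStats <- function(ubm, x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty feature matrix")
  if (ncol(x) != featureDim(ubm)) stop("dimension mismatch")
  ld <- sweep(componentLogDensities(ubm, x), 2L, log(ubm@weights), "+")
  resp <- exp(ld - logSumExpRows(ld))
  new("SufficientStats", n = colSums(resp), first = t(resp) %*% x,
      second = t(resp) %*% x^2, nFrames = nrow(x))
}

## zero statistics matching a UBM's shape
emptyStats <- function(ubm) {
  K <- nComponents(ubm); d <- featureDim(ubm)
  new("SufficientStats", n = numeric(K), first = matrix(0, K, d),
      second = matrix(0, K, d), nFrames = 0)
}

#' MAP-adapt a class model from the UBM
#'
#' Data-balanced per-component interpolation with relevance factor r:
#' adapted mean_k = (n_k x̄_k + r mu_k) / (n_k + r). Components with no
#' data (n_k = 0) keep the UBM parameters; r = Inf returns the UBM
#' exactly; r = 0 gives the per-component ML mean wherever n_k > 0.
#' Weights and variances are adapted only if requested in the
#' [MapConfig-class], otherwise copied from the UBM.
#'
#' @param ubm the [GmmParams-class] background model.
#' @param stats [SufficientStats-class] computed against this UBM.
#' @param config a [MapConfig-class].
#' @return the adapted [GmmParams-class].
#' @export
mapAdapt <- function(ubm, stats, config = mapConfig()) {
  r <- config@relevanceFactor
  if (is.infinite(r)) return(ubm)
  nk <- stats@n
  alpha <- ifelse(nk + r > 0, nk / (nk + r), 0)
  xbar <- ubm@means
  pos <- nk > 0
  xbar[pos, ] <- stats@first[pos, , drop = FALSE] / nk[pos]

  means <- ubm@means
  if ("means" %in% config@adapt)
    means <- alpha * xbar + (1 - alpha) * ubm@means
  weights <- ubm@weights
  if ("weights" %in% config@adapt && stats@nFrames > 0) {
    weights <- alpha * nk / stats@nFrames + (1 - alpha) * ubm@weights
    weights <- weights / sum(weights)
  }
  variances <- ubm@variances
  if ("variances" %in% config@adapt) {
    e2 <- ubm@variances + ubm@means^2
    e2[pos, ] <- stats@second[pos, , drop = FALSE] / nk[pos]
    variances <- alpha * e2 + (1 - alpha) * (ubm@variances + ubm@means^2) -
      means^2
    fl <- if (length(ubm@varianceFloor)) ubm@varianceFloor else 1e-12
    variances <- pmax(variances, rep(fl, each = nrow(variances)))
  }
  new("GmmParams", weights = weights, means = means, variances = variances,
      varianceFloor = ubm@varianceFloor, logLikTrace = numeric(0))
}

#' Average log-likelihood of a frame set under a mixture
#'
#' Mean over frames of log sum_k w_k N(x | mu_k, Sigma_k), computed in the
#' log domain. Using the per-frame mean makes the value invariant to
#' frame duplication and removes duration differences between classes.
#'
#' @param model a [GmmParams-class].
#' @param x frames matrix (T x d).
#' @return nats per frame.
#' @export
avgLogLik <- function(model, x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty feature matrix")
  if (ncol(x) != featureDim(model)) stop("dimension mismatch")
  mean(frameLogLik(model, x))
}

#' Score a vocalization against class models and the UBM
#'
#' score_c = avgLogLik(class model c) - avgLogLik(UBM): the per-frame
#' log-likelihood ratio between the class and the background model.
#'
#' @param classModels named list of [GmmParams-class].
#' @param ubm the [GmmParams-class] background model.
#' @param x frames matrix of one vocalization.
#' @return named numeric vector of scores, one per class.
#' @export
scoreVocalization <- function(classModels, ubm, x) {
  if (!length(classModels)) stop("need at least one class model")
  ubmLL <- avgLogLik(ubm, x)
  vapply(classModels, function(m) avgLogLik(m, x) - ubmLL, 0)
}

#' Predict the class from a score vector
#'
#' Argmax over classes; exact ties are broken by lexicographic class
#' label, so the prediction is deterministic.
#'
#' @param scores named numeric score vector.
#' @return the winning class label (character).
#' @examples
#' classifyScores(c(B = 0, A = 0))   # tie -> "A"
#' @export
classifyScores <- function(scores) {
  if (!length(scores)) stop("empty score vector")
  ord <- order(names(scores))
  s <- scores[ord]
  names(s)[which.max(s)]
}

## ---------------------------------------------------------------------------
## Model serialization
## ---------------------------------------------------------------------------

## short deterministic content hash (FNV-1a over the formatted parameters)
paramHash <- function(model) {
  txt <- paste(format(c(model@weights, model@means, model@variances),
                      digits = 15), collapse = ",")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- mulmod32(xor32(h, b), 16777619)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write / read mixture parameters as JSON
#'
#' Plain-text parameter files (K, dim, weights, means, variances and a
#' provenance block) that round-trip bit-exactly at full double
#' precision.
#'
#' @param model a [GmmParams-class].
#' @param path file path.
#' @param provenance optional named list stored verbatim (e.g. UBM hash,
#'   adaptation settings).
#' @export
writeGmm <- function(model, path, provenance = list()) {
  x <- list(K = nComponents(model), dim = featureDim(model),
            weights = model@weights, means = model@means,
            variances = model@variances,
            varianceFloor = model@varianceFloor,
            hash = paramHash(model), provenance = provenance)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeGmm
#' @export
readGmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GmmParams", weights = as.numeric(x$weights),
      means = matrix(as.numeric(x$means), x$K, x$dim),
      variances = matrix(as.numeric(x$variances), x$K, x$dim),
      varianceFloor = as.numeric(x$varianceFloor %||% numeric(0)),
      logLikTrace = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
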