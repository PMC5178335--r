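## Task orchestration: class-size filtering, leave-one-out cross-validation
## by sufficient-statistic downdating, balanced accuracy and permutation
## significance.
##
## Leave-one-out is exact under a fixed UBM: a vocalization's statistics
## are subtracted from its own class accumulator and only that class model
## is re-adapted before the vocalization is scored. Equality with a naive
## per-fold re-accumulation is part of the test suite.

taskAbort <- function(message, report) {
  stop(structure(class = c("batvoc_task_abort", "error", "condition"),
                 list(message = message, call = sys.call(-1L),
                      report = report)))
}

axisLabels <- function(meta, labelAxis) {
  if (labelAxis == "context_x_emitter") {
    if (!all(c("context", "emitter") %in% names(meta)))
      taskAbort("annotations lack context/emitter columns", list())
    paste(meta$context, meta$emitter, sep = "|")
  } else {
    if (!labelAxis %in% names(meta))
      taskAbort(paste0("annotations lack column '", labelAxis, "'"), list())
    as.character(meta[[labelAxis]])
  }
}

#' Assemble a labeled vocalization set for one classification task
#'
#' Applies the population filter, drops excluded labels, then drops
#' classes below the minimum class size. Fewer than two surviving classes
#' aborts the task with a structured condition of class
#' `batvoc_task_abort` carrying a report of the surviving class sizes.
#'
#' @param featureSet a [FeatureSet-class] whose meta carries the
#'   annotation label columns.
#' @param spec a [TaskSpec-class].
#' @return list with `features` (filtered [FeatureSet-class]), `labels`
#'   (factor) and `report` (class sizes before/after filtering).
#' @export
buildTask <- function(featureSet, spec) {
  validObject(spec)
  meta <- vocMeta(featureSet)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(spec@populationFilter)) {
    keep <- keep & spec@populationFilter(meta)
    if (anyNA(keep)) keep[is.na(keep)] <- FALSE
  }
  labels <- axisLabels(meta, spec@labelAxis)
  keep <- keep & !(labels %in% spec@excludedLabels)
  before <- table(labels[keep])
  sizes <- table(labels[keep])
  small <- names(sizes)[sizes < spec@minClassSize]
  keep <- keep & !(labels %in% small)
  after <- table(labels[keep])
  report <- list(task = spec@name, axis = spec@labelAxis,
                 sizesBeforeMinFilter = as.list(before),
                 sizes = as.list(after), dropped = small)
  if (length(after) < 2L)
    taskAbort(sprintf("task '%s': fewer than 2 classes survive filtering",
                      spec@name), report)
  idx <- which(keep)
  fs <- new("FeatureSet", features = vocFeatures(featureSet)[idx],
            meta = meta[idx, , drop = FALSE])
  list(features = fs, labels = factor(labels[idx]), report = report)
}

## ---------------------------------------------------------------------------
## LOO engine: everything that does not depend on the labels is computed
## once so permutation tests only pay for accumulation + adaptation +
## scoring.
## ---------------------------------------------------------------------------

looEngine <- function(features, ubm, config = mapConfig()) {
  if (is(features, "FeatureSet")) features <- vocFeatures(features)
  N <- length(features)
  if (!N) stop("no vocalizations")
  stats <- lapply(features, function(x) accumulateStats(ubm, x))
  nFrames <- vapply(features, nrow, 0L)
  X <- do.call(rbind, features)
  vocIndex <- rep.int(seq_len(N), nFrames)
  ubmAvg <- as.numeric(rowsum(frameLogLik(ubm, X), vocIndex)) / nFrames
  ## per-vocalization moments flattened to matrices so that per-class
  ## accumulation and leave-one-out downdating are plain column sums
  K <- nComponents(ubm)
  nMat <- do.call(rbind, lapply(stats, function(s) s@n))
  firstMat <- do.call(rbind, lapply(stats, function(s) as.numeric(s@first)))
  list(features = features, stats = stats, X = X, X2 = X^2,
       vocIndex = vocIndex, nFrames = nFrames, ubm = ubm, config = config,
       N = N, ubmAvg = ubmAvg, K = K, d = featureDim(ubm),
       nMat = nMat, firstMat = firstMat,
       meansOnly = identical(config@adapt, "means"))
}

## batch per-vocalization average log-likelihood under raw parameters
batchAvgLogLikRaw <- function(engine, weights, means, variances) {
  fll <- frameLogLikRaw(weights, means, variances, engine$X, engine$X2)
  as.numeric(rowsum(fll, engine$vocIndex)) / engine$nFrames
}

sumStats <- function(statsList, ubm) {
  if (!length(statsList)) return(emptyStats(ubm))
  Reduce(`+`, statsList)
}

## MAP mean adaptation from flattened moments:
## (n_k x̄_k + r mu_k) / (n_k + r) with first = n x̄
adaptedMeans <- function(engine, n, firstFlat) {
  ubm <- engine$ubm
  r <- engine$config@relevanceFactor
  if (is.infinite(r)) return(ubm@means)
  n <- pmax(n, 0)
  first <- matrix(firstFlat, engine$K, engine$d)
  denom <- n + r
  zero <- denom <= 0 | n <= 0
  m <- (first + r * ubm@means) / denom
  if (any(zero)) m[zero, ] <- ubm@means[zero, , drop = FALSE]
  if (r == 0) {
    pos <- n > 0
    m[pos, ] <- first[pos, , drop = FALSE] / n[pos]
  }
  m
}

## the core LOO pass; labels may be any factor over the engine's items
looRun <- function(engine, labels) {
  labels <- factor(labels)
  classes <- sort(levels(labels))
  C <- length(classes)
  scores <- matrix(0, engine$N, C, dimnames = list(NULL, classes))
  ubm <- engine$ubm

  if (engine$meansOnly) {
    idxByClass <- split(seq_len(engine$N), factor(labels, levels = classes))
    for (j in seq_len(C)) {
      idx <- idxByClass[[j]]
      nC <- colSums(engine$nMat[idx, , drop = FALSE])
      fC <- colSums(engine$firstMat[idx, , drop = FALSE])
      mFull <- adaptedMeans(engine, nC, fC)
      scores[, j] <- batchAvgLogLikRaw(engine, ubm@weights, mFull,
                                       ubm@variances) - engine$ubmAvg
      for (v in idx) {
        mDown <- adaptedMeans(engine, nC - engine$nMat[v, ],
                              fC - engine$firstMat[v, ])
        x <- engine$features[[v]]
        scores[v, j] <- mean(frameLogLikRaw(ubm@weights, mDown,
                                            ubm@variances, x)) -
          engine$ubmAvg[v]
      }
    }
  } else {
    classStats <- lapply(classes, function(cl)
      sumStats(engine$stats[labels == cl], ubm))
    names(classStats) <- classes
    for (j in seq_len(C)) {
      m <- mapAdapt(ubm, classStats[[j]], engine$config)
      scores[, j] <- batchAvgLogLikRaw(engine, m@weights, m@means,
                                       m@variances) - engine$ubmAvg
    }
    for (v in seq_len(engine$N)) {
      cl <- as.character(labels[v])
      model <- mapAdapt(ubm, classStats[[cl]] - engine$stats[[v]],
                        engine$config)
      scores[v, cl] <- avgLogLik(model, engine$features[[v]]) -
        engine$ubmAvg[v]
    }
  }
  predicted <- classes[max.col(scores, ties.method = "first")]
  list(scores = scores, predicted = factor(predicted, levels = levels(labels)))
}

## naive oracle: per fold, re-accumulate the held-out class from pooled
## frames instead of subtracting statistics
looRunRefit <- function(engine, labels) {
  labels <- factor(labels)
  classes <- sort(levels(labels))
  C <- length(classes)
  scores <- matrix(0, engine$N, C, dimnames = list(NULL, classes))
  for (v in seq_len(engine$N)) {
    models <- lapply(classes, function(cl) {
      members <- setdiff(which(labels == cl), v)
      st <- if (length(members)) {
        accumulateStats(engine$ubm,
                        do.call(rbind, engine$features[members]))
      } else emptyStats(engine$ubm)
      mapAdapt(engine$ubm, st, engine$config)
    })
    names(models) <- classes
    scores[v, ] <- scoreVocalization(models, engine$ubm,
                                     engine$features[[v]])
  }
  predicted <- classes[max.col(scores, ties.method = "first")]
  list(scores = scores, predicted = factor(predicted, levels = levels(labels)))
}

#' Leave-one-out cross-validated classification
#'
#' Each vocalization in turn is removed from its class accumulator, all
#' class models are MAP-adapted, and the vocalization is scored against
#' every class and the UBM; every prediction is therefore made on data
#' unseen by its class model. A class reduced to zero vocalizations after
#' removal falls back to the UBM (the adaptation of empty statistics).
#'
#' @param features a [FeatureSet-class] or list of frame matrices.
#' @param labels factor/character of true labels, one per vocalization.
#' @param ubm the [GmmParams-class] background model, trained on a pool
#'   disjoint from these vocalizations.
#' @param config a [MapConfig-class].
#' @param method "downdate" (sufficient-statistic subtraction, exact and
#'   fast) or "refit" (naive per-fold re-accumulation; the verification
#'   oracle).
#' @return a [LooResult-class].
#' @export
leaveOneOutCV <- function(features, labels, ubm, config = mapConfig(),
                          method = c("downdate", "refit")) {
  method <- match.arg(method)
  vocIds <- if (is(features, "FeatureSet")) vocMeta(features)$voc_id
            else sprintf("voc_%05d", seq_along(features))
  engine <- looEngine(features, ubm, config)
  if (length(labels) != engine$N)
    stop("labels length must match the number of vocalizations")
  run <- if (method == "downdate") looRun(engine, labels)
         else looRunRefit(engine, labels)
  new("LooResult", vocIds = as.character(vocIds),
      truth = factor(labels, levels = levels(run$predicted)),
      predicted = run$predicted, scores = run$scores, provenance = "loo")
}

#' Build a confusion matrix from true and predicted labels
#'
#' @param truth,predicted factors over the same classes.
#' @return a [ConfusionMatrix-class] (rows = truth).
#' @export
confusionMatrix <- function(truth, predicted) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  counts <- unclass(table(truth, predicted))
  dimnames(counts) <- list(levels(truth), levels(truth))
  new("ConfusionMatrix", labels = levels(truth),
      counts = matrix(as.numeric(counts), nrow(counts),
                      dimnames = dimnames(counts)))
}

## fast balanced accuracy straight from label vectors
baFromLabels <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) {
    i <- truth == cl
    sum(predicted[i] == cl) / sum(i)
  }, 0))
}

#' Chance level of balanced accuracy
#'
#' The expected per-class recall of a uniform random guesser is 1/C for
#' every class whatever the class sizes, so the expected balanced
#' accuracy is 1/C (e.g. one out of seven, 14\%, for 7 emitters).
#'
#' @param nClasses number of classes C.
#' @return 1/C.
#' @export
chanceLevel <- function(nClasses) {
  if (nClasses < 1L) stop("need at least one class")
  1 / nClasses
}

#' Permutation test of classification performance
#'
#' Labels are permuted uniformly at random (seeded) and the full pipeline
#' (class accumulation, MAP adaptation, leave-one-out scoring, balanced
#' accuracy) is re-run for each permutation. The p-value uses the add-one
#' estimator p = (1 + #\{null BA >= observed BA\}) / (1 + nPerm), which is
#' never zero; with the 100 permutations used throughout, the smallest
#' attainable p is 1/101.
#'
#' @param features a [FeatureSet-class] or list of frame matrices.
#' @param labels true labels.
#' @param ubm the [GmmParams-class] background model.
#' @param config a [MapConfig-class].
#' @param nPerm number of permutations (default 100).
#' @param seed permutation seed.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(features, labels, ubm, config = mapConfig(),
                            nPerm = 100L, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  engine <- looEngine(features, ubm, config)
  labels <- factor(labels)
  obs <- looRun(engine, labels)
  observedBA <- baFromLabels(labels, obs$predicted)
  nullBAs <- vapply(seq_len(nPerm), function(p) {
    perm <- withSeed(deriveSeed(seed, "perm", p), sample(labels))
    run <- looRun(engine, perm)
    baFromLabels(perm, run$predicted)
  }, 0)
  pValue <- (1 + sum(nullBAs >= observedBA)) / (1 + nPerm)
  new("PermutationResult", observedBA = observedBA, nullBAs = nullBAs,
      pValue = pValue, nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Train a universal background model
#'
#' Pools all frames of a background feature set (a sample of syllables
#' disjoint from every train/test vocalization) and fits a K-component
#' diagonal-covariance GMM by EM.
#'
#' @param features a [FeatureSet-class], or a frames matrix.
#' @param K components (default 16).
#' @param seed EM initialization seed.
#' @param ... passed to [fitGmmEM()].
#' @return a [GmmParams-class].
#' @export
trainUbm <- function(features, K = 16L, seed = 1L, ...) {
  x <- if (is(features, "FeatureSet")) do.call(rbind, vocFeatures(features))
       else as.matrix(features)
  fitGmmEM(x, K = K, seed = seed, ...)
}

#' Run one classification task end to end
#'
#' [buildTask()] then [leaveOneOutCV()], confusion matrix, balanced
#' accuracy and [permutationTest()].
#'
#' @param featureSet a [FeatureSet-class] with annotation labels in meta.
#' @param spec a [TaskSpec-class].
#' @param ubm the [GmmParams-class] background model.
#' @param config a [MapConfig-class].
#' @param nPerm permutations for the significance test.
#' @param seed permutation seed.
#' @return list: task name, classes, class sizes, `loo` ([LooResult-class]),
#'   `confusion` ([ConfusionMatrix-class]), `ba`, `chance`,
#'   `permutation` ([PermutationResult-class]).
#' @export
runTask <- function(featureSet, spec, ubm, config = mapConfig(),
                    nPerm = 100L, seed = 1L) {
  task <- buildTask(featureSet, spec)
  loo <- leaveOneOutCV(task$features, task$labels, ubm, config)
  cm <- confusionMatrix(trueLabels(loo), predictedLabels(loo))
  perm <- permutationTest(task$features, task$labels, ubm, config,
                          nPerm = nPerm, seed = seed)
  list(task = spec@name, classes = levels(task$labels),
       classSizes = as.list(table(task$labels)), loo = loo,
       confusion = cm, ba = balancedAccuracy(cm),
       chance = chanceLevel(nlevels(task$labels)), permutation = perm,
       report = task$report)
}

#' Non-voiced control analysis
#'
#' Re-runs the identical classification pipeline on features extracted
#' from the unvoiced spans between syllables (never reusing voiced
#' samples). On data whose background noise carries no class information
#' the control balanced accuracy is statistically indistinguishable from
#' chance; a significant control would indicate that classification was
#' driven by context-dependent background noise rather than the calls.
#'
#' @param dataset a [SynthDataset-class] or annotation data.frame.
#' @param segments voiced-segment table from [segmentDataset()].
#' @param spec a [TaskSpec-class].
#' @param ubm the [GmmParams-class] background model.
#' @param config a [MapConfig-class].
#' @param nPerm,seed permutation settings.
#' @param segConfig,fparams,cconfig feature-extraction settings (must
#'   match the main analysis).
#' @return as [runTask()], or NULL (with a message) when too little
#'   unvoiced material survives.
#' @export
nonvoicedControl <- function(dataset, segments, spec, ubm,
                             config = mapConfig(), nPerm = 100L, seed = 1L,
                             segConfig = segmenterConfig(),
                             fparams = frameParams(),
                             cconfig = cepstralConfig()) {
  fs <- featurizeDataset(dataset, segments = segments, segConfig = segConfig,
                         fparams = fparams, cconfig = cconfig,
                         cms = TRUE, spans = "unvoiced")
  if (!length(vocFeatures(fs))) {
    message("non-voiced control skipped: no unvoiced material")
    return(NULL)
  }
  tryCatch(runTask(fs, spec, ubm, config, nPerm = nPerm, seed = seed),
           batvoc_task_abort = function(e) {
             message("non-voiced control skipped: ", conditionMessage(e))
             NULL
           })
}
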