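#' @importFrom S4Vectors DataFrame
#' @import IRanges
NULL

## ---------------------------------------------------------------------------
## Synthetic-corpus specification
## ---------------------------------------------------------------------------

#' SynthSpec: generative parameters for a synthetic vocalization corpus
#'
#' Describes a corpus of multisyllabic harmonic calls with planted,
#' individually tunable class structure along four orthogonal axes:
#' emitter (fundamental frequency and envelope base), context (formant-like
#' envelope centre shift), addressee (spectral tilt) and interaction outcome
#' (amplitude/bandwidth). Setting an axis' effect size to 0 removes all
#' class signal along that axis, which is how null datasets are produced.
#'
#' @slot seed integer; master seed, all randomness derives from it.
#' @slot sampleRate sampling rate in Hz.
#' @slot nEmitters number of emitter identities.
#' @slot contexts character vector of context labels.
#' @slot addressees character vector of addressee identities.
#' @slot addresseeSex named character ("F"/"M"), one entry per addressee;
#'   a deterministic attribute of the addressee identity.
#' @slot outcomes character vector of interaction outcomes.
#' @slot callsPerCell vocalizations per (emitter, context) cell.
#' @slot syllableCountRange integer pair within \[1, 20\].
#' @slot syllableDurationRange seconds, min/max per syllable.
#' @slot gapDurationRange seconds, min/max inter-syllable silence.
#' @slot f0Base fundamental frequency in Hz, one entry per emitter.
#' @slot formantShiftPerContext Hz; per-context envelope-centre step
#'   (0 = no context signal).
#' @slot addresseeTilt dB/kHz; per-addressee spectral-tilt step.
#' @slot outcomeGain dB; per-outcome amplitude/bandwidth step.
#' @slot noiseSnr signal-to-noise ratio of additive white noise, dB.
#' @slot nChannels number of recording channels calls are assigned to.
#' @slot channelColoration dB/kHz fixed spectral slope per channel.
#' @export
setClass("SynthSpec",
  representation(
    seed = "integer",
    sampleRate = "numeric",
    nEmitters = "integer",
    contexts = "character",
    addressees = "character",
    addresseeSex = "character",
    outcomes = "character",
    callsPerCell = "integer",
    syllableCountRange = "integer",
    syllableDurationRange = "numeric",
    gapDurationRange = "numeric",
    f0Base = "numeric",
    formantShiftPerContext = "numeric",
    addresseeTilt = "numeric",
    outcomeGain = "numeric",
    noiseSnr = "numeric",
    nChannels = "integer",
    channelColoration = "numeric"))

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (length(object@seed) != 1L) msg <- c(msg, "seed must be a single integer")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (object@nEmitters < 1L) msg <- c(msg, "need at least one emitter")
  if (length(object@contexts) < 1L) msg <- c(msg, "contexts must be non-empty")
  if (length(object@addressees) < 1L) msg <- c(msg, "addressees must be non-empty")
  if (length(object@outcomes) < 1L) msg <- c(msg, "outcomes must be non-empty")
  if (anyDuplicated(object@contexts)) msg <- c(msg, "duplicate context labels")
  if (object@callsPerCell < 1L) msg <- c(msg, "callsPerCell must be >= 1")
  r <- object@syllableCountRange
  if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L || r[2L] > 20L)
    msg <- c(msg, "syllableCountRange must be an ordered pair within [1, 20]")
  if (any(object@syllableDurationRange <= 0))
    msg <- c(msg, "syllable durations must be > 0")
  if (length(object@f0Base) != object@nEmitters)
    msg <- c(msg, "f0Base needs one entry per emitter")
  if (!setequal(names(object@addresseeSex), object@addressees))
    msg <- c(msg, "addresseeSex must be named by addressee")
  if (!all(object@addresseeSex %in% c("F", "M")))
    msg <- c(msg, "addresseeSex entries must be 'F' or 'M'")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (length(object@channelColoration) != object@nChannels)
    msg <- c(msg, "channelColoration needs one entry per channel")
  if (length(msg)) msg else TRUE
})

#' SynthDataset: a generated corpus plus its ground truth
#'
#' @slot audioDir directory holding the WAV recordings.
#' @slot annotations data.frame, one row per vocalization, columns
#'   voc_id, wav_path, channel, t_start_s, t_end_s, emitter, addressee,
#'   addressee_sex, context, outcome, detailed_outcome.
#' @slot truth the [SynthSpec-class] used to generate the corpus.
#' @slot syllables ground-truth planted syllable positions (voc_id,
#'   syll_idx, start_sample, end_sample; 1-based inclusive), used as the
#'   oracle for segmentation tests.
#' @export
setClass("SynthDataset",
  representation(audioDir = "character", annotations = "data.frame",
                 truth = "SynthSpec", syllables = "data.frame"))

setValidity("SynthDataset", function(object) {
  ann <- object@annotations
  need <- c("voc_id", "wav_path", "channel", "t_start_s", "t_end_s",
            "emitter", "addressee", "addressee_sex", "context", "outcome")
  if (!all(need %in% names(ann)))
    return(paste("annotations missing columns:",
                 paste(setdiff(need, names(ann)), collapse = ", ")))
  if (anyDuplicated(ann$voc_id)) return("duplicate voc_id")
  sp <- object@truth
  if (!all(ann$context %in% sp@contexts)) return("unknown context label")
  if (!all(ann$addressee %in% sp@addressees)) return("unknown addressee label")
  if (!all(ann$outcome %in% sp@outcomes)) return("unknown outcome label")
  TRUE
})

## ---------------------------------------------------------------------------
## Feature extraction configuration
## ---------------------------------------------------------------------------

#' FrameParams: short-time analysis framing
#'
#' Defaults follow the analysis design: a 20 ms sliding window advancing by
#' 1 ms (19 ms overlap between consecutive windows).
#'
#' @slot windowLength window length in seconds (default 0.020).
#' @slot hop hop between frame starts in seconds (default 0.001).
#' @slot windowFunction taper name; only "hann" is implemented.
#' @export
setClass("FrameParams",
  representation(windowLength = "numeric", hop = "numeric",
                 windowFunction = "character"))

setValidity("FrameParams", function(object) {
  if (object@hop <= 0) return("hop must be > 0")
  if (object@hop > object@windowLength) return("hop must be <= windowLength")
  if (!object@windowFunction %in% c("hann", "rectangular"))
    return("windowFunction must be 'hann' or 'rectangular'")
  TRUE
})

#' CepstralConfig: MFCC computation parameters
#'
#' @slot nCoefficients cepstral coefficients kept per frame (default 64).
#' @slot nMelFilters triangular mel filters (default 128).
#' @slot fMin,fMax filterbank frequency range in Hz.
#' @slot logFloor floor applied to mel energies before the log.
#' @slot includeC0 keep the 0th (energy) coefficient.
#' @slot preEmphasis first-order pre-emphasis coefficient, 0 disables.
#' @slot nFft FFT size; 0 means the next power of two >= window length.
#' @export
setClass("CepstralConfig",
  representation(nCoefficients = "integer", nMelFilters = "integer",
                 fMin = "numeric", fMax = "numeric", logFloor = "numeric",
                 includeC0 = "logical", preEmphasis = "numeric",
                 nFft = "integer"))

setValidity("CepstralConfig", function(object) {
  if (object@nMelFilters < object@nCoefficients)
    return("need nMelFilters >= nCoefficients")
  if (object@fMin < 0 || object@fMin >= object@fMax)
    return("need 0 <= fMin < fMax")
  if (object@logFloor <= 0) return("logFloor must be > 0")
  TRUE
})

#' SegmenterConfig: voiced-segment detector parameters
#'
#' The detector thresholds short-time RMS energy, bridges sub-`mergeGap`
#' silences and drops runs shorter than `minSegment`.
#'
#' @slot energyWindow RMS window, seconds.
#' @slot energyHop RMS hop, seconds; must not exceed energyWindow.
#' @slot thresholdMode "relative" (dB above the noise floor, robust to
#'   amplitude scaling) or "absolute" (dBFS).
#' @slot thresholdValue threshold in dB, interpreted per thresholdMode.
#' @slot minSegment minimum voiced-run duration kept, seconds.
#' @slot mergeGap gaps shorter than this are bridged, seconds.
#' @export
setClass("SegmenterConfig",
  representation(energyWindow = "numeric", energyHop = "numeric",
                 thresholdMode = "character", thresholdValue = "numeric",
                 minSegment = "numeric", mergeGap = "numeric"))

setValidity("SegmenterConfig", function(object) {
  if (object@minSegment <= 0) return("minSegment must be > 0")
  if (object@energyHop <= 0 || object@energyWindow < object@energyHop)
    return("need energyWindow >= energyHop > 0")
  if (!object@thresholdMode %in% c("relative", "absolute"))
    return("thresholdMode must be 'relative' or 'absolute'")
  TRUE
})

## ---------------------------------------------------------------------------
## Feature container
## ---------------------------------------------------------------------------

#' FeatureSet: per-vocalization cepstral feature matrices
#'
#' One numeric matrix (frames x coefficients) per vocalization, aligned
#' with a metadata table carrying the annotation labels.
#'
#' @slot features list of numeric matrices, one per vocalization; all
#'   share the same number of columns.
#' @slot meta data.frame with one row per vocalization (voc_id, channel,
#'   label columns, nFrames).
#' @export
setClass("FeatureSet",
  representation(features = "list", meta = "data.frame"))

setValidity("FeatureSet", function(object) {
  if (length(object@features) != nrow(object@meta))
    return("features and meta length mismatch")
  if (length(object@features)) {
    d <- vapply(object@features, ncol, 0L)
    if (length(unique(d)) > 1L) return("inconsistent feature dimension")
    if (!all(vapply(object@features, function(m) all(is.finite(m)), TRUE)))
      return("non-finite feature values")
  }
  if (!all(c("voc_id", "channel") %in% names(object@meta)))
    return("meta must contain voc_id and channel")
  TRUE
})

## ---------------------------------------------------------------------------
## Mixture model classes
## ---------------------------------------------------------------------------

#' GmmParams: a diagonal-covariance Gaussian mixture
#'
#' @slot weights mixture weights on the simplex.
#' @slot means K x d component means.
#' @slot variances K x d strictly positive diagonal variances.
#' @slot varianceFloor per-dimension floor applied during fitting.
#' @slot logLikTrace per-iteration training log-likelihood (empty unless
#'   the object came out of [fitGmmEM()]).
#' @export
setClass("GmmParams",
  representation(weights = "numeric", means = "matrix",
                 variances = "matrix", varianceFloor = "numeric",
                 logLikTrace = "numeric"))

setValidity("GmmParams", function(object) {
  K <- length(object@weights)
  if (nrow(object@means) != K || nrow(object@variances) != K)
    return("means/variances rows must match number of weights")
  if (!identical(dim(object@means), dim(object@variances)))
    return("means and variances dimensions differ")
  if (abs(sum(object@weights) - 1) > 1e-12)
    return("weights must sum to 1 within 1e-12")
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (any(object@variances <= 0)) return("variances must be > 0")
  if (length(object@varianceFloor) &&
      length(object@varianceFloor) != ncol(object@means))
    return("varianceFloor must have one entry per dimension")
  TRUE
})

#' MapConfig: MAP adaptation settings
#'
#' The canonical speaker-verification recipe: each class model is the UBM
#' with its component statistics pulled toward the class data, weighted by
#' the relevance factor (a pseudo-count). By default only the means are
#' adapted.
#'
#' @slot relevanceFactor pseudo-count r >= 0; Inf returns the UBM unchanged.
#' @slot adapt character subset of c("means", "weights", "variances").
#' @export
setClass("MapConfig",
  representation(relevanceFactor = "numeric", adapt = "character"))

setValidity("MapConfig", function(object) {
  if (length(object@relevanceFactor) != 1L || is.na(object@relevanceFactor) ||
      object@relevanceFactor < 0)
    return("relevanceFactor must be a single number >= 0 (Inf allowed)")
  if (!length(object@adapt) ||
      !all(object@adapt %in% c("means", "weights", "variances")))
    return("adapt must be a subset of means/weights/variances")
  TRUE
})

#' SufficientStats: zeroth/first/second moments against a fixed UBM
#'
#' Per-component soft counts and moment sums with posteriors computed
#' against a fixed UBM, so statistics of a set of vocalizations are the
#' elementwise sum of the statistics of its members. This additivity is
#' what makes exact leave-one-out by subtraction possible.
#'
#' @slot n length-K soft counts.
#' @slot first K x d weighted sums of the frames.
#' @slot second K x d weighted sums of squared frames.
#' @slot nFrames total frame count.
#' @export
setClass("SufficientStats",
  representation(n = "numeric", first = "matrix", second = "matrix",
                 nFrames = "numeric"))

#' @describeIn SufficientStats-class statistics add across vocalization sets.
#' @param e1,e2 SufficientStats computed against the same UBM.
#' @export
setMethod("+", signature("SufficientStats", "SufficientStats"), function(e1, e2) {
  new("SufficientStats", n = e1@n + e2@n, first = e1@first + e2@first,
      second = e1@second + e2@second, nFrames = e1@nFrames + e2@nFrames)
})

#' @describeIn SufficientStats-class subtraction (leave-one-out downdating).
#' @export
setMethod("-", signature("SufficientStats", "SufficientStats"), function(e1, e2) {
  new("SufficientStats", n = pmax(e1@n - e2@n, 0),
      first = e1@first - e2@first, second = e1@second - e2@second,
      nFrames = e1@nFrames - e2@nFrames)
})

## ---------------------------------------------------------------------------
## Evaluation classes
## ---------------------------------------------------------------------------

#' TaskSpec: one classification task
#'
#' @slot labelAxis one of emitter, addressee, addressee_sex, context,
#'   context_x_emitter, outcome, detailed_outcome.
#' @slot populationFilter function(data.frame) -> logical row mask, or NULL.
#' @slot minClassSize classes with fewer vocalizations are dropped.
#' @slot excludedLabels labels removed before filtering.
#' @slot name display name.
#' @export
setClass("TaskSpec",
  representation(labelAxis = "character", populationFilter = "ANY",
                 minClassSize = "integer", excludedLabels = "character",
                 name = "character"))

setValidity("TaskSpec", function(object) {
  axes <- c("emitter", "addressee", "addressee_sex", "context",
            "context_x_emitter", "outcome", "detailed_outcome")
  if (!object@labelAxis %in% axes)
    return(paste("labelAxis must be one of:", paste(axes, collapse = ", ")))
  if (object@minClassSize < 1L) return("minClassSize must be >= 1")
  if (!is.null(object@populationFilter) && !is.function(object@populationFilter))
    return("populationFilter must be NULL or a function")
  TRUE
})

#' ConfusionMatrix: raw counts with row-normalized view
#'
#' Rows are true classes, columns predicted classes.
#'
#' @slot labels ordered class labels.
#' @slot counts C x C integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(labels = "character", counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  C <- length(object@labels)
  if (!identical(dim(object@counts), c(C, C)))
    return("counts must be C x C")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (any(rowSums(object@counts) == 0))
    return("every true class needs at least one vocalization")
  TRUE
})

#' PermutationResult: label-permutation significance of a balanced accuracy
#'
#' @slot observedBA balanced accuracy on the true labels.
#' @slot nullBAs balanced accuracies under label permutations.
#' @slot pValue add-one estimator (1 + #\{null >= observed\}) / (1 + nPerm).
#' @slot nPerm number of permutations.
#' @slot seed permutation seed.
#' @export
setClass("PermutationResult",
  representation(observedBA = "numeric", nullBAs = "numeric",
                 pValue = "numeric", nPerm = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullBAs) != object@nPerm)
    return("nullBAs length must equal nPerm")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' LooResult: leave-one-out predictions and class scores
#'
#' Every score was produced while the vocalization was held out of its own
#' class model, so the score matrix is safe to use for test-time
#' visualization (provenance slot set to "loo").
#'
#' @slot vocIds vocalization identifiers.
#' @slot truth true labels (factor).
#' @slot predicted predicted labels (factor, same levels).
#' @slot scores N x C log-likelihood-ratio matrix, columns named by class.
#' @slot provenance "loo" for cross-validated scores.
#' @export
setClass("LooResult",
  representation(vocIds = "character", truth = "factor", predicted = "factor",
                 scores = "matrix", provenance = "character"))

setValidity("LooResult", function(object) {
  N <- length(object@vocIds)
  if (length(object@truth) != N || length(object@predicted) != N)
    return("truth/predicted length mismatch")
  if (nrow(object@scores) != N) return("scores rows must match vocIds")
  if (is.null(colnames(object@scores))) return("scores columns must be named")
  if (!all(is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' ProjectionResult: 2-D discriminant projection of score vectors
#'
#' @slot vocIds vocalization identifiers.
#' @slot labels class labels used for the discriminant fit.
#' @slot coordinates N x 2 projected coordinates.
#' @slot discriminantVectors C x 2 discriminant directions in score space.
#' @slot classCentroids2d per-class centroids of the projection.
#' @export
setClass("ProjectionResult",
  representation(vocIds = "character", labels = "factor",
                 coordinates = "matrix", discriminantVectors = "matrix",
                 classCentroids2d = "matrix"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec:", object@nEmitters, "emitters x",
      length(object@contexts), "contexts x", object@callsPerCell,
      "calls/cell @", object@sampleRate / 1000, "kHz\n")
  cat("  effects: context", object@formantShiftPerContext, "Hz, addressee",
      object@addresseeTilt, "dB/kHz, outcome", object@outcomeGain,
      "dB; SNR", object@noiseSnr, "dB; seed", object@seed, "\n")
})

setMethod("show", "SynthDataset", function(object) {
  cat("SynthDataset:", nrow(object@annotations), "vocalizations in",
      object@audioDir, "\n")
})

setMethod("show", "FeatureSet", function(object) {
  d <- if (length(object@features)) ncol(object@features[[1L]]) else 0L
  cat("FeatureSet:", length(object@features), "vocalizations,",
      sum(vapply(object@features, nrow, 0L)), "frames of dimension", d, "\n")
})

setMethod("show", "GmmParams", function(object) {
  cat("GmmParams:", length(object@weights), "diagonal components in",
      ncol(object@means), "dimensions\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth):\n")
  print(object@counts)
  cat(sprintf("balanced accuracy: %.3f\n", balancedAccuracy(object)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: observed BA %.3f, p = %.4g (%d permutations)\n",
              object@observedBA, object@pValue, object@nPerm))
})

setMethod("show", "LooResult", function(object) {
  cat("LooResult:", length(object@vocIds), "vocalizations,",
      ncol(object@scores), "classes, accuracy",
      sprintf("%.3f", mean(object@truth == object@predicted)), "\n")
})
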