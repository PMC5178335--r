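#' @include AllClasses.R
NULL

#' Create a synthetic-corpus specification
#'
#' Defaults describe the study conditions the generator emulates: audio at
#' 250 kHz, four aggression contexts, multisyllabic calls of 1--20
#' broad-band multi-harmonic syllables with short silences between them,
#' two recording channels with fixed coloration, and a demonstration-scale
#' population of 4 emitters with 40 calls per (emitter, context) cell.
#' Effect sizes are per-axis and orthogonal; setting one to 0 removes the
#' class signal along that axis only.
#'
#' Addressee sex is a deterministic attribute of the addressee identity
#' (odd-indexed addressees female, even-indexed male), so the sex
#' classification task is derivable from labels alone.
#'
#' @param seed master seed (integer).
#' @param sampleRate Hz.
#' @param nEmitters number of emitters.
#' @param contexts context labels.
#' @param addressees addressee labels.
#' @param outcomes outcome labels.
#' @param callsPerCell calls per (emitter, context) cell.
#' @param syllableCountRange integer pair within \[1, 20\].
#' @param syllableDurationRange seconds.
#' @param gapDurationRange seconds.
#' @param f0Base per-emitter fundamental (Hz); default spreads emitters
#'   over 500--800 Hz.
#' @param formantShiftPerContext Hz per context step; 0 = null.
#' @param addresseeTilt dB/kHz per addressee step; 0 = null.
#' @param outcomeGain dB per outcome step; 0 = null.
#' @param noiseSnr additive white-noise SNR in dB.
#' @param nChannels recording channels.
#' @param channelColoration per-channel spectral slope, dB/kHz.
#' @return a validated [SynthSpec-class].
#' @examples
#' spec <- synthSpec(seed = 1, nEmitters = 2, callsPerCell = 5)
#' spec
#' @export
synthSpec <- function(seed = 1L,
                      sampleRate = 250000,
                      nEmitters = 4L,
                      contexts = c("feeding_aggr", "mating_aggr",
                                   "perch_aggr", "sleep_aggr"),
                      addressees = paste0("A", 1:4),
                      outcomes = c("depart", "remain_together"),
                      callsPerCell = 40L,
                      syllableCountRange = c(1L, 20L),
                      syllableDurationRange = c(0.025, 0.050),
                      gapDurationRange = c(0.015, 0.040),
                      f0Base = NULL,
                      formantShiftPerContext = 3000,
                      addresseeTilt = 0.6,
                      outcomeGain = 4,
                      noiseSnr = 30,
                      nChannels = 2L,
                      channelColoration = NULL) {
  nEmitters <- as.integer(nEmitters)
  if (is.null(f0Base)) {
    f0Base <- if (nEmitters == 1L) 600
    else seq(500, 800, length.out = nEmitters)
  }
  if (is.null(channelColoration)) {
    nChannels <- as.integer(nChannels)
    channelColoration <- if (nChannels == 1L) 0
    else seq(-0.15, 0.15, length.out = nChannels)
  }
  sex <- setNames(rep(c("F", "M"), length.out = length(addressees)), addressees)
  new("SynthSpec", seed = as.integer(seed), sampleRate = sampleRate,
      nEmitters = nEmitters, contexts = contexts, addressees = addressees,
      addresseeSex = sex, outcomes = outcomes,
      callsPerCell = as.integer(callsPerCell),
      syllableCountRange = as.integer(syllableCountRange),
      syllableDurationRange = syllableDurationRange,
      gapDurationRange = gapDurationRange, f0Base = f0Base,
      formantShiftPerContext = formantShiftPerContext,
      addresseeTilt = addresseeTilt, outcomeGain = outcomeGain,
      noiseSnr = noiseSnr, nChannels = as.integer(nChannels),
      channelColoration = channelColoration)
}

#' Short-time framing parameters
#'
#' @param windowLength window length, seconds (default 20 ms).
#' @param hop frame advance, seconds (default 1 ms, i.e. 19 ms overlap).
#' @param windowFunction "hann" or "rectangular".
#' @export
frameParams <- function(windowLength = 0.020, hop = 0.001,
                        windowFunction = "hann") {
  new("FrameParams", windowLength = windowLength, hop = hop,
      windowFunction = windowFunction)
}

#' MFCC configuration
#'
#' Defaults: 64 coefficients from 128 triangular mel filters spanning
#' 100 Hz to 60 kHz (the band that carries the call energy), log floor
#' 1e-10, orthonormal DCT-II, c0 retained (channel/loudness bias is later
#' removed by cepstral mean subtraction).
#'
#' @param nCoefficients coefficients kept (default 64).
#' @param nMelFilters number of mel filters (default 128).
#' @param fMin,fMax filterbank range, Hz.
#' @param logFloor energy floor before the log.
#' @param includeC0 keep the 0th coefficient.
#' @param preEmphasis first-order pre-emphasis coefficient (0 disables).
#' @param nFft FFT size, 0 = next power of two >= window length.
#' @export
cepstralConfig <- function(nCoefficients = 64L, nMelFilters = 128L,
                           fMin = 100, fMax = 60000, logFloor = 1e-10,
                           includeC0 = TRUE, preEmphasis = 0, nFft = 0L) {
  new("CepstralConfig", nCoefficients = as.integer(nCoefficients),
      nMelFilters = as.integer(nMelFilters), fMin = fMin, fMax = fMax,
      logFloor = logFloor, includeC0 = includeC0, preEmphasis = preEmphasis,
      nFft = as.integer(nFft))
}

#' Voiced-segment detector configuration
#'
#' @param energyWindow RMS window, seconds.
#' @param energyHop RMS hop, seconds.
#' @param thresholdMode "relative" (dB above estimated noise floor) or
#'   "absolute" (dBFS).
#' @param thresholdValue threshold in dB.
#' @param minSegment shortest voiced run kept, seconds.
#' @param mergeGap silences shorter than this are bridged, seconds.
#' @export
segmenterConfig <- function(energyWindow = 0.004, energyHop = 0.001,
                            thresholdMode = "relative", thresholdValue = 12,
                            minSegment = 0.01, mergeGap = 0.008) {
  new("SegmenterConfig", energyWindow = energyWindow, energyHop = energyHop,
      thresholdMode = thresholdMode, thresholdValue = thresholdValue,
      minSegment = minSegment, mergeGap = mergeGap)
}

#' MAP adaptation configuration
#'
#' @param relevanceFactor pseudo-count (default 16); Inf yields the UBM.
#' @param adapt parameter groups to adapt; default means only.
#' @export
mapConfig <- function(relevanceFactor = 16, adapt = "means") {
  new("MapConfig", relevanceFactor = relevanceFactor, adapt = adapt)
}

#' Construct a mixture model from explicit parameters
#'
#' @param weights simplex weights.
#' @param means K x d matrix.
#' @param variances K x d matrix of positive diagonal variances.
#' @export
gmmParams <- function(weights, means, variances) {
  means <- as.matrix(means)
  variances <- as.matrix(variances)
  new("GmmParams", weights = weights / sum(weights), means = means,
      variances = variances, varianceFloor = numeric(0),
      logLikTrace = numeric(0))
}

#' Define a classification task
#'
#' @param labelAxis annotation column to classify (see [TaskSpec-class]).
#' @param populationFilter optional function(annotations) -> logical mask,
#'   e.g. `function(a) a$emitter == "E1"`.
#' @param minClassSize classes smaller than this are dropped (the study
#'   used 15 per context, 20 per addressee and 10 in per-emitter controls).
#' @param excludedLabels labels removed up front (e.g. mating aggression is
#'   excluded from addressee tasks because it is addressed exclusively to
#'   the male).
#' @param name display name, defaults to the axis.
#' @export
taskSpec <- function(labelAxis, populationFilter = NULL, minClassSize = 1L,
                     excludedLabels = character(0), name = labelAxis) {
  new("TaskSpec", labelAxis = labelAxis, populationFilter = populationFilter,
      minClassSize = as.integer(minClassSize),
      excludedLabels = excludedLabels, name = name)
}
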