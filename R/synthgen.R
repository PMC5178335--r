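## Synthetic vocalization generator.
##
## The acoustic family is a harmonic stack shaped by a formant-like
## Gaussian spectral envelope, with additive white noise. Class axes map
## to orthogonal acoustic dimensions so each classification task has an
## individually tunable planted signal:
##   emitter   -> fundamental frequency + envelope base centre
##   context   -> formant (envelope) centre shift
##   addressee -> spectral tilt (dB/kHz)
##   outcome   -> amplitude gain and envelope bandwidth

ENV_CENTER_BASE <- 9000   # Hz, emitter envelope base centre
ENV_CENTER_STEP <- 500    # Hz per emitter around the base
ENV_WIDTH_BASE <- 4000    # Hz, formant envelope standard width
SYLLABLE_PEAK <- 0.25     # nominal waveform peak before outcome gain
NOMINAL_RMS <- 0.08       # reference level defining the noise SNR

## centred per-class offsets: label i of C gets (i - (C+1)/2) * step
axisOffset <- function(i, n, step) (i - (n + 1) / 2) * step

emitterParamsFor <- function(spec, e) {
  list(f0 = spec@f0Base[e],
       envCenter = ENV_CENTER_BASE +
         axisOffset(e, spec@nEmitters, ENV_CENTER_STEP),
       envWidth = ENV_WIDTH_BASE)
}

contextParamsFor <- function(spec, ci) {
  list(formantShift = axisOffset(ci, length(spec@contexts),
                                 spec@formantShiftPerContext))
}

addresseeParamsFor <- function(spec, ai) {
  list(tilt = axisOffset(ai, length(spec@addressees), spec@addresseeTilt))
}

outcomeParamsFor <- function(spec, oi) {
  off <- axisOffset(oi, length(spec@outcomes), 1)
  list(gainDb = off * spec@outcomeGain,
       bwFactor = exp(0.05 * off * spec@outcomeGain))
}

#' Synthesize one harmonic syllable
#'
#' Produces a stack of at least 8 harmonics of the emitter's fundamental,
#' shaped by a context-dependent formant-like Gaussian spectral envelope,
#' an addressee-dependent spectral tilt and an outcome-dependent
#' amplitude/bandwidth, amplitude-enveloped to zero at both ends by
#' raised-cosine ramps.
#'
#' @param emitterParams list(f0, envCenter, envWidth) in Hz.
#' @param contextParams list(formantShift) in Hz.
#' @param addresseeParams list(tilt) in dB/kHz.
#' @param outcomeParams list(gainDb, bwFactor).
#' @param duration syllable duration in seconds (> 0).
#' @param sampleRate Hz; must satisfy the Nyquist bound for the highest
#'   synthesized harmonic, otherwise the call is rejected as aliasing.
#' @param rngSeed seed for per-syllable jitter and harmonic phases.
#' @param channelTilt recording-channel coloration, dB/kHz.
#' @param nHarmonics harmonic count; NULL chooses enough harmonics to
#'   fill the band up to min(60 kHz, 0.45 * sampleRate).
#' @return numeric waveform of round(duration * sampleRate) samples.
#' @examples
#' w <- generateSyllable(list(f0 = 500, envCenter = 9000, envWidth = 4000),
#'                       list(formantShift = 0), list(tilt = 0),
#'                       list(gainDb = 0, bwFactor = 1),
#'                       duration = 0.02, sampleRate = 250000, rngSeed = 7)
#' length(w)
#' @export
generateSyllable <- function(emitterParams, contextParams, addresseeParams,
                             outcomeParams, duration, sampleRate,
                             rngSeed = 1L, channelTilt = 0,
                             nHarmonics = NULL) {
  stopifnotScalarNumber(duration, "duration")
  if (duration <= 0) stop("duration must be > 0")
  f0 <- emitterParams$f0
  if (is.null(nHarmonics)) {
    bandTop <- min(60000, 0.45 * sampleRate)
    nHarmonics <- max(8L, floor(bandTop / f0))
  }
  if (2 * nHarmonics * f0 > sampleRate)
    stop(sprintf("aliasing: highest harmonic %.0f Hz exceeds Nyquist %.0f Hz",
                 nHarmonics * f0, sampleRate / 2))

  n <- round(duration * sampleRate)
  withSeed(rngSeed, {
    f0 <- f0 * 2^rnorm(1L, 0, 0.02)   # small per-syllable pitch jitter
    phases <- runif(nHarmonics, 0, 2 * pi)
    freqs <- f0 * seq_len(nHarmonics)
    center <- emitterParams$envCenter + contextParams$formantShift
    width <- emitterParams$envWidth * outcomeParams$bwFactor
    ampDb <- -10 * ((freqs - center) / width)^2 +
      (addresseeParams$tilt + channelTilt) * freqs / 1000
    amps <- dbToLinear(ampDb)
    t <- (seq_len(n) - 1L) / sampleRate
    wave <- sin(outer(t, 2 * pi * freqs) +
                matrix(phases, n, nHarmonics, byrow = TRUE)) %*% amps
    wave <- as.numeric(wave)
    ## raised-cosine onset/offset ramps (20% of the syllable each),
    ## exactly zero at the first and last sample
    nr <- max(1L, round(0.2 * n))
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1L) / nr)
    env <- rep(1, n)
    env[seq_len(nr)] <- ramp
    env[n + 1L - seq_len(nr)] <- ramp
    wave <- wave * env
    peak <- max(abs(wave))
    if (peak > 0) wave <- wave * (SYLLABLE_PEAK / peak)
    wave * dbToLinear(outcomeParams$gainDb)
  })
}

#' Generate a labeled synthetic corpus
#'
#' Writes one WAV per vocalization (a syllable train with inter-syllable
#' silences and leading/trailing padding, plus additive white noise at the
#' specified SNR and per-channel coloration) and assembles the annotation
#' table. Identical specs (including seed) give byte-identical output.
#'
#' @param spec a [SynthSpec-class].
#' @param dir output directory for the WAV files.
#' @return a [SynthDataset-class].
#' @examples
#' spec <- synthSpec(seed = 1, nEmitters = 2, callsPerCell = 1,
#'                   syllableCountRange = c(1, 2))
#' ds <- generateDataset(spec, dir = tempfile())
#' head(annotations(ds))
#' @export
generateDataset <- function(spec, dir = tempfile("synthds")) {
  validObject(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rate <- spec@sampleRate
  padSamples <- round(0.05 * rate)
  sigma <- NOMINAL_RMS * 10^(-spec@noiseSnr / 20)

  grid <- expand.grid(k = seq_len(spec@callsPerCell),
                      ci = seq_along(spec@contexts),
                      e = seq_len(spec@nEmitters))
  nVoc <- nrow(grid)
  ann <- vector("list", nVoc)
  syl <- vector("list", nVoc)

  for (i in seq_len(nVoc)) {
    e <- grid$e[i]; ci <- grid$ci[i]
    vocSeed <- deriveSeed(spec@seed, "voc", i)
    draw <- withSeed(vocSeed, {
      nSyll <- sample(seq(spec@syllableCountRange[1L],
                          spec@syllableCountRange[2L]), 1L)
      list(ai = sample(seq_along(spec@addressees), 1L),
           oi = sample(seq_along(spec@outcomes), 1L),
           channel = sample(seq_len(spec@nChannels), 1L),
           nSyll = nSyll,
           durs = runif(nSyll, spec@syllableDurationRange[1L],
                        spec@syllableDurationRange[2L]),
           gaps = runif(max(nSyll - 1L, 0L), spec@gapDurationRange[1L],
                        spec@gapDurationRange[2L]),
           leaver = sample(c("emitter_leaves", "addressee_leaves",
                             "both_leave"), 1L))
    })
    ep <- emitterParamsFor(spec, e)
    cp <- contextParamsFor(spec, ci)
    ap <- addresseeParamsFor(spec, draw$ai)
    op <- outcomeParamsFor(spec, draw$oi)
    chTilt <- spec@channelColoration[draw$channel]

    pieces <- vector("list", 2L * draw$nSyll + 1L)
    pieces[[1L]] <- numeric(padSamples)
    pos <- padSamples
    starts <- ends <- integer(draw$nSyll)
    for (j in seq_len(draw$nSyll)) {
      w <- generateSyllable(ep, cp, ap, op, draw$durs[j], rate,
                            rngSeed = deriveSeed(vocSeed, "syll", j),
                            channelTilt = chTilt)
      starts[j] <- pos + 1L
      ends[j] <- pos + length(w)
      pieces[[2L * j]] <- w
      pos <- pos + length(w)
      gapN <- if (j < draw$nSyll) round(draw$gaps[j] * rate) else padSamples
      pieces[[2L * j + 1L]] <- numeric(gapN)
      pos <- pos + gapN
    }
    wave <- unlist(pieces, use.names = FALSE)
    wave <- wave + withSeed(deriveSeed(vocSeed, "noise"),
                            rnorm(length(wave), 0, sigma))

    vocId <- sprintf("voc_%05d", i)
    wavPath <- file.path(dir, paste0(vocId, ".wav"))
    writeWav(wave, wavPath, rate, bitDepth = 32L)

    outcome <- spec@outcomes[draw$oi]
    ann[[i]] <- data.frame(
      voc_id = vocId, wav_path = wavPath, channel = draw$channel,
      t_start_s = 0, t_end_s = length(wave) / rate,
      emitter = paste0("E", e),
      addressee = spec@addressees[draw$ai],
      addressee_sex = unname(spec@addresseeSex[spec@addressees[draw$ai]]),
      context = spec@contexts[ci], outcome = outcome,
      detailed_outcome = if (outcome == "depart") draw$leaver else outcome,
      stringsAsFactors = FALSE)
    syl[[i]] <- data.frame(voc_id = vocId, syll_idx = seq_len(draw$nSyll),
                           start_sample = starts, end_sample = ends,
                           stringsAsFactors = FALSE)
  }

  new("SynthDataset", audioDir = dir,
      annotations = do.call(rbind, ann), truth = spec,
      syllables = do.call(rbind, syl))
}

#' Draw feature vectors from a diagonal-covariance mixture
#'
#' @param model a [GmmParams-class].
#' @param n number of vectors.
#' @return n x d numeric matrix.
#' @export
sampleGmm <- function(model, n) {
  K <- nComponents(model)
  comp <- sample.int(K, n, replace = TRUE, prob = mixtureWeights(model))
  mu <- mixtureMeans(model)[comp, , drop = FALSE]
  sd <- sqrt(mixtureVariances(model))[comp, , drop = FALSE]
  mu + matrix(rnorm(n * ncol(mu)), n, ncol(mu)) * sd
}

#' Generate labeled feature streams from known class mixtures
#'
#' Bypasses audio synthesis and DSP entirely: each item is a sequence of
#' vectors drawn i.i.d. from its class mixture, so classifier behaviour
#' can be tested against known generative truth (including the zero-effect
#' null, where all classes share one mixture).
#'
#' @param models named list of [GmmParams-class], one per class; all must
#'   share dimensionality.
#' @param labels character vector, class of each item (names of `models`).
#' @param lengths integer vector, frames per item.
#' @param seed integer seed.
#' @return a [FeatureSet-class] whose meta has a `class` column.
#' @examples
#' m <- gmmParams(1, matrix(0, 1, 2), matrix(1, 1, 2))
#' fs <- generateFeatureStreams(list(a = m), rep("a", 3), c(5, 7, 9), seed = 1)
#' vapply(vocFeatures(fs), nrow, 0L)
#' @export
generateFeatureStreams <- function(models, labels, lengths, seed = 1L) {
  dims <- vapply(models, featureDim, 0L)
  if (length(unique(dims)) != 1L)
    stop("mismatched dimensions: all class mixtures must share dimensionality")
  if (!all(labels %in% names(models)))
    stop("labels must name entries of 'models'")
  if (length(labels) != length(lengths))
    stop("labels and lengths must have equal length")
  feats <- lapply(seq_along(labels), function(i) {
    withSeed(deriveSeed(seed, "stream", i),
             sampleGmm(models[[labels[i]]], lengths[i]))
  })
  meta <- data.frame(voc_id = sprintf("fs_%05d", seq_along(labels)),
                     channel = 1L, class = labels,
                     nFrames = as.integer(lengths),
                     stringsAsFactors = FALSE)
  new("FeatureSet", features = feats, meta = meta)
}

#' Write / read an annotation table
#'
#' Delimited text with the delimiter declared in a leading header line
#' (`# delim=,`), columns voc_id, wav_path, channel, t_start_s, t_end_s,
#' emitter, addressee, addressee_sex, context, outcome, detailed_outcome.
#'
#' @param annotations annotation data.frame (or a [SynthDataset-class]).
#' @param path file path.
#' @param delim "," or tab.
#' @return `path` invisibly; `readAnnotations` returns the data.frame.
#' @export
writeAnnotations <- function(annotations, path, delim = ",") {
  if (is(annotations, "SynthDataset")) annotations <- annotations@annotations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# delim=", if (delim == "\t") "\\t" else delim), con)
  utils::write.table(annotations, con, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- sub("^# delim=", "", header)
  if (delim == "\\t") delim <- "\t"
  utils::read.table(path, sep = delim, header = TRUE, skip = 1L,
                    stringsAsFactors = FALSE)
}

#' Serialize a SynthSpec as a flat JSON config
#'
#' @param spec a [SynthSpec-class].
#' @param path file path.
#' @export
writeSynthSpec <- function(spec, path) {
  sl <- slotNames(spec)
  x <- lapply(sl, function(s) slot(spec, s))
  names(x) <- sl
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSynthSpec
#' @export
readSynthSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SynthSpec", seed = as.integer(x$seed), sampleRate = x$sampleRate,
      nEmitters = as.integer(x$nEmitters), contexts = x$contexts,
      addressees = x$addressees,
      addresseeSex = setNames(as.character(x$addresseeSex), x$addressees),
      outcomes = x$outcomes, callsPerCell = as.integer(x$callsPerCell),
      syllableCountRange = as.integer(x$syllableCountRange),
      syllableDurationRange = x$syllableDurationRange,
      gapDurationRange = x$gapDurationRange, f0Base = x$f0Base,
      formantShiftPerContext = x$formantShiftPerContext,
      addresseeTilt = x$addresseeTilt, outcomeGain = x$outcomeGain,
      noiseSnr = x$noiseSnr, nChannels = as.integer(x$nChannels),
      channelColoration = x$channelColoration)
}
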