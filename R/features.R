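## MFCC feature extraction.
##
## Per frame: power spectrum -> triangular mel filterbank energies ->
## log (floored) -> orthonormal type-II DCT -> first nCoefficients kept.
## Defaults give the 64-dimensional vectors used by every classification
## task: 20 ms Hann windows advancing 1 ms, 128 mel filters over
## 100 Hz -- 60 kHz.

melOfHz <- function(f) 2595 * log10(1 + f / 700)
hzOfMel <- function(m) 700 * (10^(m / 2595) - 1)

#' Cut a segment into tapered analysis frames
#'
#' Frames start every `hop` seconds; only frames fully inside the segment
#' are produced. A segment shorter than one window yields an empty
#' framing flagged with `attr(, "tooShort")` so the caller can drop it
#' (padding would fabricate spectra).
#'
#' @param audio numeric segment waveform.
#' @param params a [FrameParams-class].
#' @param sampleRate Hz.
#' @return list with `frames` (window x nFrames matrix, taper applied)
#'   and `times` (frame centre times, seconds from segment start).
#' @examples
#' fr <- frameSegment(rnorm(5000), frameParams(), 50000)
#' ncol(fr$frames)   # floor((5000 - 1000)/50) + 1
#' @export
frameSegment <- function(audio, params = frameParams(), sampleRate) {
  validObject(params)
  win <- round(params@windowLength * sampleRate)
  hop <- max(1L, round(params@hop * sampleRate))
  if (length(audio) < win) {
    out <- list(frames = matrix(numeric(0), nrow = win, ncol = 0),
                times = numeric(0))
    attr(out, "tooShort") <- TRUE
    return(out)
  }
  starts <- seq.int(1L, length(audio) - win + 1L, by = hop)
  idx <- outer(seq_len(win) - 1L, starts, "+")
  frames <- matrix(audio[idx], nrow = win)
  if (params@windowFunction == "hann")
    frames <- frames * hannWindow(win)
  list(frames = frames, times = (starts - 1L + win / 2) / sampleRate)
}

#' Triangular mel filterbank
#'
#' Filter centres are uniformly spaced on the mel scale
#' m = 2595 log10(1 + f/700); each filter is a triangle between its
#' neighbouring centres, evaluated at the FFT bin frequencies. All
#' weights are non-negative.
#'
#' @param nFilters number of filters.
#' @param fMin,fMax band edges, Hz (fMax at most Nyquist).
#' @param nFft FFT size.
#' @param sampleRate Hz.
#' @return nFilters x (nFft/2 + 1) weight matrix with attribute
#'   `centersHz`.
#' @export
melFilterbank <- function(nFilters, fMin, fMax, nFft, sampleRate) {
  if (fMax > sampleRate / 2) stop("fMax must not exceed Nyquist")
  melPts <- seq(melOfHz(fMin), melOfHz(fMax), length.out = nFilters + 2L)
  hzPts <- hzOfMel(melPts)
  binHz <- (seq_len(nFft %/% 2L + 1L) - 1L) * sampleRate / nFft
  fb <- matrix(0, nFilters, length(binHz))
  for (k in seq_len(nFilters)) {
    lo <- hzPts[k]; ce <- hzPts[k + 1L]; hi <- hzPts[k + 2L]
    up <- (binHz - lo) / (ce - lo)
    down <- (hi - binHz) / (hi - ce)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0))
    stop("nFft too small to resolve the requested mel filters")
  attr(fb, "centersHz") <- hzPts[2:(nFilters + 1L)]
  fb
}

## small per-session cache so the filterbank and DCT matrices are not
## rebuilt for every segment
.featureCache <- new.env(parent = emptyenv())

cachedFilterbank <- function(nFilters, fMin, fMax, nFft, sampleRate) {
  key <- paste("fb", nFilters, fMin, fMax, nFft, sampleRate, sep = "_")
  if (is.null(.featureCache[[key]]))
    .featureCache[[key]] <- melFilterbank(nFilters, fMin, fMax, nFft,
                                          sampleRate)
  .featureCache[[key]]
}

cachedDct <- function(n) {
  key <- paste0("dct_", n)
  if (is.null(.featureCache[[key]])) .featureCache[[key]] <- dctMatrix(n)
  .featureCache[[key]]
}

## orthonormal type-II DCT matrix (n x n)
dctMatrix <- function(n) {
  k <- seq_len(n) - 1L
  j <- seq_len(n) - 1L
  D <- sqrt(2 / n) * cos(pi * outer(k, j + 0.5) / n)
  D[1L, ] <- sqrt(1 / n)
  D
}

#' Compute MFCC vectors for a framed segment
#'
#' @param frames window x nFrames matrix from [frameSegment()] (taper
#'   already applied).
#' @param config a [CepstralConfig-class].
#' @param sampleRate Hz.
#' @return nFrames x nCoefficients matrix of cepstral vectors.
#' @export
computeMFCC <- function(frames, config = cepstralConfig(), sampleRate) {
  validObject(config)
  if (!is.matrix(frames) || ncol(frames) == 0L)
    stop("framed input must be a non-empty matrix")
  if (!all(is.finite(frames))) stop("non-finite input")
  win <- nrow(frames)
  nFft <- if (config@nFft > 0L) config@nFft else 2L^ceiling(log2(win))
  if (nFft < win) stop("nFft smaller than window length")
  fb <- cachedFilterbank(config@nMelFilters, config@fMin,
                         min(config@fMax, sampleRate / 2), nFft, sampleRate)
  D <- cachedDct(config@nMelFilters)
  rows <- if (config@includeC0) seq_len(config@nCoefficients)
          else seq_len(config@nCoefficients) + 1L
  D <- D[rows, , drop = FALSE]

  nF <- ncol(frames)
  out <- matrix(0, nF, config@nCoefficients)
  chunk <- 256L
  nBins <- nFft %/% 2L + 1L
  for (i0 in seq.int(1L, nF, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nF)
    padded <- matrix(0, nFft, i1 - i0 + 1L)
    padded[seq_len(win), ] <- frames[, i0:i1, drop = FALSE]
    P <- abs(stats::mvfft(padded))[seq_len(nBins), , drop = FALSE]^2
    logE <- log(pmax(fb %*% P, config@logFloor))
    out[i0:i1, ] <- t(D %*% logE)
  }
  out
}

#' Pool the frames of all segments of one vocalization
#'
#' Concatenates per-segment frame matrices in temporal order; silent gaps
#' contribute no frames.
#'
#' @param segmentFrames list of nFrames x nCoefficients matrices, one per
#'   segment.
#' @param segmentTimes matching list of frame-centre time vectors
#'   (seconds, in recording coordinates); optional.
#' @return matrix of pooled vectors with attribute `frameTimes`.
#' @export
poolVocalization <- function(segmentFrames, segmentTimes = NULL) {
  segmentFrames <- segmentFrames[vapply(segmentFrames, nrow, 0L) > 0L]
  if (!length(segmentFrames))
    stop("vocalization has zero usable frames")
  pooled <- do.call(rbind, segmentFrames)
  if (!is.null(segmentTimes))
    attr(pooled, "frameTimes") <- unlist(segmentTimes, use.names = FALSE)
  pooled
}

#' Extract pooled MFCC features for one vocalization
#'
#' @param audio full-recording waveform (one channel).
#' @param sampleRate Hz.
#' @param segments an [IRanges::IRanges] (or data.frame with start_sample
#'   / end_sample) of voiced segments, 1-based inclusive.
#' @param fparams a [FrameParams-class].
#' @param cconfig a [CepstralConfig-class].
#' @return nFrames x nCoefficients matrix (attribute `frameTimes`), or
#'   NULL if no segment yields a full analysis window.
#' @export
featurizeVocalization <- function(audio, sampleRate, segments,
                                  fparams = frameParams(),
                                  cconfig = cepstralConfig()) {
  if (is.data.frame(segments))
    segments <- IRanges::IRanges(start = segments$start_sample,
                                 end = segments$end_sample)
  if (!length(segments)) return(NULL)
  if (cconfig@preEmphasis > 0)
    audio <- c(audio[1L], audio[-1L] - cconfig@preEmphasis *
                 audio[-length(audio)])
  frames <- list(); times <- list()
  for (i in seq_along(segments)) {
    s <- IRanges::start(segments)[i]; e <- IRanges::end(segments)[i]
    fr <- frameSegment(audio[s:e], fparams, sampleRate)
    if (ncol(fr$frames) == 0L) next
    frames[[length(frames) + 1L]] <- computeMFCC(fr$frames, cconfig, sampleRate)
    times[[length(times) + 1L]] <- fr$times + (s - 1L) / sampleRate
  }
  if (!length(frames)) return(NULL)
  poolVocalization(frames, times)
}

#' Featurize a whole dataset
#'
#' Segments (or accepts precomputed segments for) every vocalization,
#' extracts pooled MFCC frames, drops vocalizations with zero usable
#' frames (with a message), and optionally applies per-channel cepstral
#' mean subtraction.
#'
#' @param dataset a [SynthDataset-class] or annotation data.frame.
#' @param segments optional segment table from [segmentDataset()];
#'   computed if NULL.
#' @param segConfig a [SegmenterConfig-class].
#' @param fparams a [FrameParams-class].
#' @param cconfig a [CepstralConfig-class].
#' @param cms apply [cepstralMeanSubtract()] before returning.
#' @param spans "voiced" (default) or "unvoiced"; the latter extracts
#'   features from the complement of the voiced segments (used by the
#'   non-voiced control) and never reuses voiced samples.
#' @return a [FeatureSet-class]; meta carries the annotation labels.
#' @export
featurizeDataset <- function(dataset, segments = NULL,
                             segConfig = segmenterConfig(),
                             fparams = frameParams(),
                             cconfig = cepstralConfig(),
                             cms = TRUE, spans = c("voiced", "unvoiced")) {
  spans <- match.arg(spans)
  ann <- if (is(dataset, "SynthDataset")) annotations(dataset) else dataset
  if (is.null(segments)) segments <- segmentDataset(dataset, segConfig)

  feats <- list(); keep <- integer(0)
  for (i in seq_len(nrow(ann))) {
    w <- readWav(ann$wav_path[i])
    audio <- w$samples[, min(ann$channel[i], ncol(w$samples))]
    segs <- segments[segments$voc_id == ann$voc_id[i], , drop = FALSE]
    ir <- IRanges::IRanges(start = segs$start_sample, end = segs$end_sample)
    if (spans == "unvoiced")
      ir <- IRanges::gaps(ir, start = 1L, end = length(audio))
    m <- featurizeVocalization(audio, w$sampleRate, ir, fparams, cconfig)
    if (is.null(m)) {
      message("dropping ", ann$voc_id[i], ": zero usable frames")
      next
    }
    feats[[length(feats) + 1L]] <- m
    keep <- c(keep, i)
  }
  meta <- ann[keep, setdiff(names(ann), c("wav_path", "t_start_s", "t_end_s")),
              drop = FALSE]
  meta$nFrames <- vapply(feats, nrow, 0L)
  rownames(meta) <- NULL
  fs <- new("FeatureSet", features = feats, meta = meta)
  if (cms) cepstralMeanSubtract(fs) else fs
}

#' Per-channel cepstral mean subtraction
#'
#' Within each recording channel, the coefficient-wise mean over all
#' frames of all vocalizations is subtracted from every frame, removing
#' fixed channel coloration and loudness bias.
#'
#' @param featureSet a [FeatureSet-class].
#' @return the normalized [FeatureSet-class].
#' @export
cepstralMeanSubtract <- function(featureSet) {
  meta <- vocMeta(featureSet)
  feats <- vocFeatures(featureSet)
  if (!length(feats)) stop("empty feature set")
  for (ch in unique(meta$channel)) {
    idx <- which(meta$channel == ch)
    pooled <- do.call(rbind, feats[idx])
    if (!nrow(pooled)) stop("empty channel group: ", ch)
    mu <- colMeans(pooled)
    for (i in idx) feats[[i]] <- sweep(feats[[i]], 2L, mu)
  }
  initialize(featureSet, features = feats)
}

## ---------------------------------------------------------------------------
## Feature cache: raw little-endian doubles plus a plain-text manifest.
## Round-trips are bit-exact because values never pass through text.
## ---------------------------------------------------------------------------

#' Write / read a feature cache
#'
#' One record per vocalization in a columnar binary block
#' (`features.bin`, little-endian doubles, frames-major) indexed by a
#' plain-text manifest (`manifest.tsv`: voc_id, channel, n_frames,
#' n_coefficients, offset). Round-trip is bit-exact.
#'
#' @param featureSet a [FeatureSet-class].
#' @param dir cache directory.
#' @return `dir` invisibly; `readFeatureCache` returns the
#'   [FeatureSet-class].
#' @export
writeFeatureCache <- function(featureSet, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- vocMeta(featureSet)
  feats <- vocFeatures(featureSet)
  d <- featureDim(featureSet)
  offsets <- cumsum(c(0, vapply(feats, length, 0)))[seq_along(feats)]
  man <- cbind(meta, n_coefficients = d, offset = offsets)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  con <- file(file.path(dir, "features.bin"), "wb")
  on.exit(close(con))
  for (m in feats) writeBin(as.numeric(m), con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname writeFeatureCache
#' @export
readFeatureCache <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  con <- file(file.path(dir, "features.bin"), "rb")
  on.exit(close(con))
  feats <- lapply(seq_len(nrow(man)), function(i) {
    n <- man$nFrames[i] * man$n_coefficients[i]
    matrix(readBin(con, "double", n = n, size = 8, endian = "little"),
           nrow = man$nFrames[i])
  })
  meta <- man[, setdiff(names(man), c("n_coefficients", "offset")),
              drop = FALSE]
  new("FeatureSet", features = feats, meta = meta)
}
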