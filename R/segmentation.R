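## Voiced-segment detection.
##
## A deterministic dB threshold on short-time RMS energy with merge and
## minimum-duration post-rules. In "relative" mode the threshold sits a
## fixed number of dB above an estimated noise floor (20th percentile of
## the short-time RMS), which makes segment boundaries invariant to
## amplitude scaling of the waveform.

#' Detect voiced segments in a waveform
#'
#' Maximal runs of above-threshold short-time RMS energy; gaps shorter
#' than `mergeGap` are bridged, runs shorter than `minSegment` discarded.
#' All-silent input yields an empty result (not an error).
#'
#' @param audio numeric waveform (one channel).
#' @param sampleRate Hz.
#' @param config a [SegmenterConfig-class].
#' @return an [IRanges::IRanges] of sample intervals (1-based, inclusive)
#'   with a metadata column `rmsEnergy` (linear RMS of each segment).
#' @examples
#' sr <- 50000
#' x <- c(numeric(sr / 2), sin(2 * pi * 1000 * seq_len(sr / 10) / sr),
#'        numeric(sr / 2))
#' detectVoicedSegments(x, sr, segmenterConfig(thresholdMode = "absolute",
#'                                             thresholdValue = -30))
#' @export
detectVoicedSegments <- function(audio, sampleRate, config = segmenterConfig()) {
  if (!length(audio)) stop("audio must be non-empty")
  validObject(config)
  win <- max(1L, round(config@energyWindow * sampleRate))
  hop <- max(1L, round(config@energyHop * sampleRate))
  if (length(audio) < win) {
    ## degenerate-short input: treat the whole signal as one energy window
    win <- length(audio)
  }
  starts <- seq.int(1L, length(audio) - win + 1L, by = hop)
  csum <- c(0, cumsum(audio^2))
  energy <- sqrt((csum[starts + win] - csum[starts]) / win)
  energyDb <- 20 * log10(pmax(energy, .Machine$double.xmin))

  thr <- if (config@thresholdMode == "absolute") {
    config@thresholdValue
  } else {
    floorDb <- stats::quantile(energyDb, 0.2, names = FALSE, type = 7)
    floorDb + config@thresholdValue
  }
  above <- energyDb > thr
  if (!any(above)) return(IRanges::IRanges())

  ## windows -> sample runs
  r <- rle(above)
  endsIdx <- cumsum(r$lengths)
  startsIdx <- endsIdx - r$lengths + 1L
  keep <- which(r$values)
  segStart <- starts[startsIdx[keep]]
  segEnd <- pmin(starts[endsIdx[keep]] + win - 1L, length(audio))
  ir <- IRanges::IRanges(start = segStart, end = segEnd)

  ## bridge short gaps, then drop short runs
  mergeSamples <- round(config@mergeGap * sampleRate)
  ir <- IRanges::reduce(ir, min.gapwidth = mergeSamples)
  if (!length(ir)) return(ir)

  ## refine run bounds to hop resolution: a coarse run extends a full
  ## energy window past the voiced material, so trim each end to the
  ## first/last hop-length block still above threshold
  thrLin <- dbToLinear(thr)
  refined <- vapply(seq_along(ir), function(i) {
    s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
    nb <- (e - s + 1L) %/% hop
    if (nb < 2L) return(as.integer(c(s, e)))
    bs <- s + (seq_len(nb) - 1L) * hop
    brms <- sqrt((csum[pmin(bs + hop, e + 1L)] - csum[bs]) / hop)
    above <- which(brms > thrLin)
    if (!length(above)) return(as.integer(c(s, e)))
    as.integer(c(bs[above[1L]],
                 min(bs[above[length(above)]] + hop - 1L, e)))
  }, integer(2L))
  ir <- IRanges::IRanges(start = refined[1L, ], end = refined[2L, ])
  ir <- ir[IRanges::width(ir) >= round(config@minSegment * sampleRate)]
  if (!length(ir)) return(ir)

  rms <- vapply(seq_along(ir), function(i) {
    s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
    sqrt((csum[e + 1L] - csum[s]) / (e - s + 1L))
  }, 0)
  S4Vectors::mcols(ir)$rmsEnergy <- rms
  ir
}

#' Segment every vocalization of a dataset
#'
#' @param dataset a [SynthDataset-class] (or any object with the same
#'   annotation columns; audio is read from `wav_path`).
#' @param config a [SegmenterConfig-class].
#' @return data.frame (voc_id, seg_idx, start_sample, end_sample,
#'   rms_energy), coordinates 1-based inclusive.
#' @export
segmentDataset <- function(dataset, config = segmenterConfig()) {
  ann <- if (is(dataset, "SynthDataset")) annotations(dataset) else dataset
  out <- lapply(seq_len(nrow(ann)), function(i) {
    w <- readWav(ann$wav_path[i])
    audio <- w$samples[, min(ann$channel[i], ncol(w$samples))]
    ir <- detectVoicedSegments(audio, w$sampleRate, config)
    if (!length(ir)) return(NULL)
    data.frame(voc_id = ann$voc_id[i], seg_idx = seq_along(ir),
               start_sample = IRanges::start(ir),
               end_sample = IRanges::end(ir),
               rms_energy = S4Vectors::mcols(ir)$rmsEnergy,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(voc_id = character(), seg_idx = integer(),
                      start_sample = integer(), end_sample = integer(),
                      rms_energy = numeric())
  res
}

#' Sample a background pool of syllables
#'
#' Uniform, seeded sample without replacement from a segment table, used
#' to train the universal background model. The background pool must be
#' disjoint from the train/test vocalizations; pass segments from a
#' held-out corpus.
#'
#' @param segments segment table as returned by [segmentDataset()].
#' @param n sample size (the study used a background set of 3900
#'   syllables).
#' @param seed integer seed.
#' @return subset of `segments`, ordered by voc_id then seg_idx.
#' @export
sampleBackgroundSyllables <- function(segments, n, seed = 1L) {
  if (n > nrow(segments))
    stop(sprintf("requested %d syllables from a pool of %d", n,
                 nrow(segments)))
  idx <- withSeed(seed, sample.int(nrow(segments), n))
  out <- segments[sort(idx), , drop = FALSE]
  out[order(out$voc_id, out$seg_idx), , drop = FALSE]
}

#' Write a segment table as delimited text
#'
#' Columns voc_id, seg_idx, start_sample, end_sample (1-based inclusive
#' sample coordinates).
#'
#' @param segments segment table.
#' @param path file path.
#' @param delim field delimiter.
#' @export
writeSegments <- function(segments, path, delim = "\t") {
  utils::write.table(segments, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
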