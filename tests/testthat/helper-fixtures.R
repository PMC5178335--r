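# shared fixtures, built in code and memoized for the duration of a test run

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small diagonal-covariance mixture with reproducible random parameters
randomStreamModel <- function(d = 4L, K = 2L, seed = 1L, spread = 1.5) {
  set.seed(seed)
  gmmParams(runif(K, 0.3, 0.7),
            matrix(rnorm(K * d, 0, spread), K, d),
            matrix(runif(K * d, 0.5, 1.5), K, d))
}

# class mixtures with means separated by `sep` along every dimension
separatedModels <- function(classes, d = 4L, sep = 6, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(2 * d, 0, 1), 2, d)
  out <- lapply(seq_along(classes), function(i)
    gmmParams(c(0.5, 0.5), base + (i - 1) * sep, matrix(1, 2, d)))
  names(out) <- classes
  out
}

# compact waveform corpus used by several modules; audio stays in tempdir
smallWaveSpec <- function(seed = 11L, ...) {
  synthSpec(seed = seed, nEmitters = 2L, callsPerCell = 4L,
            contexts = c("feeding_aggr", "perch_aggr", "sleep_aggr"),
            syllableCountRange = c(2L, 4L), ...)
}

smallWaveFixture <- function() {
  memoFixture("smallWave", {
    ds <- generateDataset(smallWaveSpec(), dir = tempfile("swave"))
    segs <- segmentDataset(ds)
    fs <- featurizeDataset(ds, segments = segs)
    bgSpec <- smallWaveSpec(seed = 77L)
    bg <- generateDataset(bgSpec, dir = tempfile("swbg"))
    bgSegs <- segmentDataset(bg)
    X <- batvoc:::backgroundFrames(annotations(bg), bgSegs,
                                   frameParams(), cepstralConfig())
    ubm <- fitGmmEM(X, K = 8L, seed = 5L)
    list(ds = ds, segs = segs, fs = fs, ubm = ubm)
  })
}

# textbook mel filterbank built independently with explicit loops
referenceFilterbank <- function(nFilters, fMin, fMax, nFft, sampleRate) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(fMin), mel(fMax), length.out = nFilters + 2))
  nBins <- nFft %/% 2 + 1
  fb <- matrix(0, nFilters, nBins)
  for (k in seq_len(nFilters)) {
    for (b in seq_len(nBins)) {
      f <- (b - 1) * sampleRate / nFft
      if (f > pts[k] && f < pts[k + 1]) {
        fb[k, b] <- (f - pts[k]) / (pts[k + 1] - pts[k])
      } else if (f >= pts[k + 1] && f < pts[k + 2]) {
        fb[k, b] <- (pts[k + 2] - f) / (pts[k + 2] - pts[k + 1])
      }
    }
  }
  fb
}

# brute-force MFCC of one raw (already tapered) frame: power spectrum,
# filterbank energies, log, then an explicit-cosine-sum DCT
referenceMFCC <- function(frame, config, sampleRate) {
  win <- length(frame)
  nFft <- if (config@nFft > 0) config@nFft else 2^ceiling(log2(win))
  padded <- c(frame, numeric(nFft - win))
  P <- Mod(stats::fft(padded))[seq_len(nFft %/% 2 + 1)]^2
  fb <- referenceFilterbank(config@nMelFilters, config@fMin,
                            min(config@fMax, sampleRate / 2), nFft,
                            sampleRate)
  E <- numeric(config@nMelFilters)
  for (k in seq_len(config@nMelFilters)) E[k] <- sum(fb[k, ] * P)
  logE <- log(pmax(E, config@logFloor))
  n <- config@nMelFilters
  cep <- numeric(config@nCoefficients)
  off <- if (config@includeC0) 0L else 1L
  for (i in seq_len(config@nCoefficients)) {
    k <- i - 1L + off
    s <- 0
    for (j in seq_len(n)) s <- s + logE[j] * cos(pi * k * (j - 0.5) / n)
    cep[i] <- if (k == 0L) s * sqrt(1 / n) else s * sqrt(2 / n)
  }
  cep
}
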