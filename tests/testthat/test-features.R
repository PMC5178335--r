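test_that("framing produces the expected frame grid", {
  sr <- 250000
  fp <- frameParams()   # 20 ms window, 1 ms hop
  fr <- frameSegment(rnorm(25000), fp, sr)      # 100 ms
  expect_equal(ncol(fr$frames), 81L)            # floor((100-20)/1)+1
  expect_equal(nrow(fr$frames), 5000L)
  expect_equal(diff(fr$times)[1], 0.001, tolerance = 1e-12)

  fr1 <- frameSegment(rnorm(5000), fp, sr)      # exactly one window
  expect_equal(ncol(fr1$frames), 1L)

  short <- frameSegment(rnorm(4999), fp, sr)
  expect_equal(ncol(short$frames), 0L)
  expect_true(isTRUE(attr(short, "tooShort")))

  # constant input: every (tapered) frame identical
  frc <- frameSegment(rep(1, 25000), fp, sr)
  expect_lt(max(abs(frc$frames - frc$frames[, 1])), 1e-12)
})

test_that("mel filterbank is non-negative, ordered and textbook-exact", {
  fb <- melFilterbank(32, 100, 8000, 1024, 16000)
  expect_true(all(fb >= 0))
  expect_true(all(diff(attr(fb, "centersHz")) > 0))
  ref <- referenceFilterbank(32, 100, 8000, 1024, 16000)
  expect_lt(max(abs(fb - ref)), 1e-6)

  # default analysis band at the default FFT size
  fb2 <- melFilterbank(128, 100, 60000, 8192, 250000)
  expect_true(all(rowSums(fb2) > 0))
  expect_error(melFilterbank(128, 100, 60000, 256, 250000), "nFft")
  expect_error(melFilterbank(32, 100, 10000, 1024, 16000), "Nyquist")
})

test_that("silent frames give the closed-form constant cepstrum", {
  sr <- 250000
  cfg <- cepstralConfig()
  m <- computeMFCC(matrix(0, 5000, 3), cfg, sr)
  c0 <- sqrt(cfg@nMelFilters) * log(cfg@logFloor)
  expect_equal(m[, 1], rep(c0, 3), tolerance = 1e-9)
  expect_lt(max(abs(m[, -1])), 1e-9)
})

test_that("a pure tone at a filter centre maximizes that filter's energy", {
  sr <- 16000
  nFft <- 1024L
  fb <- melFilterbank(24, 100, 7000, nFft, sr)
  centers <- attr(fb, "centersHz")
  k <- 12L
  fc <- round(centers[k] / (sr / nFft)) * (sr / nFft)  # snap to a bin
  tone <- sin(2 * pi * fc * seq_len(nFft) / sr)
  P <- Mod(stats::fft(tone))[seq_len(nFft / 2 + 1)]^2
  E <- fb %*% P
  expect_equal(which.max(E), k)
})

test_that("MFCC computation matches the brute-force oracle", {
  sr <- 250000
  cfg <- cepstralConfig()
  set.seed(8)
  fr <- frameSegment(rnorm(12000), frameParams(), sr)
  m <- computeMFCC(fr$frames, cfg, sr)
  for (j in c(1L, 15L, 29L)) {
    ref <- referenceMFCC(fr$frames[, j], cfg, sr)
    expect_lt(max(abs(m[j, ] - ref)), 1e-5)
  }
})

test_that("amplitude scaling moves only the 0th coefficient", {
  sr <- 250000
  cfg <- cepstralConfig()
  set.seed(9)
  fr <- frameSegment(rnorm(6000, 0, 0.3), frameParams(), sr)
  m1 <- computeMFCC(fr$frames, cfg, sr)
  m2 <- computeMFCC(4 * fr$frames, cfg, sr)
  expect_lt(max(abs(m1[, -1] - m2[, -1])), 1e-8)
  # g^2 on mel energies -> + 2 log g spread over the constant DCT basis
  expect_equal(m2[, 1] - m1[, 1],
               rep(sqrt(cfg@nMelFilters) * 2 * log(4), nrow(m1)),
               tolerance = 1e-8)
})

test_that("cepstral mean subtraction centres each channel independently", {
  set.seed(10)
  f1 <- matrix(rnorm(40), 10, 4)
  f2 <- matrix(rnorm(40), 10, 4)
  bias1 <- c(3, -1, 2, 0.5)
  bias2 <- c(-2, 4, 1, -3)
  fs <- new("FeatureSet",
            features = list(sweep(f1, 2, -bias1), sweep(f2, 2, -bias2)),
            meta = data.frame(voc_id = c("a", "b"), channel = c(1L, 2L)))
  out <- cepstralMeanSubtract(fs)
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(vocFeatures(out)[[i]]))), 1e-10)
  }
  # the additive bias cancels exactly: centred originals are recovered
  expect_equal(vocFeatures(out)[[1]], sweep(f1, 2, colMeans(f1)),
               tolerance = 1e-12)
})

test_that("pooling concatenates segment frames in temporal order", {
  a <- matrix(1, 10, 4); b <- matrix(2, 15, 4)
  pooled <- poolVocalization(list(a, b), list(1:10 / 100, 11:25 / 100))
  expect_equal(nrow(pooled), 25L)
  expect_true(all(diff(attr(pooled, "frameTimes")) > 0))
  expect_identical(poolVocalization(list(a)), a)
  expect_error(poolVocalization(list(matrix(0, 0, 4))), "zero usable")
})

test_that("the feature cache round-trips bit-exactly", {
  fix <- smallWaveFixture()
  dir <- tempfile("cache")
  writeFeatureCache(fix$fs, dir)
  back <- readFeatureCache(dir)
  plain <- lapply(vocFeatures(fix$fs), function(m)
    matrix(as.numeric(m), nrow(m)))
  expect_identical(vocFeatures(back), plain)
  expect_equal(vocMeta(back)$voc_id, vocMeta(fix$fs)$voc_id)
})

test_that("every vector of the default pipeline has 64 coefficients", {
  fix <- smallWaveFixture()
  expect_equal(featureDim(fix$fs), 64L)
  expect_true(all(vapply(vocFeatures(fix$fs), ncol, 0L) == 64L))
  expect_true(all(vapply(vocFeatures(fix$fs),
                         function(m) all(is.finite(m)), TRUE)))
})
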