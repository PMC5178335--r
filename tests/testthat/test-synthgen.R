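ep <- list(f0 = 400, envCenter = 9000, envWidth = 4000)
cp0 <- list(formantShift = 0)
ap0 <- list(tilt = 0)
op0 <- list(gainDb = 0, bwFactor = 1)

test_that("syllable synthesis honours duration, effects and aliasing limits", {
  w <- generateSyllable(ep, cp0, ap0, op0, duration = 0.05,
                        sampleRate = 250000, rngSeed = 3)
  expect_length(w, 12500)
  expect_equal(w[1], 0)          # enveloped to zero at the ends
  expect_equal(w[length(w)], 0, tolerance = 1e-12)

  # zero effect sizes: different context labels give identical waveforms
  w2 <- generateSyllable(ep, list(formantShift = 0 * 2), ap0, op0,
                         duration = 0.05, sampleRate = 250000, rngSeed = 3)
  expect_identical(w, w2)

  expect_error(generateSyllable(ep, cp0, ap0, op0, duration = -0.01,
                                sampleRate = 250000), "duration")
  expect_error(generateSyllable(ep, cp0, ap0, op0, duration = 0.02,
                                sampleRate = 5000), "aliasing")
})

test_that("synthesized spectrum peaks at the harmonic frequencies", {
  sr <- 250000
  w <- generateSyllable(list(f0 = 400, envCenter = 1600, envWidth = 2000),
                        cp0, ap0, op0, duration = 0.1, sampleRate = sr,
                        rngSeed = 9, nHarmonics = 8L)
  n <- length(w)
  spec <- Mod(stats::fft(w))[seq_len(n %/% 2)]
  binHz <- sr / n
  # the per-syllable pitch jitter is a few percent: pick the local peak
  # within +/-6% of each nominal harmonic, then require all eight peaks
  # to be consistent multiples of one fundamental
  peakHz <- vapply(1:8, function(k) {
    lo <- floor(k * 400 * 0.94 / binHz) + 1
    hi <- ceiling(k * 400 * 1.06 / binHz) + 1
    (lo + which.max(spec[lo:hi]) - 2) * binHz
  }, 0)
  f0hat <- stats::median(peakHz / 1:8)
  expect_lt(abs(f0hat / 400 - 1), 0.06)
  for (k in 1:8)
    expect_lt(abs(peakHz[k] - k * f0hat), 2 * binHz + 0.5 * k)
})

test_that("dataset generation yields the full design grid, deterministically", {
  spec <- synthSpec(seed = 21L, nEmitters = 2L, callsPerCell = 2L,
                    contexts = c("feeding_aggr", "perch_aggr"),
                    syllableCountRange = c(1L, 2L))
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  ds1 <- generateDataset(spec, d1)
  ds2 <- generateDataset(spec, d2)
  ann <- annotations(ds1)
  expect_equal(nrow(ann), 2 * 2 * 2)   # emitters x contexts x callsPerCell
  expect_setequal(unique(ann$context), spec@contexts)
  # identical spec -> identical annotation tables and identical WAV bytes
  a2 <- annotations(ds2)
  expect_identical(ann[setdiff(names(ann), "wav_path")],
                   a2[setdiff(names(a2), "wav_path")])
  for (i in seq_len(nrow(ann))) {
    b1 <- readBin(ann$wav_path[i], "raw", file.size(ann$wav_path[i]))
    b2 <- readBin(a2$wav_path[i], "raw", file.size(a2$wav_path[i]))
    expect_identical(b1, b2)
  }
  # every annotation row points inside its recording
  lens <- vapply(ann$wav_path, function(p) nrow(readWav(p)$samples), 0)
  expect_true(all(ann$t_end_s <= lens / spec@sampleRate + 1e-9))
  # planted syllable counts respect the configured range
  counts <- table(ds1@syllables$voc_id)
  expect_true(all(counts >= 1 & counts <= 2))
})

test_that("generator rejects invalid designs", {
  expect_error(synthSpec(contexts = character(0)), "contexts")
  expect_error(synthSpec(callsPerCell = 0), "callsPerCell")
  expect_error(synthSpec(syllableCountRange = c(0L, 25L)), "syllableCountRange")
})

test_that("feature streams reproduce the requested shape and truth", {
  m <- gmmParams(1, matrix(c(2, -1), 1, 2), matrix(1e-12, 1, 2))
  fs <- generateFeatureStreams(list(a = m), rep("a", 3), c(5L, 7L, 9L),
                               seed = 4)
  expect_equal(vapply(vocFeatures(fs), nrow, 0L), c(5L, 7L, 9L))
  # zero-covariance limit: every vector equals the mean
  expect_true(all(vapply(vocFeatures(fs), function(x)
    max(abs(sweep(x, 2, c(2, -1)))) < 1e-4, TRUE)))

  m2 <- gmmParams(1, matrix(0, 1, 3), matrix(1, 1, 3))
  expect_error(generateFeatureStreams(list(a = m, b = m2), c("a", "b"),
                                      c(5L, 5L)), "dimensions")
  # seeded determinism
  f1 <- generateFeatureStreams(list(a = m), "a", 10L, seed = 9)
  f2 <- generateFeatureStreams(list(a = m), "a", 10L, seed = 9)
  expect_identical(vocFeatures(f1), vocFeatures(f2))
})

test_that("spec serialization round-trips", {
  spec <- smallWaveSpec()
  f <- tempfile(fileext = ".json")
  writeSynthSpec(spec, f)
  spec2 <- readSynthSpec(f)
  for (s in slotNames(spec))
    expect_equal(slot(spec, s), slot(spec2, s), info = s)
})

test_that("downstream context accuracy increases with the planted formant shift", {
  shifts <- c(0, 1000, 3000)
  fix <- smallWaveFixture()   # ubm reused across effect sizes
  bas <- vapply(shifts, function(sh) {
    spec <- smallWaveSpec(seed = 31L, formantShiftPerContext = sh)
    ds <- generateDataset(spec, tempfile())
    fs <- featurizeDataset(ds)
    loo <- leaveOneOutCV(fs, vocMeta(fs)$context, fix$ubm)
    balancedAccuracy(confusionMatrix(trueLabels(loo), predictedLabels(loo)))
  }, 0)
  # monotone within Monte-Carlo tolerance on a 3-point grid
  expect_gt(bas[3], bas[1] - 0.05)
  expect_gt(bas[3], bas[2] - 0.15)
  # strong effect clearly above the 1/3 chance level
  expect_gt(bas[3], chanceLevel(3) + 0.15)
})
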