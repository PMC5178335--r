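makeBurst <- function(len, sr, rampMs = 1) {
  b <- sin(2 * pi * 2000 * seq_len(len) / sr)
  nr <- round(rampMs / 1000 * sr)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
  b[seq_len(nr)] <- b[seq_len(nr)] * ramp
  b[len + 1 - seq_len(nr)] <- b[len + 1 - seq_len(nr)] * ramp
  b
}

test_that("silence yields no segments and a lone burst yields exactly one", {
  sr <- 250000
  expect_length(detectVoicedSegments(numeric(5000), sr), 0L)

  set.seed(4)
  burst <- makeBurst(12500, sr)
  x <- c(numeric(125000), burst, numeric(125000)) +
    rnorm(262500, 0, 1e-4)
  seg <- detectVoicedSegments(x, sr)
  expect_length(seg, 1L)
  hop <- 0.001 * sr
  expect_lt(abs(IRanges::start(seg) - 125001), 2 * hop)
  expect_lt(abs(IRanges::end(seg) - 137500), 2 * hop)
})

test_that("gaps below mergeGap are bridged and above it split", {
  sr <- 250000
  set.seed(5)
  burst <- makeBurst(12500, sr)
  pad <- numeric(50000)
  mk <- function(gapS) c(pad, burst, numeric(round(gapS * sr)), burst, pad) +
    rnorm(2 * 12500 + round(gapS * sr) + 100000, 0, 1e-4)
  expect_length(detectVoicedSegments(mk(0.004), sr), 1L)  # < mergeGap
  expect_length(detectVoicedSegments(mk(0.020), sr), 2L)  # > mergeGap
})

test_that("relative-threshold boundaries are invariant to amplitude scaling", {
  sr <- 250000
  set.seed(6)
  x <- c(numeric(60000), makeBurst(10000, sr), numeric(60000)) +
    rnorm(130000, 0, 1e-4)
  s1 <- detectVoicedSegments(x, sr)
  for (g in c(0.01, 3.7, 120)) {
    s2 <- detectVoicedSegments(g * x, sr)
    expect_identical(IRanges::start(s2), IRanges::start(s1))
    expect_identical(IRanges::end(s2), IRanges::end(s1))
  }
})

test_that("re-running the detector on a detected segment returns its extent", {
  sr <- 250000
  set.seed(7)
  x <- c(numeric(60000), makeBurst(10000, sr), numeric(60000)) +
    rnorm(130000, 0, 1e-4)
  seg <- detectVoicedSegments(x, sr)
  inner <- x[IRanges::start(seg):IRanges::end(seg)]
  # absolute mode: the relative noise floor is meaningless inside a
  # segment that is voiced throughout
  cfg <- segmenterConfig(thresholdMode = "absolute", thresholdValue = -45)
  seg2 <- detectVoicedSegments(inner, sr, cfg)
  expect_length(seg2, 1L)
  expect_lt(IRanges::start(seg2) - 1, 2 * 0.001 * sr)
  expect_lt(length(inner) - IRanges::end(seg2), 2 * 0.001 * sr)
})

test_that("planted syllables are recovered with high recall at default SNR", {
  fix <- smallWaveFixture()
  tr <- fix$ds@syllables
  segs <- fix$segs
  hit <- 0L
  for (i in seq_len(nrow(tr))) {
    s <- segs[segs$voc_id == tr$voc_id[i], , drop = FALSE]
    ov <- pmin(s$end_sample, tr$end_sample[i]) -
      pmax(s$start_sample, tr$start_sample[i])
    if (any(ov > 0.8 * (tr$end_sample[i] - tr$start_sample[i]))) hit <- hit + 1L
  }
  expect_gte(hit / nrow(tr), 0.95)
})

test_that("background syllable sampling is uniform, seeded and bounded", {
  fix <- smallWaveFixture()
  pool <- fix$segs
  all1 <- sampleBackgroundSyllables(pool, nrow(pool), seed = 3)
  expect_equal(nrow(all1), nrow(pool))    # n = pool size -> whole pool
  expect_setequal(paste(all1$voc_id, all1$seg_idx),
                  paste(pool$voc_id, pool$seg_idx))
  s1 <- sampleBackgroundSyllables(pool, 10, seed = 42)
  s2 <- sampleBackgroundSyllables(pool, 10, seed = 42)
  expect_identical(s1, s2)
  s3 <- sampleBackgroundSyllables(pool, 10, seed = 43)
  expect_false(identical(s1, s3))
  expect_error(sampleBackgroundSyllables(pool, nrow(pool) + 1), "pool")
})
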