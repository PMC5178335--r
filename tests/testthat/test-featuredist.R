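mkFeatureSet <- function(mats, labels) {
  new("FeatureSet", features = mats,
      meta = data.frame(voc_id = sprintf("v%03d", seq_along(mats)),
                        channel = 1L, class = labels,
                        stringsAsFactors = FALSE))
}

test_that("class histograms are max-normalized with exact raw counts", {
  set.seed(41)
  mats <- c(replicate(5, matrix(rnorm(40), 10, 4), simplify = FALSE),
            replicate(5, matrix(rnorm(40, 2), 10, 4), simplify = FALSE))
  labels <- rep(c("a", "b"), each = 5)
  fs <- mkFeatureSet(mats, labels)
  h <- classHistogram2D(fs, labels, pair = c(1L, 3L), bins = 20L,
                        limits = list(x = c(-5, 7), y = c(-5, 7)))
  for (cl in c("a", "b")) {
    expect_equal(max(h$histograms[[cl]]), 1)
    expect_equal(sum(h$counts[[cl]]), 50)   # all frames fall in range
  }
  # single-frame class: exactly one bin at 1
  fs1 <- mkFeatureSet(list(matrix(c(0, 0, 0, 0), 1, 4)), "solo")
  h1 <- classHistogram2D(fs1, "solo", pair = c(1L, 2L), bins = 10L,
                         limits = list(x = c(-1, 1), y = c(-1, 1)))
  expect_equal(sum(h1$histograms$solo == 1), 1L)
  expect_equal(sum(h1$histograms$solo), 1)
})

test_that("isolines trace the requested level of the normalized histogram", {
  set.seed(42)
  fs <- mkFeatureSet(list(matrix(rnorm(2000), 500, 4)), "a")
  h <- classHistogram2D(fs, "a", pair = c(1L, 2L), bins = 25L)
  iso <- histogramIsolines(h$histograms$a, h$xBreaks, h$yBreaks, 0.5)
  expect_true(length(iso) >= 1L)
  expect_true(all(vapply(iso, function(p) p$level == 0.5, TRUE)))
  expect_error(histogramIsolines(h$histograms$a, h$xBreaks, h$yBreaks, 1.2),
               "level")
})

test_that("region attribution uses any-frame semantics and sums to one", {
  # class "hi" has an exclusive extreme region around (10, 10) in one
  # frame of each vocalization; all other frames overlap class "lo"
  set.seed(43)
  lo <- replicate(6, matrix(rnorm(40), 10, 4), simplify = FALSE)
  hi <- replicate(3, {
    m <- matrix(rnorm(40), 10, 4)
    m[1, c(1, 2)] <- c(10, 10)
    m
  }, simplify = FALSE)
  fs <- mkFeatureSet(c(lo, hi), rep(c("lo", "hi"), c(6, 3)))
  labels <- rep(c("lo", "hi"), c(6, 3))

  planted <- regionAttribution(fs, labels, pair = c(1L, 2L),
                               xlim = c(8, 12), ylim = c(8, 12))
  expect_equal(unname(planted["hi"]), 1)
  expect_equal(sum(planted), 1, tolerance = 1e-12)

  # whole plane: fractions equal the class shares of the pool
  whole <- regionAttribution(fs, labels, pair = c(1L, 2L),
                             xlim = c(-100, 100), ylim = c(-100, 100))
  expect_equal(unname(whole["lo"]), 6 / 9, tolerance = 1e-12)
  expect_equal(sum(whole), 1, tolerance = 1e-12)

  # duplicating non-hitting frames changes nothing
  fs2 <- fs
  fs2@features[[1]] <- rbind(fs2@features[[1]], fs2@features[[1]])
  planted2 <- regionAttribution(fs2, labels, pair = c(1L, 2L),
                                xlim = c(8, 12), ylim = c(8, 12))
  expect_equal(planted2, planted)

  expect_error(regionAttribution(fs, labels, pair = c(1L, 2L),
                                 xlim = c(50, 60), ylim = c(50, 60)),
               "zero vocalizations")
  expect_error(regionAttribution(fs, labels, pair = c(1L, 1L),
                                 xlim = c(0, 1), ylim = c(0, 1)),
               "distinct")
})
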