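streamTask <- function(classes, perClass, framesPer = 15L, d = 4L,
                       sep = 5, seed = 1L) {
  models <- separatedModels(classes, d = d, sep = sep, seed = seed)
  labels <- rep(classes, each = perClass)
  fs <- generateFeatureStreams(models, labels,
                               rep(framesPer, length(labels)),
                               seed = seed + 1L)
  ubmX <- batvoc:::withSeed(seed + 2L, do.call(rbind,
    lapply(models, function(m) sampleGmm(m, 200L))))
  ## a broad low-resolution UBM: with means-only MAP adaptation the
  ## class signal lives in shared components pulled class-specifically,
  ## so the background model must not dedicate components to classes
  ubm <- fitGmmEM(ubmX, K = 1L, seed = seed + 3L)
  list(fs = fs, labels = labels, ubm = ubm, models = models)
}

test_that("task building applies exclusions, filters and size thresholds", {
  meta <- data.frame(
    voc_id = sprintf("v%02d", 1:60),
    channel = 1L,
    emitter = rep(c("E1", "E2"), each = 30),
    addressee = c(rep("A1", 20), rep("A2", 19), rep("A3", 21)),
    context = rep(c("feeding_aggr", "mating_aggr", "perch_aggr"), 20),
    stringsAsFactors = FALSE)
  fs <- new("FeatureSet",
            features = replicate(60, matrix(rnorm(8), 2, 4),
                                 simplify = FALSE),
            meta = meta)

  # a 19-member class is dropped at threshold 20
  task <- buildTask(fs, taskSpec("addressee", minClassSize = 20L))
  expect_setequal(levels(task$labels), c("A1", "A3"))
  expect_equal(task$report$dropped, "A2")

  # all classes below threshold -> structured abort
  expect_error(buildTask(fs, taskSpec("addressee", minClassSize = 25L)),
               class = "batvoc_task_abort")

  # population filter restricts rows
  t2 <- buildTask(fs, taskSpec("addressee", minClassSize = 1L,
                               populationFilter = function(a)
                                 a$emitter == "E1"))
  expect_true(all(vocMeta(t2$features)$emitter == "E1"))

  # excluded labels are removed before anything else
  t3 <- buildTask(fs, taskSpec("context", minClassSize = 1L,
                               excludedLabels = "mating_aggr"))
  expect_false("mating_aggr" %in% levels(t3$labels))

  # composite axis
  t4 <- buildTask(fs, taskSpec("context_x_emitter", minClassSize = 1L))
  expect_equal(nlevels(t4$labels), 6L)
})

test_that("balanced accuracy is the mean of per-class recall", {
  cm <- new("ConfusionMatrix", labels = c("a", "b"),
            counts = matrix(c(8, 4, 2, 6), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(balancedAccuracy(cm), (0.8 + 0.6) / 2)
  expect_equal(rowSums(rowNormalized(cm)), c(a = 1, b = 1),
               tolerance = 1e-12)
  expect_equal(classSizes(cm), c(a = 10, b = 10))

  truth <- factor(rep(c("x", "y"), c(30, 3)))
  ident <- confusionMatrix(truth, truth)
  expect_equal(balancedAccuracy(ident), 1)

  # imbalance invariance: duplicating one class leaves the expected BA
  # of a label-independent classifier unchanged
  pred <- factor(rep("x", 33), levels = c("x", "y"))
  ba1 <- balancedAccuracy(confusionMatrix(truth, pred))
  truth2 <- factor(rep(c("x", "y"), c(300, 3)))
  pred2 <- factor(rep("x", 303), levels = c("x", "y"))
  expect_equal(balancedAccuracy(confusionMatrix(truth2, pred2)), ba1)
})

test_that("statistic-subtraction LOO equals naive refitting", {
  st <- streamTask(c("a", "b", "c"), perClass = 8L, sep = 2, seed = 21L)
  fast <- leaveOneOutCV(st$fs, st$labels, st$ubm, method = "downdate")
  slow <- leaveOneOutCV(st$fs, st$labels, st$ubm, method = "refit")
  expect_identical(predictedLabels(fast), predictedLabels(slow))
  expect_lt(max(abs(scoreMatrix(fast) - scoreMatrix(slow))), 1e-8)
})

test_that("LOO predictions are invariant to input order", {
  st <- streamTask(c("a", "b"), perClass = 6L, sep = 3, seed = 22L)
  loo <- leaveOneOutCV(st$fs, st$labels, st$ubm)
  set.seed(23)
  o <- sample(length(st$labels))
  fs2 <- new("FeatureSet", features = vocFeatures(st$fs)[o],
             meta = vocMeta(st$fs)[o, ])
  loo2 <- leaveOneOutCV(fs2, st$labels[o], st$ubm)
  expect_identical(as.character(predictedLabels(loo2)),
                   as.character(predictedLabels(loo))[o])
})

test_that("two singleton classes resolve deterministically via the tie rule", {
  models <- separatedModels(c("a", "b"), d = 3, sep = 4, seed = 24L)
  fs <- generateFeatureStreams(models, c("a", "b"), c(10L, 10L), seed = 25L)
  ubmX <- batvoc:::withSeed(26L, rbind(sampleGmm(models$a, 150),
                                       sampleGmm(models$b, 150)))
  ubm <- fitGmmEM(ubmX, K = 4, seed = 27L)
  l1 <- leaveOneOutCV(fs, c("a", "b"), ubm)
  l2 <- leaveOneOutCV(fs, c("a", "b"), ubm)
  expect_identical(predictedLabels(l1), predictedLabels(l2))
  # each held-out vocalization's own class model collapses to the UBM,
  # so its own-class score is exactly zero
  expect_equal(unname(scoreMatrix(l1)[1, "a"]), 0, tolerance = 1e-12)
  expect_equal(unname(scoreMatrix(l1)[2, "b"]), 0, tolerance = 1e-12)
})

test_that("well-separated classes are classified nearly perfectly", {
  st <- streamTask(c("a", "b", "c"), perClass = 10L, sep = 6, seed = 28L)
  loo <- leaveOneOutCV(st$fs, st$labels, st$ubm)
  acc <- mean(trueLabels(loo) == predictedLabels(loo))
  expect_gte(acc, 0.95)
})

test_that("the permutation test is seeded, bounded and correctly scored", {
  st <- streamTask(c("a", "b"), perClass = 8L, sep = 4, seed = 29L)
  p1 <- permutationTest(st$fs, st$labels, st$ubm, nPerm = 15L, seed = 5L)
  p2 <- permutationTest(st$fs, st$labels, st$ubm, nPerm = 15L, seed = 5L)
  expect_identical(p1@nullBAs, p2@nullBAs)
  expect_equal(p1@pValue,
               (1 + sum(p1@nullBAs >= p1@observedBA)) / 16)
  expect_gt(p1@pValue, 0)
  # strong separation: observed beats every null
  expect_equal(p1@pValue, 1 / 16)
})

test_that("chance level is one over the class count", {
  expect_equal(chanceLevel(2), 0.5)
  expect_equal(chanceLevel(4), 0.25)
  expect_error(chanceLevel(0), "class")
})

test_that("unvoiced spans never overlap voiced segments", {
  fix <- smallWaveFixture()
  ann <- annotations(fix$ds)
  for (i in seq_len(min(nrow(ann), 6L))) {
    segs <- fix$segs[fix$segs$voc_id == ann$voc_id[i], , drop = FALSE]
    len <- nrow(readWav(ann$wav_path[i])$samples)
    voiced <- IRanges::IRanges(segs$start_sample, segs$end_sample)
    unvoiced <- IRanges::gaps(voiced, start = 1L, end = len)
    expect_equal(sum(IRanges::countOverlaps(unvoiced, voiced)), 0L)
  }
})

test_that("the non-voiced control runs and stays near chance", {
  fix <- smallWaveFixture()
  res <- nonvoicedControl(fix$ds, fix$segs,
                          taskSpec("context", minClassSize = 2L),
                          fix$ubm, nPerm = 30L, seed = 9L)
  expect_false(is.null(res))
  # context-independent noise: observed BA inside the central 95% of
  # its own permutation null
  lo <- stats::quantile(res$permutation@nullBAs, 0.025)
  hi <- stats::quantile(res$permutation@nullBAs, 0.975)
  expect_gte(res$ba, lo - 1e-9)
  expect_lte(res$ba, hi + 1e-9)
})
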