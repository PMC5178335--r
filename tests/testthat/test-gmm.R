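test_that("single-component EM recovers the closed-form Gaussian MLE", {
  set.seed(11)
  x <- matrix(rnorm(500, 2, 3), 100, 5)
  m <- fitGmmEM(x, K = 1, seed = 1)
  expect_equal(mixtureWeights(m), 1)
  expect_equal(mixtureMeans(m)[1, ], colMeans(x), tolerance = 1e-10)
  mle <- colMeans(x^2) - colMeans(x)^2
  expect_equal(mixtureVariances(m)[1, ], mle, tolerance = 1e-8)
})

test_that("EM recovers well-separated mixture components", {
  truth <- rbind(rep(0, 3), rep(8, 3))
  gen <- gmmParams(c(0.5, 0.5), truth, matrix(1, 2, 3))
  set.seed(12)
  x <- sampleGmm(gen, 2000)
  m <- fitGmmEM(x, K = 2, seed = 7)
  est <- mixtureMeans(m)
  # each true mean recovered within 3 standard errors (per coordinate,
  # n ~ 1000 draws per component)
  for (k in 1:2) {
    dists <- apply(est, 1, function(r) max(abs(r - truth[k, ])))
    expect_lt(min(dists), 3 / sqrt(1000))
  }
})

test_that("sufficient statistics are additive with counts summing to frames", {
  fix <- list(ubm = randomStreamModel(d = 4, K = 3, seed = 3))
  set.seed(13)
  a <- matrix(rnorm(80), 20, 4)
  b <- matrix(rnorm(48), 12, 4)
  sa <- accumulateStats(fix$ubm, a)
  sb <- accumulateStats(fix$ubm, b)
  expect_equal(sum(sa@n), 20, tolerance = 1e-10)
  sab <- accumulateStats(fix$ubm, rbind(a, b))
  s2 <- sa + sb
  expect_equal(sab@n, s2@n, tolerance = 1e-10)
  expect_equal(sab@first, s2@first, tolerance = 1e-10)
  expect_equal(sab@second, s2@second, tolerance = 1e-10)
  expect_error(accumulateStats(fix$ubm, matrix(0, 0, 4)), "empty")
})

test_that("a frame at a well-separated component's mean is assigned to it", {
  ubm <- gmmParams(c(0.5, 0.5), rbind(rep(-5, 4), rep(5, 4)),
                   matrix(1, 2, 4))
  st <- accumulateStats(ubm, mixtureMeans(ubm)[2, , drop = FALSE])
  expect_gt(st@n[2], 0.999)
  expect_lt(st@n[1], 0.001)
})

test_that("MAP adaptation obeys its limits and the K=1 closed form", {
  ubm <- randomStreamModel(d = 3, K = 4, seed = 5)
  set.seed(14)
  x <- matrix(rnorm(120, 1), 40, 3)
  st <- accumulateStats(ubm, x)

  # r -> Inf reproduces the UBM exactly
  inf <- mapAdapt(ubm, st, mapConfig(relevanceFactor = Inf))
  expect_identical(mixtureMeans(inf), mixtureMeans(ubm))

  # empty statistics leave the UBM untouched
  none <- mapAdapt(ubm, batvoc:::emptyStats(ubm), mapConfig(16))
  expect_equal(mixtureMeans(none), mixtureMeans(ubm))

  # r = 0: per-component ML mean wherever n_k > 0
  ml <- mapAdapt(ubm, st, mapConfig(relevanceFactor = 0))
  pos <- st@n > 1e-6
  expect_equal(mixtureMeans(ml)[pos, ],
               (st@first / st@n)[pos, ], tolerance = 1e-10)

  # K = 1, r = 16, n = 48: hand-computed convex combination
  ubm1 <- gmmParams(1, matrix(c(1, -2, 0.5), 1, 3), matrix(2, 1, 3))
  set.seed(15)
  y <- matrix(rnorm(144, 3), 48, 3)
  st1 <- accumulateStats(ubm1, y)
  ad <- mapAdapt(ubm1, st1, mapConfig(16))
  hand <- numeric(3)
  for (j in 1:3) {
    xbar <- sum(y[, j]) / 48
    hand[j] <- (48 * xbar + 16 * mixtureMeans(ubm1)[1, j]) / (48 + 16)
  }
  expect_equal(mixtureMeans(ad)[1, ], hand, tolerance = 1e-12)
})

test_that("average log-likelihood matches the naive density oracle", {
  model <- randomStreamModel(d = 4, K = 3, seed = 6)
  set.seed(16)
  x <- matrix(rnorm(60), 15, 4)
  # naive per-frame, per-component summation
  w <- mixtureWeights(model); mu <- mixtureMeans(model)
  v <- mixtureVariances(model)
  naive <- mean(vapply(seq_len(nrow(x)), function(t) {
    s <- 0
    for (k in seq_along(w)) {
      dens <- 1
      for (j in 1:4) dens <- dens * stats::dnorm(x[t, j], mu[k, j],
                                                 sqrt(v[k, j]))
      s <- s + w[k] * dens
    }
    log(s)
  }, 0))
  expect_equal(avgLogLik(model, x), naive, tolerance = 1e-8)

  # value at the mode of a unit-variance single Gaussian
  d <- 64L
  m1 <- gmmParams(1, matrix(0, 1, d), matrix(1, 1, d))
  expect_equal(avgLogLik(m1, matrix(0, 1, d)), -(d / 2) * log(2 * pi),
               tolerance = 1e-12)

  # per-frame mean: duplication leaves the value unchanged
  expect_equal(avgLogLik(model, rbind(x, x)), avgLogLik(model, x),
               tolerance = 1e-12)
  expect_error(avgLogLik(model, matrix(0, 3, 5)), "dimension")
})

test_that("likelihood-ratio scores vanish for the UBM and ignore duration", {
  ubm <- randomStreamModel(d = 3, K = 2, seed = 7)
  set.seed(17)
  x <- matrix(rnorm(30), 10, 3)
  sc <- scoreVocalization(list(same = ubm), ubm, x)
  expect_identical(unname(sc), 0)
  other <- randomStreamModel(d = 3, K = 2, seed = 8)
  s1 <- scoreVocalization(list(a = other), ubm, x)
  s2 <- scoreVocalization(list(a = other), ubm, rbind(x, x))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("argmax classification breaks exact ties lexicographically", {
  expect_equal(classifyScores(c(A = 0.2, B = -0.1)), "A")
  expect_equal(classifyScores(c(B = 0, A = 0)), "A")
  expect_equal(classifyScores(c(Z = 1, M = 1, A = 0.5)), "M")
  # permuting entry order never changes the winner
  s <- c(a = 0.3, b = 0.7, c = -0.2)
  for (p in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(classifyScores(s[p]), "b")
  }
})

test_that("model parameters survive a JSON round-trip", {
  m <- randomStreamModel(d = 5, K = 3, seed = 9)
  f <- tempfile(fileext = ".json")
  writeGmm(m, f, provenance = list(role = "ubm"))
  m2 <- readGmm(f)
  expect_equal(mixtureWeights(m2), mixtureWeights(m), tolerance = 1e-14)
  expect_equal(mixtureMeans(m2), mixtureMeans(m), tolerance = 1e-14)
  expect_equal(mixtureVariances(m2), mixtureVariances(m), tolerance = 1e-14)
})
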