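# Monte-Carlo sampling, predictive mean, probability variation and
# normalization, each against independent loop-based oracles.

test_that("MC sampling is seeded and degenerates without dropout", {
  det <- buildUnet(unetConfig(inChannels = 2, depth = 2, baseFilters = 4),
                   seed = 1)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  expect_warning(st <- mcSample(det, x, T = 3, seed = 1), "identical")
  expect_identical(st@samples[, , , 1], st@samples[, , , 2])
  expect_identical(st@samples[, , , 1], st@samples[, , , 3])

  bay <- buildUnet(bayesianUnetConfig(inChannels = 2, depth = 2,
                                      baseFilters = 4), seed = 1)
  a <- mcSample(bay, x, T = 4, seed = 9)
  b <- mcSample(bay, x, T = 4, seed = 9)
  expect_identical(a@samples, b@samples)
  expect_false(identical(a@samples[, , , 1], a@samples[, , , 2]))
  expect_error(mcSample(bay, x, T = 0), "T must be")
})

test_that("the per-pixel sample mean stabilizes as T grows", {
  bay <- buildUnet(bayesianUnetConfig(inChannels = 2, depth = 2,
                                      baseFilters = 4), seed = 2)
  s <- generateSample(smallPhantomConfig(), seed = 3)
  st <- mcSample(bay, gaussianNormalize(imageArray(s)), T = 30, seed = 5)
  fg <- st@samples[, , 2, ]
  half <- apply(fg[, , 1:15], c(1, 2), mean)
  full <- apply(fg, c(1, 2), mean)
  sdMap <- apply(fg, c(1, 2), sd)
  # split-half Monte-Carlo bound: the half mean deviates from the full mean
  # by no more than a few standard errors almost everywhere
  bound <- 5 * pmax(sdMap, 1e-3) / sqrt(15)
  expect_gt(mean(abs(half - full) <= bound), 0.99)
})

test_that("mean probability equals the naive summation oracle", {
  s <- array(c(0.2, 0.8, 0.4, 0.6), dim = c(1, 1, 2, 2))
  st <- new("ProbabilityStack", samples = s, sourceModelId = "toy")
  expect_equal(as.vector(probabilities(meanProbability(st))), c(0.3, 0.7))

  one <- randomStack(4, 4, 2, T = 1, seed = 2)
  rep5 <- new("ProbabilityStack",
              samples = array(rep(one@samples, 5), dim = c(4, 4, 2, 5)),
              sourceModelId = "toy")
  expect_equal(probabilities(meanProbability(rep5)),
               array(one@samples, dim = c(4, 4, 2)))

  st7 <- randomStack(5, 6, 2, T = 7, seed = 3)
  oracle <- array(0, dim = c(5, 6, 2))
  for (t in 1:7) oracle <- oracle + st7@samples[, , , t]
  expect_equal(probabilities(meanProbability(st7)), oracle / 7,
               tolerance = 1e-12)
})

test_that("probability variation is the per-pixel population SD", {
  idn <- randomStack(4, 4, 2, T = 1, seed = 4)
  rep4 <- new("ProbabilityStack",
              samples = array(rep(idn@samples, 4), dim = c(4, 4, 2, 4)),
              sourceModelId = "toy")
  expect_true(all(uncertaintyValues(probabilityVariation(rep4)) == 0))

  two <- new("ProbabilityStack",
             samples = array(c(0.6, 0.4, 0.4, 0.6), dim = c(1, 1, 2, 2)),
             sourceModelId = "toy")
  expect_equal(as.vector(uncertaintyValues(probabilityVariation(two))), 0.1)

  st9 <- randomStack(6, 5, 2, T = 9, seed = 6)
  v <- uncertaintyValues(probabilityVariation(st9))
  oracle <- matrix(0, 6, 5)
  for (y in 1:6) for (x in 1:5) {
    p <- st9@samples[y, x, 2, ]
    oracle[y, x] <- sqrt(mean(p^2) - mean(p)^2)  # brute-force variance
  }
  expect_equal(v, oracle, tolerance = 1e-10)
  expect_true(all(v >= 0))

  expect_error(probabilityVariation(st9, classOfInterest = 5), "1..2")
  t1 <- randomStack(3, 3, 2, T = 1, seed = 7)
  expect_warning(z <- probabilityVariation(t1), "zero")
  expect_true(all(uncertaintyValues(z) == 0))
})

test_that("normalization min-max rescales and preserves ranks", {
  raw <- new("UncertaintyMap", values = matrix(c(0, 0.05, 0.1), 1),
             normalized = FALSE, normalizationStats = c(NA_real_, NA_real_))
  nm <- normalizeUncertainty(raw)
  expect_equal(as.vector(uncertaintyValues(nm)), c(0, 0.5, 1))
  expect_equal(normalizationStats(nm), c(0, 0.1))
  expect_true(isNormalized(nm))

  const <- new("UncertaintyMap", values = matrix(0.3, 4, 4),
               normalized = FALSE, normalizationStats = c(NA_real_, NA_real_))
  expect_true(all(uncertaintyValues(normalizeUncertainty(const)) == 0))

  set.seed(8)
  r16 <- new("UncertaintyMap", values = matrix(runif(256), 16, 16),
             normalized = FALSE, normalizationStats = c(NA_real_, NA_real_))
  n16 <- normalizeUncertainty(r16)
  expect_identical(order(uncertaintyValues(n16)), order(r16@values))
  expect_equal(max(uncertaintyValues(n16)), 1)

  expect_error(new("UncertaintyMap", values = matrix(-0.1, 2, 2),
                   normalized = FALSE,
                   normalizationStats = c(NA_real_, NA_real_)),
               ">= 0")
})

test_that("mean probability commutes with pixel restriction", {
  st <- randomStack(8, 7, 2, T = 5, seed = 9)
  m <- probabilities(meanProbability(st))
  crop <- new("ProbabilityStack", samples = st@samples[2:5, 3:6, , ,
                                                       drop = FALSE],
              sourceModelId = "toy")
  expect_equal(probabilities(meanProbability(crop)), m[2:5, 3:6, ],
               tolerance = 1e-12)
})
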