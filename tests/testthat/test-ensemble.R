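# Fusion and ensemble training.

test_that("fusion averages, thresholds and measures member spread", {
  # singleton ensemble: identity fusion, zero uncertainty
  m1 <- randomProbMap(4, 4, 2, seed = 1)
  single <- fuse(list(m1))
  expect_equal(probabilities(fusedProbability(single)), probabilities(m1))
  expect_true(all(uncertaintyValues(epistemicUncertainty(single)) == 0))

  # two members, tie resolves to foreground, U = population SD
  a <- array(c(0.8, 0.2), dim = c(1, 1, 2))
  b <- array(c(0.2, 0.8), dim = c(1, 1, 2))
  pr <- fuse(list(a, b))
  expect_equal(as.vector(probabilities(fusedProbability(pr))), c(0.5, 0.5))
  expect_identical(as.vector(segmentationMap(pr)), 1L)
  expect_equal(as.vector(uncertaintyValues(epistemicUncertainty(pr))), 0.3)
})

test_that("fusion matches loop-based oracles and is permutation-invariant", {
  maps <- lapply(1:5, function(s) randomProbMap(6, 5, 2, seed = s))
  pr <- fuse(maps)
  fusedOracle <- array(0, dim = c(6, 5, 2))
  uOracle <- matrix(0, 6, 5)
  for (y in 1:6) for (x in 1:5) {
    fg <- vapply(maps, function(m) probabilities(m)[y, x, 2], numeric(1))
    bg <- vapply(maps, function(m) probabilities(m)[y, x, 1], numeric(1))
    fusedOracle[y, x, ] <- c(mean(bg), mean(fg))
    uOracle[y, x] <- sqrt(mean(fg^2) - mean(fg)^2)
  }
  expect_equal(probabilities(fusedProbability(pr)), fusedOracle,
               tolerance = 1e-12)
  expect_equal(uncertaintyValues(epistemicUncertainty(pr)), uOracle,
               tolerance = 1e-12)
  # per-pixel class probabilities still sum to 1
  expect_lt(max(abs(apply(probabilities(fusedProbability(pr)),
                          c(1, 2), sum) - 1)), 1e-6)
  # member order is irrelevant
  pr2 <- fuse(maps[c(4, 2, 5, 1, 3)])
  expect_equal(probabilities(fusedProbability(pr2)),
               probabilities(fusedProbability(pr)))
  expect_equal(uncertaintyValues(epistemicUncertainty(pr2)),
               uncertaintyValues(epistemicUncertainty(pr)))

  expect_error(fuse(list(randomProbMap(4, 4), randomProbMap(4, 5))),
               "mismatch")
})

oracleAndData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- generateDataset(smallPhantomConfig(), 8, seed = 31)
      oracle <- trainUncertaintyOracle(
        train, tinyUnetConfig(dropoutRate = 0.5),
        fastTrainConfig(epochs = 3, seed = 41))
      cache <<- list(train = train, oracle = oracle)
    }
    cache
  }
})

test_that("ensemble members carry distinct lambdas and reproduce", {
  od <- oracleAndData()
  ens <- trainEnsemble(od$train, od$oracle, K = 3,
                       unetConfig = tinyUnetConfig(),
                       trainConfig = fastTrainConfig(epochs = 2),
                       masterSeed = 7, T = 6)
  lams <- vapply(members(ens), function(m) fingerprint(m)$lambda, numeric(1))
  expect_equal(lams, lambdas(ens))
  expect_equal(length(unique(lams)), 3)

  test <- generateDataset(smallPhantomConfig(seed = 77), 2, seed = 77)
  ens2 <- trainEnsemble(od$train, od$oracle, K = 3,
                        unetConfig = tinyUnetConfig(),
                        trainConfig = fastTrainConfig(epochs = 2),
                        masterSeed = 7, T = 6)
  d1 <- vapply(test, function(s)
    diceScore(segmentationMap(predictEnsemble(ens, imageArray(s))),
              cleanLabel(s)), numeric(1))
  d2 <- vapply(test, function(s)
    diceScore(segmentationMap(predictEnsemble(ens2, imageArray(s))),
              cleanLabel(s)), numeric(1))
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("K = 1 with lambda 1 degenerates to one fully supervised model", {
  od <- oracleAndData()
  ens <- trainEnsemble(od$train, od$oracle, K = 1, grid = 1.0,
                       unetConfig = tinyUnetConfig(),
                       trainConfig = fastTrainConfig(epochs = 2),
                       masterSeed = 9, T = 6)
  expect_equal(lambdas(ens), 1.0)
  s <- od$train[[1]]
  pr <- predictEnsemble(ens, imageArray(s))
  member <- predictProbabilities(members(ens)[[1]],
                                 gaussianNormalize(imageArray(s)))
  expect_equal(probabilities(fusedProbability(pr)), probabilities(member))
  expect_true(all(uncertaintyValues(epistemicUncertainty(pr)) == 0))
})

test_that("the RWI baseline trains distinct fully supervised members", {
  od <- oracleAndData()
  rwi <- trainRwiBaseline(od$train, K = 3, unetConfig = tinyUnetConfig(),
                          trainConfig = fastTrainConfig(epochs = 2),
                          masterSeed = 5)
  expect_true(all(vapply(members(rwi), function(m) fingerprint(m)$lambda,
                         numeric(1)) == 1.0))
  w1 <- members(rwi)[[1]]@weights[["enc1.c1.w"]]
  w2 <- members(rwi)[[2]]@weights[["enc1.c1.w"]]
  expect_false(identical(w1, w2))

  # probability-averaging gain: the fused ensemble is at least as good as
  # the average member on held-out phantoms
  test <- generateDataset(smallPhantomConfig(seed = 55), 3, seed = 55)
  fusedDice <- mean(vapply(test, function(s)
    diceScore(segmentationMap(predictEnsemble(rwi, imageArray(s))),
              cleanLabel(s)), numeric(1)))
  memberDice <- mean(vapply(members(rwi), function(m) meanTestDice(m, test),
                            numeric(1)))
  expect_gte(fusedDice, memberDice - 1e-8)
})

test_that("ensembles of untrained oracles are rejected", {
  expect_error(trainEnsemble(list(), buildUnet(tinyUnetConfig(), seed = 1),
                             K = 2, unetConfig = tinyUnetConfig(),
                             trainConfig = fastTrainConfig()),
               "Bayesian")
})
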