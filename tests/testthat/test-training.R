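# Mask-gated cross-entropy and base-model training.

randomLossInputs <- function(H = 4, W = 5, seed = 1, maskP = 0.7) {
  set.seed(seed)
  p <- randomProbMap(H, W, 2, seed = seed)@probabilities
  list(p = p, y = binaryMatrix(runif(H * W) < 0.4, H, W),
       m = binaryMatrix(runif(H * W) < maskP, H, W))
}

test_that("masked cross-entropy matches the triple-loop oracle", {
  for (seed in 1:8) {
    li <- randomLossInputs(seed = seed)
    ones <- binaryMatrix(1, 4, 5)
    expect_equal(maskedCrossEntropy(li$p, li$y, NULL),
                 loopLoss(list(li$p), list(li$y), list(ones)),
                 tolerance = 1e-10)
    expect_equal(maskedCrossEntropy(li$p, li$y, li$m),
                 loopLoss(list(li$p), list(li$y), list(li$m)),
                 tolerance = 1e-10)
  }
  # batch of three images
  lis <- lapply(1:3, function(s) randomLossInputs(seed = 10 + s))
  expect_equal(
    maskedCrossEntropy(lapply(lis, `[[`, "p"), lapply(lis, `[[`, "y"),
                       lapply(lis, `[[`, "m")),
    loopLoss(lapply(lis, `[[`, "p"), lapply(lis, `[[`, "y"),
             lapply(lis, `[[`, "m")),
    tolerance = 1e-10)
})

test_that("masking removes exactly the excluded terms", {
  li <- randomLossInputs(seed = 21)
  ones <- binaryMatrix(1, 4, 5)
  excluded <- loopLoss(list(li$p), list(li$y), list(1L - li$m))
  expect_equal(maskedCrossEntropy(li$p, li$y, li$m),
               maskedCrossEntropy(li$p, li$y, NULL) - excluded,
               tolerance = 1e-12)
})

test_that("a hand-computed 2x2 three-term fixture agrees", {
  # foreground probabilities per pixel: (1,1)=0.9, (2,1)=0.3, (1,2)=0.6,
  # (2,2)=0.2; labels: 1, 0, 1, 0; mask zeroes pixel (1,1), so
  # L = -(log(0.7) + log(0.6) + log(0.8)) / 4
  pf <- matrix(c(0.9, 0.3, 0.6, 0.2), 2)
  p <- array(c(1 - pf, pf), dim = c(2, 2, 2))
  y <- matrix(c(1L, 0L, 1L, 0L), 2)
  m <- matrix(c(0L, 1L, 1L, 1L), 2)
  expect_equal(maskedCrossEntropy(p, y, m),
               -(log(0.7) + log(0.6) + log(0.8)) / 4, tolerance = 1e-12)
})

test_that("degenerate masks and invalid inputs are handled", {
  li <- randomLossInputs(seed = 5)
  zero <- binaryMatrix(0, 4, 5)
  expect_warning(l <- maskedCrossEntropy(li$p, li$y, zero), "zero")
  expect_identical(l, 0)
  expect_error(maskedCrossEntropy(li$p, matrix(0L, 3, 3), NULL),
               "shape mismatch")
  expect_error(maskedCrossEntropy(li$p, li$y, matrix(0.5, 4, 5)), "binary")
  expect_gte(maskedCrossEntropy(li$p, li$y, li$m), 0)
})

test_that("the loss is invariant to batch permutation", {
  lis <- lapply(1:4, function(s) randomLossInputs(seed = 30 + s))
  l1 <- maskedCrossEntropy(lapply(lis, `[[`, "p"), lapply(lis, `[[`, "y"),
                           lapply(lis, `[[`, "m"))
  ord <- c(3, 1, 4, 2)
  l2 <- maskedCrossEntropy(lapply(lis[ord], `[[`, "p"),
                           lapply(lis[ord], `[[`, "y"),
                           lapply(lis[ord], `[[`, "m"))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("the training loss agrees with the engine's internal loss", {
  samples <- generateDataset(smallPhantomConfig(), 2, seed = 2)
  m <- buildUnet(tinyUnetConfig(), seed = 1)
  imgs <- lapply(samples, function(s) gaussianNormalize(imageArray(s)))
  labs <- lapply(samples, observedLabel)
  ones <- lapply(labs, function(l) 0L * l + 1L)
  st <- saen:::.unetTrainStepCpp(m@weights, 2L, 0, FALSE, imgs, labs, ones,
                                 "all", 1e-7)
  probs <- lapply(imgs, function(x)
    probabilities(predictProbabilities(m, x)))
  expect_equal(st$loss, maskedCrossEntropy(probs, labs, NULL),
               tolerance = 1e-6)
})

test_that("zero-epoch training returns the initialized model", {
  samples <- generateDataset(smallPhantomConfig(), 2, seed = 4)
  tc <- fastTrainConfig(epochs = 0, seed = 7)
  a <- trainBaseModel(samples, NULL, tinyUnetConfig(), tc)
  b <- trainBaseModel(samples, NULL, tinyUnetConfig(), tc)
  expect_identical(a@weights, b@weights)
  expect_equal(fingerprint(a)$epochs, 0L)
  expect_length(fingerprint(a)$lossHistory, 0)
})

test_that("one epoch of training lowers the loss (seed-averaged)", {
  samples <- generateDataset(smallPhantomConfig(), 8, seed = 6)
  labs <- lapply(samples, observedLabel)
  deltas <- vapply(1:3, function(seed) {
    tc <- fastTrainConfig(epochs = 1, seed = seed)
    init <- trainBaseModel(samples, NULL, tinyUnetConfig(),
                           fastTrainConfig(epochs = 0, seed = seed))
    trained <- trainBaseModel(samples, NULL, tinyUnetConfig(), tc)
    lossOf <- function(m) {
      probs <- lapply(samples, function(s)
        probabilities(predictProbabilities(m, gaussianNormalize(imageArray(s)))))
      maskedCrossEntropy(probs, labs, NULL)
    }
    lossOf(init) - lossOf(trained)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("training is reproducible for identical data, config and seed", {
  samples <- generateDataset(smallPhantomConfig(), 6, seed = 8)
  test <- generateDataset(smallPhantomConfig(seed = 99), 2, seed = 99)
  tc <- fastTrainConfig(epochs = 2, seed = 13)
  a <- trainBaseModel(samples, NULL, tinyUnetConfig(), tc)
  b <- trainBaseModel(samples, NULL, tinyUnetConfig(), tc)
  expect_equal(meanTestDice(a, test), meanTestDice(b, test),
               tolerance = 1e-6)
  expect_equal(a@weights, b@weights, tolerance = 1e-6)
})

test_that("missing supervision masks fail naming the image", {
  samples <- generateDataset(smallPhantomConfig(), 3, seed = 10)
  masks <- lapply(samples, function(s)
    new("SupervisionMask", mask = 0L * observedLabel(s) + 1L,
        lambdaUsed = 0.5, sourceSampleId = "x"))
  masks[2] <- list(NULL)
  expect_error(trainBaseModel(samples, masks, tinyUnetConfig(),
                              fastTrainConfig(epochs = 1)),
               "image\\(s\\) 2")
  expect_error(trainBaseModel(samples, masks[1:2], tinyUnetConfig(),
                              fastTrainConfig(epochs = 1)),
               "2 masks for 3")
})

test_that("oracle training enforces and records the Bayesian contract", {
  expect_error(trainUncertaintyOracle(list(), tinyUnetConfig(),
                                      fastTrainConfig()),
               "dropoutRate > 0")
  samples <- generateDataset(smallPhantomConfig(), 16, seed = 12)
  orc <- trainUncertaintyOracle(
    samples, tinyUnetConfig(dropoutRate = 0.5, dropoutMode = "train_only"),
    fastTrainConfig(epochs = 3, seed = 5))
  expect_equal(modelConfig(orc)@dropoutMode, "train_and_inference")
  expect_equal(fingerprint(orc)$lambda, 1.0)
  u <- probabilityVariation(
    mcSample(orc, gaussianNormalize(imageArray(samples[[1]])), T = 10,
             seed = 3))
  expect_gt(max(uncertaintyValues(u)), min(uncertaintyValues(u)))
})

test_that("checkpoints round-trip weights, config and fingerprint", {
  m <- buildUnet(tinyUnetConfig(dropoutRate = 0.3,
                                dropoutMode = "train_and_inference"),
                 seed = 5)
  p <- withr::local_tempfile(fileext = ".rds")
  writeModelCheckpoint(m, p)
  back <- readModelCheckpoint(p)
  expect_equal(back@weights, m@weights)
  expect_equal(modelConfig(back)@dropoutRate, 0.3)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  expect_identical(probabilities(predictProbabilities(back, x)),
                   probabilities(predictProbabilities(m, x)))
})
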