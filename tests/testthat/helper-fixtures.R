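# Shared fixtures: all built in code at test time.

# Small phantom regime used by unit tests (32 x 32 keeps trainings fast and
# is divisible by 4, the depth-3 requirement).
smallPhantomConfig <- function(jitter = 1.5, seed = 1L)
  phantomConfig(imageHeight = 32L, imageWidth = 32L,
                nPeriventricular = 1L, nDeep = 1L,
                lesionRadiusRange = c(3, 6),
                annotationJitterSigma = jitter, seed = seed)

tinyUnetConfig <- function(...) unetConfig(inChannels = 2L, depth = 2L,
                                           baseFilters = 4L, ...)

fastTrainConfig <- function(epochs = 2L, seed = 1L, ...)
  trainConfig(learningRate = 5e-3, batchSize = 8L, epochs = epochs,
              seed = seed, ...)

# Random softmax stack: H x W x C x T with per-pixel normalization.
randomStack <- function(H = 6L, W = 5L, C = 2L, T = 4L, seed = 1L) {
  set.seed(seed)
  raw <- array(exp(rnorm(H * W * C * T)), dim = c(H, W, C, T))
  for (t in seq_len(T)) {
    s <- apply(raw[, , , t, drop = FALSE], c(1, 2), sum)
    for (c in seq_len(C)) raw[, , c, t] <- raw[, , c, t] / s
  }
  new("ProbabilityStack", samples = raw, sourceModelId = "fixture")
}

randomProbMap <- function(H = 6L, W = 5L, C = 2L, seed = 1L) {
  s <- randomStack(H, W, C, T = 1L, seed = seed)
  probabilityMap(array(s@samples, dim = c(H, W, C)))
}

randomNormalizedUncertainty <- function(H = 8L, W = 8L, seed = 1L) {
  set.seed(seed)
  raw <- new("UncertaintyMap", values = matrix(runif(H * W) * 0.4, H, W),
             normalized = FALSE,
             normalizationStats = c(NA_real_, NA_real_))
  normalizeUncertainty(raw)
}

binaryMatrix <- function(v, H, W) matrix(as.integer(v), H, W)

segFromMap <- function(map) {
  p <- if (is(map, "ProbabilityMap")) map@probabilities else map
  matrix(as.integer(p[, , 2] >= 0.5), dim(p)[1], dim(p)[2])
}

meanTestDice <- function(model, testSamples) {
  mean(vapply(testSamples, function(s) {
    p <- predictProbabilities(model, gaussianNormalize(imageArray(s)))
    diceScore(segFromMap(p), cleanLabel(s))
  }, numeric(1)))
}
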