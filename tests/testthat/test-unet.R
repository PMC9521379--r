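# U-Net architecture: dropout placement, parameter count, shape contracts,
# determinism, and agreement between the fused C++ engine and the plain-R
# reference forward pass plus finite-difference gradients.

test_that("dropout layers sit exactly before pooling and after up-convs", {
  none <- auditDropoutPlacement(unetConfig(depth = 3, dropoutRate = 0))
  expect_equal(nrow(none), 0)

  audit <- auditDropoutPlacement(bayesianUnetConfig(depth = 3))
  expect_equal(nrow(audit), 4)  # (depth-1) per side
  expect_equal(sum(audit$position == "before_maxpool"), 2)
  expect_equal(sum(audit$position == "after_upconv"), 2)
  expect_false(any(audit$position == "other"))

  audit5 <- auditDropoutPlacement(bayesianUnetConfig(depth = 5))
  expect_equal(table(audit5$position)[["before_maxpool"]], 4)
  expect_equal(table(audit5$position)[["after_upconv"]], 4)
})

test_that("parameter count follows the documented formula", {
  # independent recomputation: two 3x3 convs per level with channel
  # doubling, 2x2 up-convs, concat-halving decoder convs, 1x1 head
  countFor <- function(inCh, classes, d, f) {
    ch <- f * 2^(0:(d - 1))
    total <- 0
    for (i in 1:(d - 1)) {
      ci <- if (i == 1) inCh else ch[i - 1]
      total <- total + 9 * ci * ch[i] + ch[i] + 9 * ch[i]^2 + ch[i]
    }
    total <- total + 9 * ch[d - 1] * ch[d] + ch[d] + 9 * ch[d]^2 + ch[d]
    for (i in (d - 1):1) {
      total <- total + 4 * ch[i + 1] * ch[i] + ch[i] +         # up-conv
        9 * 2 * ch[i] * ch[i] + ch[i] + 9 * ch[i]^2 + ch[i]    # two convs
    }
    total + classes * ch[1] + classes
  }
  cfg <- unetConfig(inChannels = 2, nClasses = 2, depth = 3, baseFilters = 8)
  expect_equal(nParameters(cfg), countFor(2, 2, 3, 8))
  m <- buildUnet(cfg, seed = 1)
  expect_equal(sum(lengths(m@weights)), nParameters(cfg))
  cfg2 <- unetConfig(inChannels = 1, nClasses = 3, depth = 4, baseFilters = 4)
  expect_equal(nParameters(cfg2), countFor(1, 3, 4, 4))
  expect_equal(sum(lengths(buildUnet(cfg2, seed = 2)@weights)),
               nParameters(cfg2))
})

test_that("forward pass obeys the shape and softmax contracts", {
  cfg <- unetConfig(inChannels = 2, depth = 3, baseFilters = 8)
  m <- buildUnet(cfg, seed = 1)
  x <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 2))
  p <- probabilities(predictProbabilities(m, x))
  expect_equal(dim(p), c(32, 32, 2))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)

  p2 <- probabilities(predictProbabilities(m, x))
  expect_identical(p, p2)  # deterministic

  expect_error(predictProbabilities(m, array(0, c(32, 32, 3))),
               "3 channel")
  expect_error(predictProbabilities(m, array(0, c(30, 32, 2))),
               "divisible")
})

test_that("a dropout-free model ignores the stochastic flag", {
  m <- buildUnet(unetConfig(inChannels = 2, depth = 2, baseFilters = 4,
                            dropoutRate = 0), seed = 3)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  expect_identical(probabilities(predictProbabilities(m, x, stochastic = TRUE,
                                                      seed = 1)),
                   probabilities(predictProbabilities(m, x)))
})

test_that("stochastic prediction is reproducible under a fixed seed", {
  m <- buildUnet(bayesianUnetConfig(inChannels = 2, depth = 2,
                                    baseFilters = 4), seed = 3)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  a <- probabilities(predictProbabilities(m, x, stochastic = TRUE, seed = 11))
  b <- probabilities(predictProbabilities(m, x, stochastic = TRUE, seed = 11))
  d <- probabilities(predictProbabilities(m, x, stochastic = TRUE, seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("the fused engine matches the plain-R reference forward pass", {
  for (depth in 2:3) {
    cfg <- unetConfig(inChannels = 2, depth = depth, baseFilters = 4)
    m <- buildUnet(cfg, seed = depth)
    x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
    pR <- saen:::.unetForwardR(m, x)$probs
    pC <- saen:::.unetForward(m, x)
    expect_equal(pC, pR, tolerance = 1e-5)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- unetConfig(inChannels = 2, depth = 2, baseFilters = 3)
  m <- buildUnet(cfg, seed = 4)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  lab <- binaryMatrix(runif(64) < 0.4, 8, 8)
  msk <- binaryMatrix(runif(64) < 0.8, 8, 8)
  lossAt <- function(w)
    saen:::.unetTrainStepCpp(w, cfg@depth, 0, FALSE, list(x), list(lab),
                             list(msk), "all", 1e-7)$loss
  st <- saen:::.unetTrainStepCpp(m@weights, cfg@depth, 0, FALSE, list(x),
                                 list(lab), list(msk), "all", 1e-7)
  for (nm in c("enc1.c1.w", "enc1.c2.b", "bot.c1.w", "dec1.up.w",
               "dec1.c2.w", "out.w")) {
    idx <- seq_len(min(3, length(m@weights[[nm]])))
    for (i in idx) {
      h <- 2e-4
      wp <- m@weights; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- m@weights; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (lossAt(wp) - lossAt(wm)) / (2 * h)
      expect_equal(st$grads[[nm]][i], fd, tolerance = 5e-3)
    }
  }
})
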