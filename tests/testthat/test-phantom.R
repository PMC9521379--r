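# Synthetic phantom generator: determinism, annotation-noise structure,
# and error handling.

test_that("generation is deterministic and seed-sensitive", {
  cfg <- smallPhantomConfig()
  a <- generateSample(cfg, seed = 7)
  b <- generateSample(cfg, seed = 7)
  expect_identical(imageArray(a), imageArray(b))
  expect_identical(observedLabel(a), observedLabel(b))
  d <- generateDataset(cfg, 2, seed = 3)
  d2 <- generateDataset(cfg, 2, seed = 3)
  expect_identical(lapply(d, imageArray), lapply(d2, imageArray))
  d3 <- generateDataset(cfg, 2, seed = 4)
  expect_false(identical(imageArray(d[[1]]), imageArray(d3[[1]])))
})

test_that("zero jitter reproduces the clean label exactly", {
  s <- generateSample(smallPhantomConfig(jitter = 0), seed = 11)
  expect_identical(observedLabel(s), cleanLabel(s))
})

test_that("a lesion-free configuration yields all-background labels", {
  cfg <- phantomConfig(imageHeight = 32, imageWidth = 32,
                       nPeriventricular = 0, nDeep = 0)
  s <- generateSample(cfg, seed = 2)
  expect_true(all(cleanLabel(s) == 0))
  expect_true(all(observedLabel(s) == 0))
})

test_that("annotation disagreements are confined to the boundary band", {
  # brute-force oracle: per disagreeing pixel, the minimum Euclidean
  # distance to any boundary pixel by direct enumeration
  cfg <- phantomConfig(imageHeight = 64, imageWidth = 64,
                       nPeriventricular = 1, nDeep = 1,
                       annotationJitterSigma = 1.5)
  s <- generateSample(cfg, seed = 7)
  dis <- which(cleanLabel(s) != observedLabel(s), arr.ind = TRUE)
  expect_gt(nrow(dis), 0)
  lab <- cleanLabel(s)
  isBoundary <- matrix(FALSE, nrow(lab), ncol(lab))
  for (y in seq_len(nrow(lab))) {
    for (x in seq_len(ncol(lab))) {
      nb <- lab[max(1, y - 1):min(nrow(lab), y + 1),
                max(1, x - 1):min(ncol(lab), x + 1)]
      if (any(nb != lab[y, x])) isBoundary[y, x] <- TRUE
    }
  }
  bcoord <- which(isBoundary, arr.ind = TRUE)
  minDist <- vapply(seq_len(nrow(dis)), function(i)
    sqrt(min((bcoord[, 1] - dis[i, 1])^2 + (bcoord[, 2] - dis[i, 2])^2)),
    numeric(1))
  expect_true(all(minDist <= 3 * cfg@annotationJitterSigma))
})

test_that("a dataset sweep satisfies the sample invariants", {
  cfg <- smallPhantomConfig(jitter = 1.5)
  samples <- generateDataset(cfg, 60, seed = 1)
  expect_length(samples, 60)
  for (s in samples) {
    expect_true(validObject(s))
    expect_true(all(observedLabel(s) %in% 0:1))
    dis <- cleanLabel(s) != observedLabel(s)
    if (any(dis)) {
      bd <- boundaryDistance(cleanLabel(s))
      expect_lte(max(bd[dis]), 3 * cfg@annotationJitterSigma)
    }
    # foreground is brighter than background in channel 1
    if (any(cleanLabel(s) == 1)) {
      img <- imageArray(s)[, , 1]
      expect_gt(mean(img[cleanLabel(s) == 1]), mean(img[cleanLabel(s) == 0]))
    }
  }
})

test_that("mean disagreement grows with the annotation jitter scale", {
  rates <- vapply(c(0, 1, 2), function(sig) {
    cfg <- smallPhantomConfig(jitter = sig)
    mean(vapply(generateDataset(cfg, 50, seed = 5), function(s)
      mean(cleanLabel(s) != observedLabel(s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_identical(rates[1], 0)
})

test_that("lesions that cannot fit raise an error naming the dimension", {
  cfg <- phantomConfig(imageHeight = 16, imageWidth = 64,
                       lesionRadiusRange = c(8, 12))
  expect_error(generateSample(cfg, seed = 1), "image_height")
  cfg2 <- phantomConfig(imageHeight = 64, imageWidth = 16,
                        lesionRadiusRange = c(8, 12))
  expect_error(generateSample(cfg2, seed = 1), "image_width")
})

test_that("phantom datasets round-trip through NIfTI plus manifest", {
  dir <- withr::local_tempdir()
  samples <- generateDataset(smallPhantomConfig(), 3, seed = 9)
  manifest <- writePhantomDataset(samples, dir)
  expect_equal(nrow(manifest), 3)
  back <- readPhantomDataset(dir)
  for (i in 1:3) {
    expect_equal(imageArray(back[[i]]), imageArray(samples[[i]]))
    expect_identical(observedLabel(back[[i]]), observedLabel(samples[[i]]))
    expect_identical(cleanLabel(back[[i]]), cleanLabel(samples[[i]]))
  }
})
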