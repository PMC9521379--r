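# Overlap, boundary-distance and lesion-wise metrics against brute-force
# oracles.

square <- function(H, W, ys, xs) {
  m <- matrix(0L, H, W)
  m[ys, xs] <- 1L
  m
}

test_that("dice handles identity, disjoint, partial and empty cases", {
  g <- square(8, 8, 2:4, 2:5)           # 12 px
  expect_equal(diceScore(g, g), 1)
  p <- square(8, 8, 6:7, 6:7)
  expect_equal(diceScore(p, g), 0)
  # P of 4 px overlapping G of 8 px in 2 px -> 2*2/(4+8) = 1/3
  g2 <- square(8, 8, 1:2, 1:4)
  p2 <- square(8, 8, 2:3, 3:4)
  expect_equal(diceScore(p2, g2), 1 / 3)
  expect_equal(diceScore(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(diceScore(matrix(0L, 4, 4), matrix(0L, 4, 5)), "mismatch")
})

test_that("dice is symmetric and bounded on random masks", {
  set.seed(1)
  for (i in 1:20) {
    a <- binaryMatrix(runif(64) < 0.4, 8, 8)
    b <- binaryMatrix(runif(64) < 0.4, 8, 8)
    d <- diceScore(a, b)
    expect_equal(d, diceScore(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("H95 matches the all-pairs boundary oracle", {
  g <- square(12, 12, 3:8, 3:8)
  expect_equal(hausdorff95(g, g), 0)

  a <- square(12, 12, 2, 2); b <- square(12, 12, 2, 7)
  expect_equal(hausdorff95(a, b), 5)

  sq <- square(16, 16, 3:12, 3:12)
  sh <- square(16, 16, 6:15, 3:12)   # shifted by 3 rows
  expect_equal(hausdorff95(sq, sh), h95Oracle(sq, sh), tolerance = 1e-12)
  expect_equal(hausdorff95(sq, sh), hausdorff95(sh, sq))

  set.seed(4)
  for (i in 1:10) {
    p <- binaryMatrix(runif(100) < 0.3, 10, 10)
    g2 <- binaryMatrix(runif(100) < 0.3, 10, 10)
    if (sum(p) == 0 || sum(g2) == 0) next
    expect_equal(hausdorff95(p, g2), h95Oracle(p, g2), tolerance = 1e-12)
  }
})

test_that("H95 respects anisotropic spacing and empty-mask sentinels", {
  a <- square(12, 12, 2, 2); b <- square(12, 12, 2, 7)
  expect_equal(hausdorff95(a, b, spacing = c(1, 2)), 10)
  expect_equal(hausdorff95(a, b, spacing = c(1, 2)),
               h95Oracle(a, b, spacing = c(1, 2)), tolerance = 1e-12)
  empty <- matrix(0L, 12, 12)
  h <- hausdorff95(empty, b)
  expect_true(isTRUE(attr(h, "empty")))
  expect_equal(as.numeric(h), sqrt(2) * 12)
})

test_that("H95 never exceeds the exact Hausdorff distance", {
  set.seed(6)
  for (i in 1:10) {
    p <- binaryMatrix(runif(81) < 0.35, 9, 9)
    g <- binaryMatrix(runif(81) < 0.35, 9, 9)
    if (sum(p) == 0 || sum(g) == 0) next
    # exact Hausdorff distance on the same boundary sets
    bp <- which(saen:::.boundaryPixels(p, "inner"), arr.ind = TRUE)
    bg <- which(saen:::.boundaryPixels(g, "inner"), arr.ind = TRUE)
    dmat <- sqrt(outer(bp[, 1], bg[, 1], "-")^2 +
                   outer(bp[, 2], bg[, 2], "-")^2)
    exact <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
    expect_lte(hausdorff95(p, g), exact + 1e-12)
  }
})

test_that("voxel recall counts true positives over ground truth", {
  g <- square(8, 8, 2:4, 2:4)
  p <- square(8, 8, 1:5, 1:5)
  expect_equal(voxelRecall(p, g), 1)
  expect_equal(voxelRecall(square(8, 8, 7, 7), g), 0)
  # printed 4x4 fixture: gt has 5 px, pred covers 3 of them
  gt <- matrix(c(1, 1, 0, 0,
                 1, 1, 0, 0,
                 0, 1, 0, 0,
                 0, 0, 0, 0), 4, 4, byrow = TRUE)
  pr <- matrix(c(1, 0, 0, 1,
                 1, 1, 0, 0,
                 0, 0, 0, 0,
                 0, 0, 0, 0), 4, 4, byrow = TRUE)
  expect_equal(voxelRecall(binaryMatrix(pr, 4, 4), binaryMatrix(gt, 4, 4)),
               3 / 5)
  expect_true(is.na(voxelRecall(pr * 0L, matrix(0L, 4, 4))))
})

test_that("component labelling distinguishes 4- and 8-connectivity", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal touch
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)
})

test_that("lesion-wise recall and F1 follow component counting", {
  gt <- matrix(0L, 10, 10)
  gt[2:3, 2:3] <- 1L; gt[7:8, 2:3] <- 1L; gt[2:3, 7:8] <- 1L
  expect_equal(lesionF1(gt, gt)$lesion_recall, 1)
  expect_equal(lesionF1(gt, gt)$lesion_f1, 1)
  expect_equal(lesionF1(gt, gt)$n_lesions, 3)

  empty <- matrix(0L, 10, 10)
  two <- matrix(0L, 10, 10); two[2:3, 2:3] <- 1L; two[7:8, 7:8] <- 1L
  e <- lesionF1(empty, two)
  expect_equal(e$lesion_recall, 0)
  expect_equal(e$lesion_f1, 0)

  # 2 GT lesions, prediction hits one and adds one spurious blob
  pred <- matrix(0L, 10, 10); pred[2, 2] <- 1L; pred[5, 9] <- 1L
  r <- lesionF1(pred, two)
  expect_equal(r$lesion_recall, 0.5)
  expect_equal(r$lesion_f1, 0.5)       # 2*1 / (2*1 + 1 + 1)
  expect_equal(r$n_false_positive, 1L)
})

test_that("lesion recall equals voxel recall for single-voxel lesions", {
  set.seed(9)
  gt <- matrix(0L, 8, 8)
  gt[cbind(c(2, 5, 7), c(2, 5, 3))] <- 1L   # isolated single voxels
  pred <- binaryMatrix(runif(64) < 0.4, 8, 8)
  expect_equal(lesionF1(pred, gt)$lesion_recall, voxelRecall(pred, gt))
})

test_that("size stratification splits at the median lesion size", {
  gt <- matrix(0L, 20, 20)
  gt[2, 2] <- 1L                              # size 2 (with neighbor)
  gt[2, 3] <- 1L
  gt[6:10, 2:3] <- 1L                         # size 10
  gt[12:18, 8:14] <- 1L                       # size 49 (close to 50)
  pred <- matrix(0L, 20, 20); pred[13, 9] <- 1L  # hits only the largest
  r <- sizeStratifiedRecall(pred, gt)
  expect_equal(r$median_size, 10)
  expect_equal(r$recall_large, 1)
  expect_equal(r$recall_small, 0)

  allhit <- sizeStratifiedRecall(gt, gt)
  expect_equal(allhit$recall_small, 1)
  expect_equal(allhit$recall_large, 1)

  one <- matrix(0L, 8, 8); one[3:4, 3:4] <- 1L
  s <- sizeStratifiedRecall(one, one)
  expect_true(is.na(s$recall_large))           # single lesion is "small"
  expect_equal(s$recall_small, 1)
  expect_error(sizeStratifiedRecall(one, matrix(0L, 8, 8)), "no lesion")
})

test_that("dilating a prediction toward the truth never lowers dice", {
  s <- generateSample(smallPhantomConfig(), seed = 17)
  gt <- cleanLabel(s)
  dIn <- boundaryDistance(gt)
  dices <- vapply(c(3, 2, 1, 0), function(k) {
    pred <- binaryMatrix(gt == 1 & dIn > k, nrow(gt), ncol(gt))
    diceScore(pred, gt)
  }, numeric(1))
  expect_true(all(diff(dices) >= 0))
})

test_that("the combined report collates all metrics", {
  s <- generateSample(smallPhantomConfig(), seed = 19)
  rep <- computeMetrics(observedLabel(s), cleanLabel(s))
  expect_true(all(c("dice", "h95", "recall", "lesion_f1", "recall_large",
                    "recall_small", "median_lesion_size", "n_lesions_gt")
                  %in% names(rep)))
  expect_gte(rep$dice, 0); expect_lte(rep$dice, 1)
  expect_gte(rep$h95, 0)
})
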