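# Evaluation metrics: Dice, 95th-percentile Hausdorff distance, voxel
# recall, lesion-wise recall/F1 over connected components, and recall
# stratified at the median lesion size.

.checkPair <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("shape mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs gt ", paste(dim(gt), collapse = "x"))
  if (!.isBinaryMatrix(pred) || !.isBinaryMatrix(gt))
    stop("masks must be binary matrices")
}

#' Dice overlap coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)`. Two empty masks score 1 (perfect
#' agreement on absence) -- relevant because lesion-free slices occur.
#'
#' @param pred,gt binary matrices of identical shape.
#' @return Dice in [0, 1].
#' @export
diceScore <- function(pred, gt) {
  .checkPair(pred, gt)
  sp <- sum(pred); sg <- sum(gt)
  if (sp + sg == 0) return(1)
  2 * sum(pred * gt) / (sp + sg)
}

#' 95th-percentile Hausdorff distance (H95)
#'
#' The maximum of the two directed 95th-percentile boundary-to-boundary
#' distances, in physical units. Boundaries are foreground pixels with an
#' 8-neighbor background pixel; directed distances are computed by exact
#' Euclidean distance transform (isotropic spacing) or all-pairs distances
#' on physical coordinates (anisotropic). If either mask is empty the image
#' diagonal is returned as a sentinel, flagged via the `"empty"` attribute.
#'
#' @param pred,gt binary matrices.
#' @param spacing numeric(2) pixel spacing (mm); default unit pixels.
#' @return H95 (>= 0); symmetric in its arguments.
#' @export
hausdorff95 <- function(pred, gt, spacing = c(1, 1)) {
  .checkPair(pred, gt)
  diag <- sqrt(sum((dim(gt) * spacing)^2))
  if (sum(pred) == 0 || sum(gt) == 0)
    return(structure(diag, empty = TRUE))
  bp <- .boundaryPixels(pred, "inner")
  bg <- .boundaryPixels(gt, "inner")
  if (abs(spacing[1] - spacing[2]) < 1e-12) {
    dToG <- .distanceTo(bg) * spacing[1]
    dToP <- .distanceTo(bp) * spacing[1]
    d1 <- stats::quantile(dToG[bp], 0.95, names = FALSE)
    d2 <- stats::quantile(dToP[bg], 0.95, names = FALSE)
  } else {
    cp <- which(bp, arr.ind = TRUE) * rep(spacing, each = sum(bp))
    cg <- which(bg, arr.ind = TRUE) * rep(spacing, each = sum(bg))
    dd <- sqrt(outer(cp[, 1], cg[, 1], "-")^2 +
                 outer(cp[, 2], cg[, 2], "-")^2)
    d1 <- stats::quantile(apply(dd, 1, min), 0.95, names = FALSE)
    d2 <- stats::quantile(apply(dd, 2, min), 0.95, names = FALSE)
  }
  max(d1, d2)
}

#' Voxel-wise recall (sensitivity)
#'
#' `|P intersect G| / |G|`; NA when the ground truth is empty.
#'
#' @param pred,gt binary matrices.
#' @return Recall in [0, 1], or NA.
#' @export
voxelRecall <- function(pred, gt) {
  .checkPair(pred, gt)
  if (sum(gt) == 0) return(NA_real_)
  sum(pred * gt) / sum(gt)
}

#' Connected-component labelling
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8, the standard for 2D lesion
#'   counting).
#' @return Integer matrix: 0 background, 1..n component labels.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  .labelComponents(.asBinaryInteger(mask), as.integer(connectivity))
}

#' Lesion-wise detection metrics
#'
#' Ground-truth components count as detected when they overlap at least one
#' predicted pixel; predicted components overlapping no ground-truth lesion
#' are false positives. `F1 = 2 TP / (2 TP + FP + FN)` over components.
#'
#' @param pred,gt binary matrices.
#' @param connectivity component connectivity (4 or 8).
#' @return list with `lesion_recall`, `lesion_f1`, `n_detected`,
#'   `n_lesions`, `n_false_positive`.
#' @export
lesionF1 <- function(pred, gt, connectivity = 8L) {
  .checkPair(pred, gt)
  labG <- labelComponents(gt, connectivity)
  labP <- labelComponents(pred, connectivity)
  nG <- max(labG); nP <- max(labP)
  detected <- if (nG == 0) integer() else
    which(vapply(seq_len(nG), function(k) any(pred[labG == k] != 0),
                 logical(1)))
  fp <- if (nP == 0) 0L else
    sum(vapply(seq_len(nP), function(k) all(gt[labP == k] == 0), logical(1)))
  tp <- length(detected)
  fn <- nG - tp
  list(lesion_recall = if (nG == 0) NA_real_ else tp / nG,
       lesion_f1 = if (nG == 0 && nP == 0) NA_real_
                   else 2 * tp / (2 * tp + fp + fn),
       n_detected = tp, n_lesions = nG, n_false_positive = as.integer(fp))
}

#' Lesion recall stratified at the median lesion size
#'
#' Ground-truth components are split at their median pixel count: components
#' `<=` the median form the "small" stratum, the rest the "large" stratum;
#' the detection fraction is reported per stratum (NA for an empty stratum).
#'
#' @param pred,gt binary matrices; `gt` must contain at least one component.
#' @param connectivity component connectivity.
#' @return list with `recall_large`, `recall_small`, `median_size`,
#'   `n_large`, `n_small`.
#' @export
sizeStratifiedRecall <- function(pred, gt, connectivity = 8L) {
  .checkPair(pred, gt)
  labG <- labelComponents(gt, connectivity)
  nG <- max(labG)
  if (nG == 0) stop("ground truth has no lesion components")
  sizes <- vapply(seq_len(nG), function(k) sum(labG == k), numeric(1))
  med <- stats::median(sizes)
  detected <- vapply(seq_len(nG), function(k) any(pred[labG == k] != 0),
                     logical(1))
  small <- sizes <= med
  list(recall_large = if (any(!small)) mean(detected[!small]) else NA_real_,
       recall_small = if (any(small)) mean(detected[small]) else NA_real_,
       median_size = med, n_large = sum(!small), n_small = sum(small))
}

#' Full metrics report for one prediction
#'
#' @param pred,gt binary matrices.
#' @param spacing pixel spacing (mm) for H95.
#' @param connectivity component connectivity.
#' @return One-row data.frame: dice, h95, recall, lesion_recall, lesion_f1,
#'   recall_large, recall_small, median_lesion_size, n_lesions_gt.
#' @export
computeMetrics <- function(pred, gt, spacing = c(1, 1), connectivity = 8L) {
  lf <- lesionF1(pred, gt, connectivity)
  strat <- if (lf$n_lesions > 0) sizeStratifiedRecall(pred, gt, connectivity)
           else list(recall_large = NA_real_, recall_small = NA_real_,
                     median_size = NA_real_)
  h <- hausdorff95(pred, gt, spacing)
  data.frame(dice = diceScore(pred, gt),
             h95 = as.numeric(h),
             h95_empty = isTRUE(attr(h, "empty")),
             recall = voxelRecall(pred, gt),
             lesion_recall = lf$lesion_recall,
             lesion_f1 = lf$lesion_f1,
             recall_large = strat$recall_large,
             recall_small = strat$recall_small,
             median_lesion_size = strat$median_size,
             n_lesions_gt = lf$n_lesions)
}
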