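# Ensemble training and probability-averaging fusion.
#
# The two-stage procedure: (1) a Bayesian oracle estimates a normalized
# annotation-uncertainty map per training image; (2) K base learners are
# trained, each under the binary masks of one uncertainty threshold lambda
# drawn from the candidate grid, and their predicted probability maps are
# averaged. The per-pixel spread of the member foreground probabilities is
# the ensemble's epistemic uncertainty.

#' Fuse member probability maps
#'
#' Averages the K member maps per pixel and class, takes the class argmax as
#' the segmentation (binary case: foreground iff the fused foreground
#' probability is >= 0.5 -- the tie resolves to foreground), and reports the
#' per-pixel population SD of the member foreground probabilities as the
#' epistemic uncertainty (identically 0 for K = 1).
#'
#' @param memberProbabilities list of >= 1 [ProbabilityMap-class] (or
#'   H x W x C arrays) of identical shape.
#' @param classOfInterest class treated as foreground (default 2).
#' @return An [EnsemblePrediction-class].
#' @examples
#' a <- array(c(0.8, 0.2), dim = c(1, 1, 2))
#' b <- array(c(0.2, 0.8), dim = c(1, 1, 2))
#' fuse(list(a, b))  # fused 0.5 -> foreground, uncertainty 0.3
#' @export
fuse <- function(memberProbabilities, classOfInterest = 2L) {
  stopifnot(length(memberProbabilities) >= 1)
  maps <- lapply(memberProbabilities, .asProbArray)
  dims <- lapply(maps, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("member maps have mismatched shapes: ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = ", "))
  K <- length(maps)
  fused <- Reduce(`+`, maps) / K
  fg <- vapply(maps, function(m) m[, , classOfInterest],
               matrix(0, dim(fused)[1], dim(fused)[2]))
  dim(fg) <- c(dim(fused)[1:2], K)
  m1 <- apply(fg, c(1, 2), mean)
  m2 <- apply(fg^2, c(1, 2), mean)
  uvals <- sqrt(pmax(m2 - m1^2, 0))
  seg <- .asBinaryInteger(matrix(fused[, , classOfInterest] >= 0.5,
                                 dim(fused)[1], dim(fused)[2]))
  new("EnsemblePrediction",
      fusedProbability = probabilityMap(fused), segmentation = seg,
      uncertainty = new("UncertaintyMap", values = uvals, normalized = FALSE,
                        normalizationStats = c(NA_real_, NA_real_)),
      memberProbabilities = lapply(maps, probabilityMap))
}

#' Train a supervision-augmented ensemble
#'
#' Runs the full second stage: per training image the oracle's normalized
#' uncertainty map is computed by Monte-Carlo dropout; a lambda schedule of
#' size K is sampled from the grid; per member the corresponding mask set is
#' built and a base model trained with the mask-gated loss. Member training
#' seeds derive from `masterSeed` plus the member index.
#'
#' @param samples training samples (list of [PhantomSample-class] or
#'   [VolumeRecord-class]).
#' @param oracle a trained Bayesian [UNetModel-class] (dropout at
#'   inference).
#' @param K ensemble size; the reference protocol uses 5.
#' @param grid lambda candidate set (default \{0.1, ..., 1.0\}).
#' @param unetConfig architecture of the base learners.
#' @param trainConfig optimization settings (its seed is overridden per
#'   member).
#' @param masterSeed seed governing uncertainty sampling, the lambda
#'   schedule and member seeds.
#' @param T Monte-Carlo samples per image for the uncertainty maps.
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(samples, oracle, K = 5L,
                          grid = seq(0.1, 1, by = 0.1), unetConfig,
                          trainConfig, masterSeed = 1L, T = 20L) {
  if (K < 1) stop("K must be >= 1")
  if (oracle@config@dropoutRate <= 0)
    stop("oracle must be a Bayesian model (dropoutRate > 0)")
  uncertainty <- lapply(seq_along(samples), function(i)
    estimateUncertainty(oracle, gaussianNormalize(.trainImage(samples[[i]])),
                        T = T, seed = .deriveSeed(masterSeed, i)))
  sched <- sampleLambdaSchedule(K, grid, seed = masterSeed)
  members <- lapply(seq_len(K), function(k) {
    lam <- sched@lambdas[k]
    masks <- lapply(seq_along(uncertainty), function(i)
      makeMask(uncertainty[[i]], lam, sourceSampleId = as.character(i)))
    cfgK <- trainConfig
    cfgK@seed <- .deriveSeed(masterSeed, 1000L + k)
    tryCatch(
      trainBaseModel(samples, masks, unetConfig, cfgK, lambda = lam),
      error = function(e)
        stop("training ensemble member ", k, " (lambda = ", lam,
             ") failed: ", conditionMessage(e)))
  })
  new("EnsembleModel", members = members, schedule = sched,
      fusion = "mean_probability")
}

#' Train a random-weight-initialization (RWI) ensemble baseline
#'
#' K fully supervised base models differing only in their initialization and
#' data-ordering seeds (all-ones masks, lambda = 1); fusion is identical to
#' the supervision-augmented ensemble. This is the classical deep-ensemble
#' control.
#'
#' @inheritParams trainEnsemble
#' @return An [EnsembleModel-class] whose schedule is all ones.
#' @export
trainRwiBaseline <- function(samples, K = 5L, unetConfig, trainConfig,
                             masterSeed = 1L) {
  if (K < 1) stop("K must be >= 1")
  members <- lapply(seq_len(K), function(k) {
    cfgK <- trainConfig
    cfgK@seed <- .deriveSeed(masterSeed, 1000L + k)
    trainBaseModel(samples, NULL, unetConfig, cfgK, lambda = 1.0)
  })
  new("EnsembleModel", members = members,
      schedule = new("LambdaSchedule", lambdas = rep(1, K),
                     grid = 1, seed = as.integer(masterSeed)),
      fusion = "mean_probability")
}

#' Predict with an ensemble
#'
#' Each member predicts a probability map (sliding-window tiled when a patch
#' shape is given), then the maps are fused.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param image numeric array H x W x C (intensity-normalized internally).
#' @param patchShape optional integer(2); when given, member predictions use
#'   50%-overlap sliding windows of this size.
#' @param normalizeInput standardize intensities first.
#' @return An [EnsemblePrediction-class].
#' @export
predictEnsemble <- function(ensemble, image, patchShape = NULL,
                            normalizeInput = TRUE) {
  if (normalizeInput) image <- gaussianNormalize(image)
  maps <- lapply(ensemble@members, function(m) {
    if (is.null(patchShape)) predictProbabilities(m, image)
    else slidingWindowPredict(m, image,
                              planTiling(dim(image)[1:2], patchShape))
  })
  fuse(maps)
}
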