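# Monte-Carlo dropout annotation-uncertainty estimation.
#
# The Bayesian U-Net (dropout active at inference) is sampled T times per
# image; the predictive mean approximates the marginal class probability and
# the per-pixel standard deviation of the foreground probability across the
# T samples ("probability variation") measures how uncertain the model is
# about each pixel's annotation. The raw variation map is min-max normalized
# per image to [0, 1] so one threshold scale applies to every image.

#' Draw Monte-Carlo dropout samples
#'
#' Runs `T` stochastic forward passes with independent dropout masks.
#' Deterministic given `seed`. A model without inference-time dropout
#' (theta = 0 or mode not `"train_and_inference"`) produces T identical
#' samples; this degenerate case triggers a warning.
#'
#' @param model a [UNetModel-class].
#' @param image numeric array H x W x C.
#' @param T number of dropout samplings (>= 1); default 20.
#' @param seed RNG seed for the dropout masks.
#' @return A [ProbabilityStack-class] with samples H x W x classes x T.
#' @export
mcSample <- function(model, image, T = 20L, seed = 1L) {
  if (T < 1) stop("T must be >= 1")
  x <- .checkInputShape(model@config, image)
  stochastic <- model@config@dropoutRate > 0 &&
    model@config@dropoutMode == "train_and_inference"
  if (!stochastic)
    warning("model has no inference-time dropout; all MC samples will be ",
            "identical")
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], model@config@nClasses, T))
  .withSeed(seed, {
    for (t in seq_len(T))
      out[, , , t] <- .unetForward(model, x, dropoutActive = stochastic)
  })
  new("ProbabilityStack", samples = out,
      sourceModelId = paste0("seed", model@fingerprint$seed %||% NA))
}

#' Mean predictive probability over Monte-Carlo samples
#'
#' Per-pixel, per-class arithmetic mean over the T samples of the stack --
#' the Monte-Carlo estimate of the marginal predictive distribution.
#'
#' @param stack a [ProbabilityStack-class].
#' @return A [ProbabilityMap-class].
#' @examples
#' s <- array(c(0.2, 0.8, 0.4, 0.6), dim = c(1, 1, 2, 2))
#' st <- new("ProbabilityStack", samples = s, sourceModelId = "toy")
#' probabilities(meanProbability(st))  # 0.3, 0.7
#' @export
meanProbability <- function(stack) {
  s <- stack@samples
  T <- dim(s)[4]
  acc <- s[, , , 1, drop = FALSE]
  if (T > 1) for (t in 2:T) acc <- acc + s[, , , t, drop = FALSE]
  probabilityMap(array(acc / T, dim = dim(s)[1:3]))
}

#' Probability variation: per-pixel SD across Monte-Carlo samples
#'
#' The uncertainty measure: the population (divide-by-T) standard deviation
#' of the class-of-interest softmax probability across the T samples. A
#' certain model yields exactly 0 (all samples agree). `T = 1` returns an
#' all-zero map with a warning.
#'
#' @param stack a [ProbabilityStack-class].
#' @param classOfInterest 1-based class index (default 2, the foreground of
#'   a binary problem).
#' @return A raw (unnormalized) [UncertaintyMap-class].
#' @export
probabilityVariation <- function(stack, classOfInterest = 2L) {
  s <- stack@samples
  d <- dim(s)
  if (classOfInterest < 1L || classOfInterest > d[3])
    stop("classOfInterest must be in 1..", d[3])
  T <- d[4]
  if (T < 2) {
    warning("T = 1: probability variation is identically zero")
    v <- matrix(0, d[1], d[2])
  } else {
    p <- array(s[, , classOfInterest, , drop = FALSE],
               dim = c(d[1], d[2], T))              # H x W x T
    m1 <- apply(p, c(1, 2), mean)
    m2 <- apply(p^2, c(1, 2), mean)
    v <- sqrt(pmax(m2 - m1^2, 0))                   # population SD
  }
  new("UncertaintyMap", values = v, normalized = FALSE,
      normalizationStats = c(NA_real_, NA_real_))
}

#' Min-max normalize an uncertainty map to [0, 1]
#'
#' Per-image rescaling `(u - min) / (max - min)`. A constant raw map (the
#' fully certain case) normalizes to all zeros. The (min, max) used are
#' recorded in the result.
#'
#' @param raw a raw [UncertaintyMap-class] (non-negative values).
#' @return A normalized [UncertaintyMap-class].
#' @export
normalizeUncertainty <- function(raw) {
  v <- raw@values
  if (any(v < 0)) stop("uncertainty values must be non-negative")
  lo <- min(v); hi <- max(v)
  out <- if (hi > lo) (v - lo) / (hi - lo) else matrix(0, nrow(v), ncol(v))
  new("UncertaintyMap", values = out, normalized = TRUE,
      normalizationStats = c(lo, hi))
}

#' Estimate a normalized annotation-uncertainty map for one image
#'
#' Convenience pipeline: Monte-Carlo sampling, probability variation,
#' min-max normalization.
#'
#' @inheritParams mcSample
#' @param classOfInterest class whose probability variation is measured.
#' @return A normalized [UncertaintyMap-class].
#' @export
estimateUncertainty <- function(model, image, T = 20L, seed = 1L,
                                classOfInterest = 2L) {
  normalizeUncertainty(
    probabilityVariation(mcSample(model, image, T = T, seed = seed),
                         classOfInterest = classOfInterest))
}

#' Write an uncertainty map as NIfTI with a JSON sidecar
#'
#' @param map an [UncertaintyMap-class].
#' @param path output path (`.nii.gz`); the sidecar takes the same stem with
#'   `.json`.
#' @param meta named list of provenance fields (T, seed, theta, ...).
#' @return Invisibly, the sidecar path.
#' @export
writeUncertaintyMap <- function(map, path, meta = list()) {
  RNifti::writeNifti(RNifti::asNifti(map@values), path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    c(meta, list(normalized = map@normalized,
                 normalization_stats = map@normalizationStats)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
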