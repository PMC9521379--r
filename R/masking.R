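# Supervision masks: threshold a normalized uncertainty map at lambda, and
# assign lambdas to ensemble members.

#' Build a binary supervision mask from a normalized uncertainty map
#'
#' `mask = 1` where the normalized uncertainty is at most `lambda`
#' (boundary inclusive), else 0: pixels whose annotation looks too uncertain
#' are excluded from the loss. `lambda = 1` keeps every pixel.
#'
#' @param uncertainty a normalized [UncertaintyMap-class].
#' @param lambda threshold in [0, 1].
#' @param sourceSampleId identifier stored with the mask.
#' @return A [SupervisionMask-class].
#' @examples
#' u <- normalizeUncertainty(new("UncertaintyMap",
#'   values = matrix(c(0, 0.05, 0.1), 1), normalized = FALSE,
#'   normalizationStats = c(NA_real_, NA_real_)))
#' maskMatrix(makeMask(u, 0.5))  # 1 1 0
#' @export
makeMask <- function(uncertainty, lambda, sourceSampleId = "sample") {
  if (!uncertainty@normalized)
    stop("uncertainty map is not normalized; call normalizeUncertainty() first")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  new("SupervisionMask",
      mask = .asBinaryInteger(uncertainty@values <= lambda),
      lambdaUsed = as.numeric(lambda), sourceSampleId = sourceSampleId)
}

#' Sample the lambda schedule for an ensemble
#'
#' Draws K thresholds from the candidate grid: without replacement while
#' K <= |grid| (each base learner gets a distinct lambda, maximizing
#' supervision diversity), with replacement otherwise. Deterministic given
#' `seed`. The default grid is \{0.1, 0.2, ..., 1.0\}.
#'
#' @param K ensemble size (>= 1).
#' @param grid candidate thresholds in [0, 1].
#' @param seed sampling seed.
#' @return A [LambdaSchedule-class].
#' @export
sampleLambdaSchedule <- function(K, grid = seq(0.1, 1, by = 0.1), seed = 1L) {
  if (K < 1) stop("K must be >= 1")
  if (length(grid) == 0) stop("lambda grid must not be empty")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  lam <- .withSeed(seed, sample(grid, K, replace = K > length(grid)))
  new("LambdaSchedule", lambdas = as.numeric(lam), grid = as.numeric(grid),
      seed = as.integer(seed))
}

#' Write a supervision mask as NIfTI with a JSON sidecar
#'
#' @param mask a [SupervisionMask-class].
#' @param path output path (`.nii.gz`).
#' @param meta extra sidecar fields (e.g. the oracle model id).
#' @return Invisibly, the sidecar path.
#' @export
writeSupervisionMask <- function(mask, path, meta = list()) {
  RNifti::writeNifti(RNifti::asNifti(mask@mask), path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    c(meta, list(lambda = mask@lambdaUsed,
                 source_sample_id = mask@sourceSampleId)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
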