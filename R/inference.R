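# Whole-image prediction by sliding-window tiling with 50% overlap.

#' Plan a sliding-window tiling
#'
#' Window origins advance at stride = patch/2 per axis (50% overlap); the
#' final window is clamped to the image edge (no padding), so windows may
#' overlap by more than 50% at the border and every pixel is covered at
#' least once on the original grid.
#'
#' @param imageShape integer(2) image height/width.
#' @param patchShape integer(2) window height/width.
#' @return A [TilingPlan-class].
#' @examples
#' windowOrigins(planTiling(c(64, 96), c(64, 64)))  # columns 1 and 33
#' @export
planTiling <- function(imageShape, patchShape) {
  imageShape <- as.integer(imageShape[1:2])
  patchShape <- as.integer(patchShape[1:2])
  if (any(patchShape > imageShape))
    stop("patch shape (", paste(patchShape, collapse = "x"),
         ") exceeds image shape (", paste(imageShape, collapse = "x"), ")")
  stride <- pmax(patchShape %/% 2L, 1L)
  axisOrigins <- function(size, patch, st) {
    o <- seq.int(1L, max(size - patch + 1L, 1L), by = st)
    last <- size - patch + 1L
    if (o[length(o)] != last) o <- c(o, last)
    o
  }
  oy <- axisOrigins(imageShape[1], patchShape[1], stride[1])
  ox <- axisOrigins(imageShape[2], patchShape[2], stride[2])
  origins <- cbind(rep(oy, times = length(ox)), rep(ox, each = length(oy)))
  colnames(origins) <- c("y", "x")
  new("TilingPlan", imageShape = imageShape, patchShape = patchShape,
      stride = as.integer(stride), origins = origins)
}

#' Sliding-window prediction
#'
#' Applies a patch-level predictor to every window of the plan and averages
#' the per-pixel class probabilities over all windows covering each pixel
#' (uniform weights).
#'
#' @param predictor a [UNetModel-class], an [EnsembleModel-class] (fused
#'   per window), or a function mapping an image patch to a
#'   [ProbabilityMap-class] / H x W x C array.
#' @param image numeric array H x W x C.
#' @param plan a [TilingPlan-class] for this image (default: built from
#'   `patchShape`).
#' @param patchShape used when `plan` is NULL; defaults to the whole image.
#' @return A [ProbabilityMap-class] on the full image grid.
#' @export
slidingWindowPredict <- function(predictor, image, plan = NULL,
                                 patchShape = NULL) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (is.null(plan)) {
    if (is.null(patchShape)) patchShape <- dim(image)[1:2]
    plan <- planTiling(dim(image)[1:2], patchShape)
  }
  if (!all(plan@imageShape == dim(image)[1:2]))
    stop("tiling plan was built for image ",
         paste(plan@imageShape, collapse = "x"), " but got ",
         paste(dim(image)[1:2], collapse = "x"))
  predictPatch <- function(patch) {
    if (is.function(predictor)) .asProbArray(predictor(patch))
    else if (is(predictor, "EnsembleModel"))
      predictEnsemble(predictor, patch, normalizeInput = FALSE)@fusedProbability@probabilities
    else predictProbabilities(predictor, patch)@probabilities
  }
  ph <- plan@patchShape[1]; pw <- plan@patchShape[2]
  first <- TRUE
  acc <- NULL; cnt <- matrix(0, dim(image)[1], dim(image)[2])
  for (r in seq_len(nrow(plan@origins))) {
    oy <- plan@origins[r, 1]; ox <- plan@origins[r, 2]
    ys <- oy:(oy + ph - 1L); xs <- ox:(ox + pw - 1L)
    p <- predictPatch(image[ys, xs, , drop = FALSE])
    if (first) {
      acc <- array(0, dim = c(dim(image)[1:2], dim(p)[3]))
      first <- FALSE
    }
    acc[ys, xs, ] <- acc[ys, xs, ] + p
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  stopifnot(all(cnt >= 1))          # the plan must cover every pixel
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / cnt
  probabilityMap(acc)
}
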