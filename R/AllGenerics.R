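# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for saen data objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("cleanLabel", function(x) standardGeneric("cleanLabel"))
#' @rdname accessors
#' @export
setGeneric("observedLabel", function(x) standardGeneric("observedLabel"))
#' @rdname accessors
#' @export
setGeneric("lesionInventory", function(x) standardGeneric("lesionInventory"))
#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname accessors
#' @export
setGeneric("uncertaintyValues", function(x) standardGeneric("uncertaintyValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("normalizationStats", function(x) standardGeneric("normalizationStats"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("lambdaUsed", function(x) standardGeneric("lambdaUsed"))
#' @rdname accessors
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("fingerprint", function(x) standardGeneric("fingerprint"))
#' @rdname accessors
#' @export
setGeneric("segmentationMap", function(x) standardGeneric("segmentationMap"))
#' @rdname accessors
#' @export
setGeneric("fusedProbability", function(x) standardGeneric("fusedProbability"))
#' @rdname accessors
#' @export
setGeneric("memberProbabilities", function(x) standardGeneric("memberProbabilities"))
#' @rdname accessors
#' @export
setGeneric("epistemicUncertainty", function(x) standardGeneric("epistemicUncertainty"))
#' @rdname accessors
#' @export
setGeneric("windowOrigins", function(x) standardGeneric("windowOrigins"))

#' @rdname accessors
setMethod("imageArray", "PhantomSample", function(x) x@image)
#' @rdname accessors
setMethod("imageArray", "VolumeRecord", function(x) x@image)
#' @rdname accessors
setMethod("labelMatrix", "VolumeRecord", function(x) x@label)
#' @rdname accessors
setMethod("cleanLabel", "PhantomSample", function(x) x@cleanLabel)
#' @rdname accessors
setMethod("observedLabel", "PhantomSample", function(x) x@observedLabel)
#' @rdname accessors
setMethod("lesionInventory", "PhantomSample", function(x) x@lesionInventory)
#' @rdname accessors
setMethod("probabilities", "ProbabilityMap", function(x) x@probabilities)
#' @rdname accessors
setMethod("probabilities", "ProbabilityStack", function(x) x@samples)
#' @rdname accessors
setMethod("uncertaintyValues", "UncertaintyMap", function(x) x@values)
#' @rdname accessors
setMethod("isNormalized", "UncertaintyMap", function(x) x@normalized)
#' @rdname accessors
setMethod("normalizationStats", "UncertaintyMap", function(x) x@normalizationStats)
#' @rdname accessors
setMethod("maskMatrix", "SupervisionMask", function(x) x@mask)
#' @rdname accessors
setMethod("lambdaUsed", "SupervisionMask", function(x) x@lambdaUsed)
#' @rdname accessors
setMethod("lambdas", "LambdaSchedule", function(x) x@lambdas)
#' @rdname accessors
setMethod("lambdas", "EnsembleModel", function(x) x@schedule@lambdas)
#' @rdname accessors
setMethod("members", "EnsembleModel", function(x) x@members)
#' @rdname accessors
setMethod("schedule", "EnsembleModel", function(x) x@schedule)
#' @rdname accessors
setMethod("modelConfig", "UNetModel", function(x) x@config)
#' @rdname accessors
setMethod("fingerprint", "UNetModel", function(x) x@fingerprint)
#' @rdname accessors
setMethod("segmentationMap", "EnsemblePrediction", function(x) x@segmentation)
#' @rdname accessors
setMethod("fusedProbability", "EnsemblePrediction", function(x) x@fusedProbability)
#' @rdname accessors
setMethod("memberProbabilities", "EnsemblePrediction", function(x) x@memberProbabilities)
#' @rdname accessors
setMethod("epistemicUncertainty", "EnsemblePrediction", function(x) x@uncertainty)
#' @rdname accessors
setMethod("windowOrigins", "TilingPlan", function(x) x@origins)

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomSample %d x %d, %d channel(s), %d lesion(s), seed %d\n",
              d[1], d[2], d[3], nrow(object@lesionInventory), object@seed))
  cat(sprintf("  clean/observed label disagreement: %d pixel(s)\n",
              sum(object@cleanLabel != object@observedLabel)))
})

setMethod("show", "UNetConfig", function(object) {
  cat(sprintf(paste0("UNetConfig: %d -> %d classes, depth %d, base filters %d,",
                     " dropout %.2f (%s)\n"),
              object@inChannels, object@nClasses, object@depth,
              object@baseFilters, object@dropoutRate, object@dropoutMode))
})

setMethod("show", "UNetModel", function(object) {
  fp <- object@fingerprint
  cat(sprintf("UNetModel (%d parameters)\n", nParameters(object@config)))
  cat(sprintf("  lambda %s, seed %s, epochs %s\n",
              format(fp$lambda %||% NA), format(fp$seed %||% NA),
              format(fp$epochs %||% 0L)))
})

setMethod("show", "UncertaintyMap", function(object) {
  cat(sprintf("UncertaintyMap %d x %d (%s), range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values),
              if (object@normalized) "normalized" else "raw",
              min(object@values), max(object@values)))
})

setMethod("show", "SupervisionMask", function(object) {
  cat(sprintf("SupervisionMask %d x %d, lambda %.2f, %.1f%% of pixels kept\n",
              nrow(object@mask), ncol(object@mask), object@lambdaUsed,
              100 * mean(object@mask)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: K = %d, fusion = %s\n",
              length(object@members), object@fusion))
  cat("  lambdas:", paste(format(object@schedule@lambdas), collapse = ", "), "\n")
})

setMethod("show", "EnsemblePrediction", function(object) {
  d <- dim(object@segmentation)
  cat(sprintf("EnsemblePrediction %d x %d from %d member(s); foreground %.1f%%\n",
              d[1], d[2], length(object@memberProbabilities),
              100 * mean(object@segmentation)))
})

setMethod("show", "TilingPlan", function(object) {
  cat(sprintf("TilingPlan: image %s, patch %s, stride %s, %d window(s)\n",
              paste(object@imageShape, collapse = "x"),
              paste(object@patchShape, collapse = "x"),
              paste(object@stride, collapse = "x"), nrow(object@origins)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
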