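# S4 classes for the pipeline's data objects. Spatial arrays are stored
# H x W x C (column-major, EBImage convention); labels and masks are
# H x W integer matrices in {0, 1}.

#' Configuration of the synthetic lesion phantom generator
#'
#' Phantoms are two-channel 2D images carrying elliptical lesions of two
#' kinds: "periventricular" lesions placed in a central vertical band with
#' hard intensity edges, and "deep" lesions placed outside the band with
#' Gaussian-blurred intensity ramps. The observed annotation is the clean
#' label deformed by a smooth random boundary-displacement field, emulating
#' rater noise that concentrates at lesion boundaries.
#'
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot nChannels number of image channels; channel 1 carries full lesion
#'   contrast (FLAIR-like), further channels half contrast (T1-like).
#' @slot nPeriventricular,nDeep lesion counts per kind.
#' @slot lesionRadiusRange numeric(2), min/max lesion radius in pixels.
#' @slot boundaryBlurSigma Gaussian sigma (pixels) of the intensity ramp of
#'   deep lesions.
#' @slot annotationJitterSigma magnitude (pixels) of the rater boundary
#'   displacement; 0 means the observed label equals the clean label.
#' @slot noiseSd additive Gaussian intensity noise SD.
#' @slot seed default seed used when none is passed to the generator.
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  imageHeight = "integer", imageWidth = "integer", nChannels = "integer",
  nPeriventricular = "integer", nDeep = "integer",
  lesionRadiusRange = "numeric", boundaryBlurSigma = "numeric",
  annotationJitterSigma = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@imageHeight < 8L || object@imageWidth < 8L)
    msg <- c(msg, "image must be at least 8 x 8 pixels")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@nPeriventricular < 0L || object@nDeep < 0L)
    msg <- c(msg, "lesion counts must be >= 0")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange <= 0) ||
      diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be positive with min <= max")
  if (object@boundaryBlurSigma < 0 || object@annotationJitterSigma < 0 ||
      object@noiseSd < 0)
    msg <- c(msg, "sigmas and noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom generator configuration
#'
#' Defaults define the package's standard phantom regime: 64 x 64 two-channel
#' images, two sharp and two blurry lesions of radius 4--9 px, boundary blur
#' 1.5 px, annotation jitter 1.5 px, intensity noise SD 0.15.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param nChannels number of channels (default 2).
#' @param nPeriventricular,nDeep lesion counts per kind.
#' @param lesionRadiusRange numeric(2) radius range in pixels.
#' @param boundaryBlurSigma intensity-ramp sigma for deep lesions (pixels).
#' @param annotationJitterSigma rater boundary-displacement scale (pixels).
#' @param noiseSd additive intensity noise SD.
#' @param seed default generation seed.
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(annotationJitterSigma = 1.5)
#' s <- generateSample(cfg, seed = 7)
#' @export
phantomConfig <- function(imageHeight = 64L, imageWidth = 64L, nChannels = 2L,
                          nPeriventricular = 2L, nDeep = 2L,
                          lesionRadiusRange = c(4, 9),
                          boundaryBlurSigma = 1.5,
                          annotationJitterSigma = 1.5,
                          noiseSd = 0.15, seed = 1L) {
  new("PhantomConfig",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      nChannels = as.integer(nChannels),
      nPeriventricular = as.integer(nPeriventricular), nDeep = as.integer(nDeep),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      boundaryBlurSigma = as.numeric(boundaryBlurSigma),
      annotationJitterSigma = as.numeric(annotationJitterSigma),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' A synthetic phantom sample
#'
#' Holds the image, the clean (noise-free) label, the observed (jittered)
#' annotation actually used for training, and an inventory of the generated
#' lesions (centroid, radius, kind).
#'
#' @slot image numeric array H x W x C.
#' @slot cleanLabel,observedLabel integer H x W matrices in \{0, 1\}.
#' @slot lesionInventory data.frame with columns y, x, radius, kind.
#' @slot seed the seed the sample was generated from.
#' @exportClass PhantomSample
setClass("PhantomSample", representation(
  image = "array", cleanLabel = "matrix", observedLabel = "matrix",
  lesionInventory = "data.frame", seed = "integer"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L) msg <- c(msg, "image must be a H x W x C array")
  if (!all(dim(object@cleanLabel) == d[1:2]) ||
      !all(dim(object@observedLabel) == d[1:2]))
    msg <- c(msg, "labels must match the image's spatial shape")
  if (!all(object@cleanLabel %in% 0:1) || !all(object@observedLabel %in% 0:1))
    msg <- c(msg, "labels must be binary")
  if (!all(is.finite(object@image))) msg <- c(msg, "image must be finite")
  if (length(msg)) msg else TRUE
})

#' A volume record: image, label, voxel spacing and identifier
#'
#' @slot image numeric array H x W x C.
#' @slot label integer H x W matrix in \{0, 1\}.
#' @slot spacing numeric(2), mm per pixel along (row, column).
#' @slot subjectId character identifier.
#' @exportClass VolumeRecord
setClass("VolumeRecord", representation(
  image = "array", label = "matrix", spacing = "numeric",
  subjectId = "character"))

setValidity("VolumeRecord", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L) msg <- c(msg, "image must be a H x W x C array")
  else if (!all(dim(object@label) == d[1:2]))
    msg <- c(msg, "label must match the image's spatial shape")
  if (!all(object@label %in% 0:1)) msg <- c(msg, "label must be binary")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname VolumeRecord-class
#' @param image numeric array H x W x C (a matrix is promoted to one channel).
#' @param label binary H x W matrix.
#' @param spacing numeric(2) pixel spacing in mm.
#' @param subjectId identifier string.
#' @export
volumeRecord <- function(image, label, spacing = c(1, 1), subjectId = "subject") {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  new("VolumeRecord", image = image,
      label = matrix(as.integer(label), nrow(label), ncol(label)),
      spacing = as.numeric(spacing), subjectId = subjectId)
}

#' U-Net architecture configuration
#'
#' Encoder--decoder with skip connections; each resolution level is two 3x3
#' convolutions + ReLU with channel doubling per level. In the Bayesian
#' variant (\code{dropoutRate > 0}, mode not \code{"off"}) one dropout layer
#' sits before each max-pooling and one after each up-convolution.
#'
#' @slot inChannels,nClasses input channels and output classes.
#' @slot depth number of resolution levels (>= 2).
#' @slot baseFilters channels at the first level.
#' @slot dropoutRate dropout probability theta in [0, 1).
#' @slot dropoutMode one of "off", "train_only", "train_and_inference".
#' @exportClass UNetConfig
setClass("UNetConfig", representation(
  inChannels = "integer", nClasses = "integer", depth = "integer",
  baseFilters = "integer", dropoutRate = "numeric", dropoutMode = "character"))

setValidity("UNetConfig", function(object) {
  msg <- character()
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@inChannels < 1L) msg <- c(msg, "inChannels must be >= 1")
  if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@dropoutMode %in% c("off", "train_only", "train_and_inference"))
    msg <- c(msg, "unknown dropoutMode")
  if (length(msg)) msg else TRUE
})

#' @rdname UNetConfig-class
#' @param inChannels,nClasses,depth,baseFilters,dropoutRate,dropoutMode see slots.
#' @export
unetConfig <- function(inChannels = 2L, nClasses = 2L, depth = 3L,
                       baseFilters = 8L, dropoutRate = 0,
                       dropoutMode = c("off", "train_only",
                                       "train_and_inference")) {
  dropoutMode <- match.arg(dropoutMode)
  if (dropoutRate == 0) dropoutMode <- "off"
  new("UNetConfig", inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      dropoutRate = as.numeric(dropoutRate), dropoutMode = dropoutMode)
}

#' @rdname UNetConfig-class
#' @details `bayesianUnetConfig()` is a convenience wrapper selecting the
#'   Monte-Carlo dropout variant (dropout kept active at inference), with the
#'   classic default theta = 0.5.
#' @export
bayesianUnetConfig <- function(inChannels = 2L, nClasses = 2L, depth = 3L,
                               baseFilters = 8L, dropoutRate = 0.5) {
  unetConfig(inChannels, nClasses, depth, baseFilters, dropoutRate,
             dropoutMode = "train_and_inference")
}

#' A (possibly trained) U-Net model
#'
#' @slot weights named list of weight matrices/vectors.
#' @slot config the [UNetConfig-class].
#' @slot fingerprint list with lambda, seed, epochs, lossHistory.
#' @exportClass UNetModel
setClass("UNetModel", representation(
  weights = "list", config = "UNetConfig", fingerprint = "list"))

#' Training configuration
#'
#' Defaults follow the reference optimization protocol: Adam with learning
#' rate 1e-4, weight decay 1e-5, batch size 16. At phantom desk scale
#' (tens of optimizer steps) the benchmark harness overrides the learning
#' rate upward; see the methods vignette.
#'
#' @slot learningRate,weightDecay Adam step size and L2 weight decay.
#' @slot batchSize images per optimizer step.
#' @slot epochs passes over the training set.
#' @slot patchShape integer(2) crop shape, or length 0 for whole images.
#' @slot seed training seed (initialization, shuffling, crops, augmentation,
#'   dropout all flow from it).
#' @slot augment logical; random flips and right-angle rotations.
#' @slot normalizeBy loss denominator: "all" pixels (literal formula) or
#'   "masked" pixels only.
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  learningRate = "numeric", weightDecay = "numeric", batchSize = "integer",
  epochs = "integer", patchShape = "integer", seed = "integer",
  augment = "logical", normalizeBy = "character"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (!object@normalizeBy %in% c("all", "masked"))
    msg <- c(msg, "normalizeBy must be 'all' or 'masked'")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param learningRate,weightDecay,batchSize,epochs,patchShape,seed,augment,normalizeBy
#'   see slots.
#' @export
trainConfig <- function(learningRate = 1e-4, weightDecay = 1e-5,
                        batchSize = 16L, epochs = 20L,
                        patchShape = integer(), seed = 1L, augment = TRUE,
                        normalizeBy = c("all", "masked")) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), patchShape = as.integer(patchShape),
      seed = as.integer(seed), augment = isTRUE(augment),
      normalizeBy = match.arg(normalizeBy))
}

#' Stack of Monte-Carlo softmax samples
#'
#' @slot samples numeric array H x W x classes x T.
#' @slot sourceModelId character.
#' @exportClass ProbabilityStack
setClass("ProbabilityStack", representation(
  samples = "array", sourceModelId = "character"))

setValidity("ProbabilityStack", function(object) {
  d <- dim(object@samples)
  if (length(d) != 4L) return("samples must be a H x W x classes x T array")
  if (d[4] < 1L) return("T must be >= 1")
  if (any(object@samples < -1e-9) || any(object@samples > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  sums <- apply(object@samples, c(1, 2, 4), sum)
  if (max(abs(sums - 1)) > 1e-6)
    return("per-pixel class probabilities must sum to 1")
  TRUE
})

#' Per-pixel class probability map
#'
#' @slot probabilities numeric array H x W x classes, summing to 1 per pixel.
#' @exportClass ProbabilityMap
setClass("ProbabilityMap", representation(probabilities = "array"))

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@probabilities)
  if (length(d) != 3L) return("probabilities must be a H x W x classes array")
  sums <- apply(object@probabilities, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6)
    return("per-pixel class probabilities must sum to 1")
  TRUE
})

probabilityMap <- function(p) new("ProbabilityMap", probabilities = p)

#' Per-pixel uncertainty map
#'
#' Raw maps hold the per-pixel standard deviation of the foreground
#' probability across Monte-Carlo samples; normalized maps are min-max
#' rescaled to [0, 1] per image (a constant raw map normalizes to all
#' zeros -- the certainty convention).
#'
#' @slot values non-negative H x W matrix.
#' @slot normalized logical flag.
#' @slot normalizationStats numeric(2), the (min, max) used (NA if raw).
#' @exportClass UncertaintyMap
setClass("UncertaintyMap", representation(
  values = "matrix", normalized = "logical", normalizationStats = "numeric"))

setValidity("UncertaintyMap", function(object) {
  if (any(object@values < 0)) return("uncertainty values must be >= 0")
  if (object@normalized && any(object@values > 1 + 1e-12))
    return("normalized uncertainty must lie in [0, 1]")
  TRUE
})

#' Binary supervision mask
#'
#' Pixel value 1 means the pixel participates in the loss; 0 means its
#' annotation was judged too uncertain at threshold lambda.
#'
#' @slot mask integer H x W matrix in \{0, 1\}.
#' @slot lambdaUsed the uncertainty threshold.
#' @slot sourceSampleId character.
#' @exportClass SupervisionMask
setClass("SupervisionMask", representation(
  mask = "matrix", lambdaUsed = "numeric", sourceSampleId = "character"))

setValidity("SupervisionMask", function(object) {
  if (!all(object@mask %in% 0:1)) return("mask must be binary")
  if (object@lambdaUsed < 0 || object@lambdaUsed > 1)
    return("lambda must lie in [0, 1]")
  TRUE
})

#' Lambda thresholds assigned to ensemble members
#'
#' @slot lambdas numeric(K) thresholds in [0, 1].
#' @slot grid the candidate set sampled from.
#' @slot seed sampling seed.
#' @exportClass LambdaSchedule
setClass("LambdaSchedule", representation(
  lambdas = "numeric", grid = "numeric", seed = "integer"))

setValidity("LambdaSchedule", function(object) {
  if (any(object@lambdas < 0 | object@lambdas > 1))
    return("all lambdas must lie in [0, 1]")
  if (length(object@lambdas) < 1L) return("schedule must not be empty")
  TRUE
})

#' An ensemble of base segmentation models
#'
#' @slot members list of [UNetModel-class], one per lambda.
#' @slot schedule the [LambdaSchedule-class].
#' @slot fusion fusion rule; only "mean_probability".
#' @exportClass EnsembleModel
setClass("EnsembleModel", representation(
  members = "list", schedule = "LambdaSchedule", fusion = "character"))

setValidity("EnsembleModel", function(object) {
  if (length(object@members) != length(object@schedule@lambdas))
    return("one lambda per member required")
  if (!identical(object@fusion, "mean_probability"))
    return("unsupported fusion rule")
  TRUE
})

#' Fused ensemble prediction
#'
#' @slot fusedProbability the averaged [ProbabilityMap-class].
#' @slot segmentation binary H x W matrix (argmax of the fused map;
#'   a foreground probability of exactly 0.5 resolves to foreground).
#' @slot uncertainty epistemic [UncertaintyMap-class]: per-pixel SD of the
#'   member foreground probabilities.
#' @slot memberProbabilities list of the K member maps.
#' @exportClass EnsemblePrediction
setClass("EnsemblePrediction", representation(
  fusedProbability = "ProbabilityMap", segmentation = "matrix",
  uncertainty = "UncertaintyMap", memberProbabilities = "list"))

#' Sliding-window tiling plan
#'
#' Window origins at stride = patch/2 (50% overlap), with the final window
#' clamped inside the image so every pixel is covered on the original grid.
#'
#' @slot imageShape,patchShape,stride integer(2).
#' @slot origins integer matrix (n x 2) of 1-based window origins.
#' @exportClass TilingPlan
setClass("TilingPlan", representation(
  imageShape = "integer", patchShape = "integer", stride = "integer",
  origins = "matrix"))

#' Benchmark specification
#'
#' Defines the standard phantom benchmark: train/test phantoms generated from
#' one configuration, then each requested method trained and evaluated for
#' each ensemble size and repeat (one master seed per repeat).
#'
#' @slot phantomConfig the phantom generator configuration.
#' @slot nTrain,nTest dataset sizes.
#' @slot KValues ensemble sizes to sweep.
#' @slot repeats number of repeated trainings.
#' @slot masterSeeds integer vector, one per repeat.
#' @slot methods subset of c("saen", "rwi", "single").
#' @slot unetConfig,oracleConfig,trainConfig model/training settings.
#' @slot mcSamples T, Monte-Carlo samples for the uncertainty oracle.
#' @slot lambdaGrid candidate lambda set.
#' @exportClass BenchmarkSpec
setClass("BenchmarkSpec", representation(
  phantomConfig = "PhantomConfig", nTrain = "integer", nTest = "integer",
  KValues = "integer", repeats = "integer", masterSeeds = "integer",
  methods = "character", unetConfig = "UNetConfig",
  oracleConfig = "UNetConfig", trainConfig = "TrainConfig",
  mcSamples = "integer", lambdaGrid = "numeric"))

setValidity("BenchmarkSpec", function(object) {
  msg <- character()
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (length(object@KValues) < 1L) msg <- c(msg, "KValues must be non-empty")
  if (length(object@masterSeeds) != object@repeats)
    msg <- c(msg, "need one master seed per repeat")
  if (!all(object@methods %in% c("saen", "rwi", "single")))
    msg <- c(msg, "methods must be a subset of saen/rwi/single")
  if (length(msg)) msg else TRUE
})
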