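# Mask-gated cross-entropy training of a single base model, and the
# uncertainty-oracle training that precedes mask generation.

.asProbArray <- function(p) {
  if (is(p, "ProbabilityMap")) p@probabilities
  else if (is.array(p) && length(dim(p)) == 3L) p
  else stop("probabilities must be a ProbabilityMap or H x W x C array")
}

.asMaskMatrix <- function(m) {
  if (is(m, "SupervisionMask")) m <- m@mask
  if (!.isBinaryMatrix(m)) stop("supervision mask must be a binary matrix")
  m
}

#' Mask-gated cross-entropy loss
#'
#' The ensemble's base learners minimize
#' \deqn{L = -\frac{1}{N}\frac{1}{M} \sum_n \sum_m \mathrm{Mask}(x_{n,m})
#'   \, \log p_{n,m}^{(y_{n,m})}}
#' i.e. ordinary per-pixel cross-entropy in which a binary mask removes the
#' terms of pixels whose annotation was judged too uncertain. With an
#' all-ones mask this is exactly the mean per-pixel cross-entropy; a fully
#' zero mask yields 0 with a warning. Probabilities are clipped at `eps`
#' before the log. The denominator uses the total pixel count `M` by default
#' (the literal formula); `normalizeBy = "masked"` divides by the per-image
#' masked-pixel count instead.
#'
#' @param probs a [ProbabilityMap-class] / H x W x C array, or a list of
#'   them (a batch).
#' @param labels integer H x W matrix of class indices in `0..C-1` (for the
#'   binary case: 0 background, 1 foreground), or a list.
#' @param masks binary H x W matrix / [SupervisionMask-class] or list;
#'   NULL means all ones.
#' @param eps clipping floor for the probabilities.
#' @param normalizeBy `"all"` or `"masked"`, see above.
#' @return The scalar loss.
#' @examples
#' p <- array(c(0.8, 0.3, 0.2, 0.7), dim = c(1, 2, 2))
#' maskedCrossEntropy(p, labels = matrix(c(0L, 1L), 1), masks = NULL)
#' @export
maskedCrossEntropy <- function(probs, labels, masks = NULL, eps = 1e-7,
                               normalizeBy = c("all", "masked")) {
  normalizeBy <- match.arg(normalizeBy)
  if (!is.list(probs)) {
    probs <- list(probs); labels <- list(labels)
    if (!is.null(masks)) masks <- list(masks)
  }
  N <- length(probs)
  total <- 0
  anyMasked <- FALSE
  for (n in seq_len(N)) {
    p <- .asProbArray(probs[[n]])
    y <- labels[[n]]
    m <- if (is.null(masks)) matrix(1L, nrow(y), ncol(y))
         else .asMaskMatrix(masks[[n]])
    if (!all(dim(p)[1:2] == dim(y)) || !all(dim(y) == dim(m)))
      stop("shape mismatch: probs ", paste(dim(p), collapse = "x"),
           ", labels ", paste(dim(y), collapse = "x"),
           ", mask ", paste(dim(m), collapse = "x"))
    C <- dim(p)[3]
    if (any(y < 0 | y >= C)) stop("labels must lie in 0..C-1")
    idx <- cbind(as.vector(row(y)), as.vector(col(y)), as.vector(y) + 1L)
    pTrue <- pmax(p[idx], eps)
    denom <- if (normalizeBy == "all") length(y) else sum(m)
    if (denom > 0) {
      total <- total - sum(as.vector(m) * log(pTrue)) / denom
      anyMasked <- anyMasked || any(m != 0)
    }
  }
  if (!anyMasked) {
    warning("all supervision masks are zero; loss is 0")
    return(0)
  }
  total / N
}

# Adam optimizer state and update (bias-corrected, beta1 = 0.9,
# beta2 = 0.999). Weight decay enters as a plain L2 term added to the
# gradient. `[] <-` keeps the kernel-size attributes on the weight matrices.
.adamInit <- function(weights)
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)

.adamStep <- function(weights, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]] + wd * weights[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    weights[[nm]][] <- weights[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(weights = weights, state = state)
}

.trainImage <- function(s) s@image

.trainLabel <- function(s) {
  if (is(s, "PhantomSample")) s@observedLabel else s@label
}

#' Train one base segmentation model
#'
#' Optimizes the mask-gated cross-entropy with Adam under the configured
#' protocol: per epoch the samples are shuffled and consumed in batches;
#' each image is (optionally) randomly cropped and augmented, with the
#' identical geometric transform applied to image, label and supervision
#' mask. Input intensities are Gaussian-normalized per channel once up
#' front. Fully deterministic given `trainConfig@seed` (single-threaded
#' BLAS).
#'
#' @param samples list of [PhantomSample-class] (trained on their observed
#'   labels) or [VolumeRecord-class].
#' @param masks list of [SupervisionMask-class] (or binary matrices), one
#'   per sample, or NULL for full supervision.
#' @param unetConfig a [UNetConfig-class].
#' @param trainConfig a [TrainConfig-class].
#' @param lambda the uncertainty threshold recorded in the fingerprint
#'   (NA when training without masks).
#' @param normalizeInput standardize intensities before training.
#' @return A trained [UNetModel-class]; the fingerprint records lambda,
#'   seed, epochs and the per-epoch mean training loss.
#' @export
trainBaseModel <- function(samples, masks = NULL, unetConfig, trainConfig,
                           lambda = NA_real_, normalizeInput = TRUE) {
  validObject(trainConfig)
  n <- length(samples)
  if (!is.null(masks)) {
    if (length(masks) != n)
      stop("need one supervision mask per training image (",
           length(masks), " masks for ", n, " images)")
    bad <- which(vapply(masks, is.null, logical(1)))
    if (length(bad))
      stop("missing supervision mask for image(s) ",
           paste(bad, collapse = ", "))
  }
  images <- lapply(samples, function(s) {
    x <- .trainImage(s)
    if (normalizeInput) gaussianNormalize(x) else x
  })
  labels <- lapply(samples, .trainLabel)
  maskMs <- if (is.null(masks)) lapply(labels, function(l) 0L * l + 1L)
            else lapply(masks, .asMaskMatrix)
  cfg <- unetConfig
  model <- buildUnet(cfg, seed = .deriveSeed(trainConfig@seed, 0L))
  model@fingerprint <- list(lambda = as.numeric(lambda),
                            seed = trainConfig@seed,
                            epochs = trainConfig@epochs,
                            lossHistory = numeric())
  if (trainConfig@epochs == 0L) return(model)

  dropoutActive <- cfg@dropoutRate > 0 && cfg@dropoutMode != "off"
  patch <- trainConfig@patchShape
  weights <- model@weights
  state <- .adamInit(weights)
  lossHistory <- numeric(trainConfig@epochs)

  .withSeed(trainConfig@seed, {
    for (epoch in seq_len(trainConfig@epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / trainConfig@batchSize))
      epochLoss <- numeric(length(batches))
      for (b in seq_along(batches)) {
        bi <- list(); bl <- list(); bm <- list()
        for (i in batches[[b]]) {
          img <- images[[i]]; lab <- labels[[i]]; msk <- maskMs[[i]]
          if (length(patch) == 2L && any(patch < dim(lab))) {
            cr <- randomCrop(img, lab, msk, patch)
            img <- cr$image; lab <- cr$label; msk <- cr$mask
          }
          if (trainConfig@augment) {
            au <- augmentPatch(img, lab, msk)
            img <- au$image; lab <- au$label; msk <- au$mask
          }
          bi[[length(bi) + 1L]] <- img
          bl[[length(bl) + 1L]] <- lab
          bm[[length(bm) + 1L]] <- msk
        }
        st <- .unetTrainStepCpp(weights, cfg@depth, cfg@dropoutRate,
                                dropoutActive, bi, bl, bm,
                                trainConfig@normalizeBy, 1e-7)
        upd <- .adamStep(weights, st$grads, state,
                         trainConfig@learningRate, trainConfig@weightDecay)
        weights <- upd$weights
        state <- upd$state
        epochLoss[b] <- st$loss
      }
      lossHistory[epoch] <- mean(epochLoss)
    }
  })
  model@weights <- weights
  model@fingerprint$lossHistory <- lossHistory
  model
}

#' Train the Bayesian uncertainty oracle
#'
#' Trains the dropout-bearing U-Net on the full dataset with all-ones masks
#' (standard cross-entropy). The returned model, with dropout kept active at
#' inference, supplies the Monte-Carlo annotation-uncertainty maps from
#' which supervision masks are generated. Its fingerprint records
#' lambda = 1 (full supervision).
#'
#' @param samples training samples as in [trainBaseModel()].
#' @param unetConfig a [UNetConfig-class] with `dropoutRate > 0`.
#' @param trainConfig a [TrainConfig-class].
#' @return A trained Bayesian [UNetModel-class] (dropout mode
#'   `"train_and_inference"`).
#' @export
trainUncertaintyOracle <- function(samples, unetConfig, trainConfig) {
  if (unetConfig@dropoutRate <= 0)
    stop("the uncertainty oracle needs dropoutRate > 0: without dropout ",
         "there is no posterior to sample")
  cfg <- unetConfig
  cfg@dropoutMode <- "train_and_inference"
  trainBaseModel(samples, masks = NULL, unetConfig = cfg,
                 trainConfig = trainConfig, lambda = 1.0)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the weights, the architecture configuration and the
#' training fingerprint, so a model can be reloaded by file path alone.
#'
#' @param model a [UNetModel-class].
#' @param path checkpoint file path (`.rds`).
#' @return `writeModelCheckpoint`: invisibly, `path`;
#'   `readModelCheckpoint`: the [UNetModel-class].
#' @export
writeModelCheckpoint <- function(model, path) {
  cfg <- model@config
  saveRDS(list(weights = model@weights,
               config = list(inChannels = cfg@inChannels,
                             nClasses = cfg@nClasses, depth = cfg@depth,
                             baseFilters = cfg@baseFilters,
                             dropoutRate = cfg@dropoutRate,
                             dropoutMode = cfg@dropoutMode),
               fingerprint = model@fingerprint), path)
  invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(unetConfig, x$config)
  new("UNetModel", weights = x$weights, config = cfg,
      fingerprint = x$fingerprint)
}
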