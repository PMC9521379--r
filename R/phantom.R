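# Synthetic lesion phantoms with boundary-concentrated annotation noise.
#
# Two lesion kinds emulate the spatial uncertainty structure of white matter
# hyperintensities: "periventricular" lesions sit in a central vertical band
# and have hard intensity edges (annotations there are reliable), "deep"
# lesions sit outside the band and have Gaussian intensity ramps (ambiguous
# boundaries). The observed annotation is the clean label whose boundary is
# displaced by a smooth Gaussian random field, so rater errors are spatially
# correlated and confined to a band around the true boundary.

# Maximum radial extent of a perturbed ellipse relative to its nominal radius
# (axis ratio <= 1, sinusoidal perturbation amplitude 0.15).
.lesionExtentFactor <- 1.15

.checkLesionFit <- function(config) {
  need <- 2 * ceiling(.lesionExtentFactor * config@lesionRadiusRange[2]) + 4
  if (need > config@imageHeight)
    stop("largest lesion (extent ", need,
         " px) cannot fit image_height = ", config@imageHeight)
  if (need > config@imageWidth)
    stop("largest lesion (extent ", need,
         " px) cannot fit image_width = ", config@imageWidth)
  invisible(TRUE)
}

# Rasterize one warped ellipse: center (cy, cx), nominal radius r, axis ratio
# q, orientation phi, sinusoidal boundary perturbation of order k and phase.
.lesionMask <- function(H, W, cy, cx, r, q, phi, k, phase) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(phi) * yy + sin(phi) * xx
  v <- -sin(phi) * yy + cos(phi) * xx
  rho <- sqrt((u / r)^2 + (v / (r * q))^2)
  psi <- atan2(v, u)
  rho <= 1 + 0.15 * sin(k * psi + phase)
}

#' Generate one synthetic phantom sample
#'
#' Deterministic given `(config, seed)`. Lesion centers are rejection-sampled
#' to limit overlap; periventricular lesions are constrained to the central
#' vertical quarter-band of the image, deep lesions to its complement.
#' Channel 1 carries the full lesion contrast (amplitude 1 over background 0),
#' further channels half of it. When `annotationJitterSigma > 0` the observed
#' label is obtained by thresholding the clean label's signed distance
#' transform plus a smooth random field clipped at twice the jitter scale, so
#' all clean/observed disagreements lie within `3 * annotationJitterSigma`
#' pixels of a clean-label boundary pixel and lesion cores are preserved.
#'
#' @param config a [PhantomConfig-class].
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return A [PhantomSample-class].
#' @examples
#' s <- generateSample(phantomConfig(), seed = 7)
#' range(cleanLabel(s))
#' @export
generateSample <- function(config, seed = config@seed) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  .checkLesionFit(config)
  .withSeed(seed, {
    H <- config@imageHeight; W <- config@imageWidth
    bandHalf <- max(2, round(W / 8))
    bandLo <- W / 2 - bandHalf; bandHi <- W / 2 + bandHalf
    inventory <- data.frame(y = numeric(), x = numeric(), radius = numeric(),
                            kind = character(), stringsAsFactors = FALSE)
    kinds <- c(rep("periventricular", config@nPeriventricular),
               rep("deep", config@nDeep))
    cleanLabel <- matrix(0L, H, W)
    sharpIntensity <- matrix(0, H, W)
    rampIntensity <- matrix(0, H, W)
    for (kind in kinds) {
      r <- stats::runif(1, config@lesionRadiusRange[1],
                        config@lesionRadiusRange[2])
      ext <- .lesionExtentFactor * r + 2
      placed <- FALSE
      for (try in seq_len(60)) {
        cy <- stats::runif(1, ext, H - ext + 1)
        cx <- if (kind == "periventricular") {
          lo <- max(ext, bandLo); hi <- min(W - ext + 1, bandHi)
          if (lo >= hi) W / 2 else stats::runif(1, lo, hi)
        } else {
          # sample outside the central band; fall back to the whole valid
          # range when the band leaves no room
          left <- c(ext, min(W - ext + 1, bandLo))
          right <- c(max(ext, bandHi), W - ext + 1)
          lens <- c(max(0, diff(left)), max(0, diff(right)))
          if (sum(lens) <= 0) {
            stats::runif(1, ext, W - ext + 1)
          } else if (stats::runif(1) < lens[1] / sum(lens)) {
            stats::runif(1, left[1], left[2])
          } else {
            stats::runif(1, right[1], right[2])
          }
        }
        if (nrow(inventory) == 0 ||
            all(sqrt((inventory$y - cy)^2 + (inventory$x - cx)^2) >
                  0.8 * (inventory$radius + r)) || try == 60) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      q <- stats::runif(1, 0.6, 1)
      phi <- stats::runif(1, 0, pi)
      kOrd <- sample(2:4, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      m <- .lesionMask(H, W, cy, cx, r, q, phi, kOrd, phase)
      cleanLabel[m] <- 1L
      if (kind == "periventricular") {
        sharpIntensity[m] <- 1
      } else {
        rampIntensity <- pmax(rampIntensity,
                              .gaussianBlur(matrix(as.numeric(m), H, W),
                                            config@boundaryBlurSigma))
      }
      inventory <- rbind(inventory,
                         data.frame(y = cy, x = cx, radius = r, kind = kind,
                                    stringsAsFactors = FALSE))
    }
    contrast <- pmax(sharpIntensity, rampIntensity)
    image <- array(0, dim = c(H, W, config@nChannels))
    for (ch in seq_len(config@nChannels)) {
      amp <- if (ch == 1) 1 else 0.5
      image[, , ch] <- amp * contrast +
        stats::rnorm(H * W, sd = config@noiseSd)
    }
    observed <- .jitterLabel(cleanLabel, config@annotationJitterSigma)
    new("PhantomSample", image = image, cleanLabel = cleanLabel,
        observedLabel = observed, lesionInventory = inventory,
        seed = as.integer(seed))
  })
}

# Displace the label boundary by a smooth random field: threshold the signed
# distance transform (positive inside) plus the field. The field is scaled to
# SD = sigma and clipped at +/- 2 sigma, which confines every flipped pixel
# to within 2 sigma (Euclidean) of a clean boundary pixel and leaves lesion
# interiors deeper than 2 sigma untouched.
.jitterLabel <- function(label, sigma) {
  if (sigma <= 0) return(label)
  fg <- label != 0
  if (!any(fg) || all(fg)) return(label)
  dIn <- .distanceTo(!fg)    # distance of fg pixels to background
  dOut <- .distanceTo(fg)    # distance of bg pixels to foreground
  sdt <- ifelse(fg, dIn, -dOut)
  g <- .gaussianBlur(matrix(stats::rnorm(length(label)), nrow(label)), 3)
  s <- stats::sd(as.vector(g))
  if (s > 0) g <- g / s * sigma
  g <- pmin(pmax(g, -2 * sigma), 2 * sigma)
  .asBinaryInteger(sdt + g > 0)
}

#' Generate a reproducible phantom dataset
#'
#' Per-sample seeds are derived from the master seed, so samples are mutually
#' independent and the whole dataset is reproducible bit-exactly.
#'
#' @param config a [PhantomConfig-class].
#' @param nSamples number of samples (>= 1).
#' @param seed master seed.
#' @return A list of [PhantomSample-class] objects.
#' @export
generateDataset <- function(config, nSamples, seed = config@seed) {
  stopifnot(nSamples >= 1)
  lapply(seq_len(nSamples), function(i)
    generateSample(config, seed = .deriveSeed(seed, i)))
}

#' Convert a phantom sample to a volume record
#'
#' @param sample a [PhantomSample-class].
#' @param which which annotation to carry as the record's label: the noisy
#'   `"observed"` one (used for training) or the `"clean"` one (used for
#'   evaluation).
#' @param spacing pixel spacing in mm.
#' @param subjectId identifier.
#' @return A [VolumeRecord-class].
#' @export
asVolumeRecord <- function(sample, which = c("observed", "clean"),
                           spacing = c(1, 1), subjectId = "phantom") {
  which <- match.arg(which)
  lab <- if (which == "observed") sample@observedLabel else sample@cleanLabel
  volumeRecord(sample@image, lab, spacing = spacing, subjectId = subjectId)
}

#' Write a phantom dataset to disk as NIfTI plus a manifest
#'
#' One NIfTI file per channel plus clean and observed labels per sample, and
#' a tab-separated manifest (sample_id, file paths, lesion counts).
#'
#' @param samples list of [PhantomSample-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
writePhantomDataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- sprintf("phantom_%03d", i)
    nch <- dim(s@image)[3]
    chPaths <- vapply(seq_len(nch), function(ch) {
      p <- file.path(dir, sprintf("%s_ch%d.nii.gz", id, ch - 1))
      RNifti::writeNifti(RNifti::asNifti(s@image[, , ch]), p)
      p
    }, character(1))
    cleanPath <- file.path(dir, sprintf("%s_clean.nii.gz", id))
    obsPath <- file.path(dir, sprintf("%s_observed.nii.gz", id))
    RNifti::writeNifti(RNifti::asNifti(s@cleanLabel), cleanPath)
    RNifti::writeNifti(RNifti::asNifti(s@observedLabel), obsPath)
    data.frame(sample_id = id, channels = paste(chPaths, collapse = ";"),
               clean_label = cleanPath, observed_label = obsPath,
               n_lesions = nrow(s@lesionInventory), seed = s@seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset back from a manifest directory
#'
#' @param dir directory holding `manifest.tsv` as written by
#'   [writePhantomDataset()].
#' @return A list of [PhantomSample-class] objects (lesion inventories are not
#'   persisted and come back empty).
#' @export
readPhantomDataset <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    chPaths <- strsplit(manifest$channels[i], ";")[[1]]
    channels <- lapply(chPaths, function(p) {
      v <- RNifti::readNifti(p)
      matrix(as.numeric(v), nrow(v))
    })
    image <- array(unlist(channels), dim = c(dim(channels[[1]]),
                                             length(channels)))
    readLab <- function(p) {
      v <- RNifti::readNifti(p)
      .asBinaryInteger(matrix(as.numeric(v), nrow(v)))
    }
    new("PhantomSample", image = image,
        cleanLabel = readLab(manifest$clean_label[i]),
        observedLabel = readLab(manifest$observed_label[i]),
        lesionInventory = data.frame(y = numeric(), x = numeric(),
                                     radius = numeric(), kind = character(),
                                     stringsAsFactors = FALSE),
        seed = as.integer(manifest$seed[i]))
  })
}
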