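# NIfTI I/O, intensity normalization, patch cropping and augmentation.

#' Write / read a volume record as NIfTI
#'
#' Channels are written as separate files (`<id>_ch<k>.nii.gz`) next to the
#' label (`<id>_label.nii.gz`); pixel spacing goes into the NIfTI header.
#' Voxel values round-trip bit-exactly (float64 storage).
#'
#' @param record a [VolumeRecord-class].
#' @param dir output directory.
#' @param id file stem; defaults to the record's subject id.
#' @return `writeVolumeRecord`: invisibly, the written paths.
#' @export
writeVolumeRecord <- function(record, dir, id = record@subjectId) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- dim(record@image)[3]
  writeOne <- function(data, p, datatype) {
    nii <- RNifti::asNifti(data)
    RNifti::pixdim(nii) <- record@spacing
    RNifti::writeNifti(nii, p, datatype = datatype)
    p
  }
  chPaths <- vapply(seq_len(nch), function(ch)
    writeOne(record@image[, , ch],
             file.path(dir, sprintf("%s_ch%d.nii.gz", id, ch - 1)), "double"),
    character(1))
  labPath <- writeOne(record@label,
                      file.path(dir, sprintf("%s_label.nii.gz", id)), "uint8")
  invisible(c(chPaths, labPath))
}

#' @rdname writeVolumeRecord
#' @param paths character vector of channel paths followed by the label path
#'   (as returned by `writeVolumeRecord`).
#' @param subjectId identifier for the reconstructed record.
#' @export
readVolumeRecord <- function(paths, subjectId = "subject") {
  n <- length(paths)
  channels <- lapply(paths[-n], function(p) {
    v <- RNifti::readNifti(p)
    matrix(as.numeric(v), nrow(v))
  })
  lab <- RNifti::readNifti(paths[n])
  spacing <- RNifti::pixdim(lab)[1:2]
  volumeRecord(array(unlist(channels),
                     dim = c(dim(channels[[1]]), length(channels))),
               .asBinaryInteger(matrix(as.numeric(lab), nrow(lab))),
               spacing = spacing, subjectId = subjectId)
}

#' Per-channel Gaussian intensity normalization
#'
#' Standardizes each channel of a volume to mean 0 and SD 1, with statistics
#' computed per subject per channel. The population (divide-by-n) SD is
#' used, so e.g. a channel holding the values \{0, 2\} in equal counts maps
#' exactly to \{-1, +1\}.
#'
#' @param volume numeric array H x W x C, a matrix (single channel), or a
#'   [VolumeRecord-class] / [PhantomSample-class] (normalized in place).
#' @return Same type as the input, intensity-standardized.
#' @examples
#' v <- array(rnorm(2 * 16, mean = 5, sd = 3), dim = c(4, 4, 2))
#' z <- gaussianNormalize(v)
#' round(apply(z, 3, mean), 10)
#' @export
gaussianNormalize <- function(volume) {
  if (is(volume, "PhantomSample") || is(volume, "VolumeRecord")) {
    volume@image <- gaussianNormalize(volume@image)
    return(volume)
  }
  wasMatrix <- is.matrix(volume)
  if (wasMatrix) volume <- array(volume, dim = c(dim(volume), 1L))
  for (ch in seq_len(dim(volume)[3])) {
    v <- volume[, , ch]
    s <- sqrt(mean((v - mean(v))^2))
    if (!is.finite(s) || s == 0)
      stop("channel ", ch, " is constant; cannot normalize")
    volume[, , ch] <- (v - mean(v)) / s
  }
  if (wasMatrix) volume[, , 1] else volume
}

#' Random patch crop
#'
#' Cuts an image patch together with the co-registered label and supervision
#' mask at a uniformly drawn offset; deterministic given `seed`. With
#' `lesionBiased = TRUE`, at least half of the draws are re-sampled (up to 10
#' tries) until the label patch contains foreground, useful when lesions are
#' sparse.
#'
#' @param image numeric array H x W x C.
#' @param label binary H x W matrix.
#' @param mask optional binary H x W matrix (defaults to all ones).
#' @param patchShape integer(2) patch size.
#' @param seed integer seed (optional; when NULL the current RNG stream is
#'   used, e.g. inside a seeded training loop).
#' @param lesionBiased logical, see Details.
#' @return list with `image`, `label`, `mask` patches and the 1-based `offset`.
#' @export
randomCrop <- function(image, label, mask = NULL, patchShape, seed = NULL,
                       lesionBiased = FALSE) {
  d <- dim(image)
  patchShape <- as.integer(patchShape)
  if (any(patchShape > d[1:2]))
    stop("patch shape (", paste(patchShape, collapse = "x"),
         ") exceeds image shape (", paste(d[1:2], collapse = "x"), ")")
  if (is.null(mask)) mask <- matrix(1L, d[1], d[2])
  draw <- function() {
    c(sample.int(d[1] - patchShape[1] + 1L, 1L),
      sample.int(d[2] - patchShape[2] + 1L, 1L))
  }
  body <- function() {
    off <- draw()
    if (lesionBiased && stats::runif(1) < 0.5) {
      for (i in seq_len(10)) {
        ys <- off[1]:(off[1] + patchShape[1] - 1L)
        xs <- off[2]:(off[2] + patchShape[2] - 1L)
        if (any(label[ys, xs] != 0)) break
        off <- draw()
      }
    }
    ys <- off[1]:(off[1] + patchShape[1] - 1L)
    xs <- off[2]:(off[2] + patchShape[2] - 1L)
    list(image = image[ys, xs, , drop = FALSE], label = label[ys, xs],
         mask = mask[ys, xs], offset = off)
  }
  if (is.null(seed)) body() else .withSeed(seed, body())
}

#' Apply one geometric transform jointly to image, label and mask
#'
#' Flips and quarter-turn rotations are lossless for binary maps (pure index
#' permutations), so label and mask stay exactly binary. Quarter turns other
#' than 180 degrees require square patches.
#'
#' @param image numeric array H x W x C.
#' @param label,mask binary H x W matrices (mask may be NULL).
#' @param flip1,flip2 flip along the first (vertical flip) / second
#'   (horizontal flip, "mirroring") axis.
#' @param rotQuarter number of 90-degree counter-clockwise turns (0--3).
#' @return list with transformed `image`, `label`, `mask`.
#' @export
applyPatchTransform <- function(image, label, mask = NULL, flip1 = FALSE,
                                flip2 = FALSE, rotQuarter = 0L) {
  rotQuarter <- as.integer(rotQuarter) %% 4L
  if (rotQuarter %in% c(1L, 3L) && nrow(label) != ncol(label))
    stop("quarter-turn rotation requires square patches")
  tfm <- function(m) {
    if (flip1) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (flip2) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    for (i in seq_len(rotQuarter))
      m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]   # 90 deg CCW
    m
  }
  img <- array(0, dim = c(dim(tfm(label)), dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) img[, , ch] <- tfm(image[, , ch])
  list(image = img, label = tfm(label),
       mask = if (is.null(mask)) NULL else tfm(mask))
}

#' Random augmentation: flips and right-angle rotations
#'
#' Each axis is flipped with probability `flipProb`; the rotation angle is
#' uniform over \{0, 90, 180, 270\} degrees (restricted to \{0, 180\} for
#' non-square patches). All three inputs receive the identical transform.
#'
#' @inheritParams applyPatchTransform
#' @param seed optional seed; NULL draws from the current RNG stream.
#' @param flipProb per-axis flip probability.
#' @param rotate logical; include random quarter-turn rotation.
#' @return list with `image`, `label`, `mask`.
#' @export
augmentPatch <- function(image, label, mask = NULL, seed = NULL,
                         flipProb = 0.5, rotate = TRUE) {
  body <- function() {
    f1 <- stats::runif(1) < flipProb
    f2 <- stats::runif(1) < flipProb
    rq <- if (!rotate) 0L
    else if (nrow(label) == ncol(label)) sample(0:3, 1)
    else sample(c(0L, 2L), 1)
    applyPatchTransform(image, label, mask, f1, f2, rq)
  }
  if (is.null(seed)) body() else .withSeed(seed, body())
}
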