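# Internal helpers: scoped RNG, seed derivation, separable Gaussian blur,
# boundary extraction and distance maps.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and an index; stays inside the
# 32-bit signed range and away from 0.
.deriveSeed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 69069 + as.numeric(index) * 7919) %%
               2147483399 + 1)
}

# Separable Gaussian blur with edge replication; radius = ceiling(3 sigma).
.gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(x) {            # columns of x convolved with k
    n <- nrow(x)
    pad <- rbind(x[rep(1L, r), , drop = FALSE], x,
                 x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(m))))
}

# Boundary pixels of a binary matrix. "inner": foreground pixels touching
# background (8-neighborhood); "outer": background pixels touching
# foreground; "both": union. Image borders do not count as background.
.boundaryPixels <- function(mask, type = c("inner", "outer", "both")) {
  type <- match.arg(type)
  H <- nrow(mask); W <- ncol(mask)
  mask <- mask != 0
  shift <- function(m, dy, dx, fill) {
    out <- matrix(fill, H, W)
    ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
    ok.y <- ys >= 1L & ys <= H; ok.x <- xs >= 1L & xs <= W
    out[ok.y, ok.x] <- m[ys[ok.y], xs[ok.x]]
    out
  }
  anyBgNeighbor <- matrix(FALSE, H, W)
  anyFgNeighbor <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- shift(mask, dy, dx, NA)
    anyBgNeighbor <- anyBgNeighbor | (!nb & !is.na(nb))
    anyFgNeighbor <- anyFgNeighbor | (nb & !is.na(nb))
  }
  inner <- mask & anyBgNeighbor
  outer <- !mask & anyFgNeighbor
  switch(type, inner = inner, outer = outer, both = inner | outer)
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
# pixel of `target`; Inf if target is empty.
.distanceTo <- function(target) {
  if (!any(target)) return(matrix(Inf, nrow(target), ncol(target)))
  # distmap gives, for each nonzero pixel, the distance to the nearest zero
  # pixel; invert so target pixels are the zeros.
  d <- EBImage::distmap(matrix(as.numeric(!target), nrow(target)))
  matrix(as.numeric(d), nrow(target))
}

#' Distance to the nearest label boundary
#'
#' Exact Euclidean distance (pixels) from every pixel to the nearest
#' boundary pixel of a binary label, where the boundary is the union of
#' foreground pixels touching background and background pixels touching
#' foreground (8-neighborhood). Infinite when the label has no boundary
#' (all foreground or all background). Used to quantify how far annotation
#' disagreements and prediction uncertainty sit from the true lesion edge.
#'
#' @param label binary matrix.
#' @return Numeric matrix of distances.
#' @export
boundaryDistance <- function(label) {
  .distanceTo(.boundaryPixels(label, "both"))
}

.boundaryDistance <- boundaryDistance

# Softmax over the 3rd (class) axis of an H x W x C array.
.softmax3 <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1]
  if (C > 1) for (k in 2:C) m <- pmax(m, z[, , k])
  e <- exp(z - as.vector(m))
  s <- e[, , 1]
  if (C > 1) for (k in 2:C) s <- s + e[, , k]
  e / as.vector(s)
}

.isBinaryMatrix <- function(m) is.matrix(m) && all(m %in% 0:1)

.asBinaryInteger <- function(m) matrix(as.integer(m != 0), nrow(m), ncol(m))
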