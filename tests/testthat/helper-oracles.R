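# Independent brute-force oracles shared across test files. These are kept
# deliberately naive (explicit loops) so they cannot share code paths with
# the implementations they check.

# triple-loop masked cross-entropy
loopLoss <- function(probsList, labelsList, masksList, eps = 1e-7) {
  N <- length(probsList)
  total <- 0
  for (n in seq_len(N)) {
    p <- probsList[[n]]; y <- labelsList[[n]]; m <- masksList[[n]]
    acc <- 0
    for (i in seq_len(nrow(y))) {
      for (j in seq_len(ncol(y))) {
        for (c in seq_len(dim(p)[3])) {
          onehot <- as.numeric(y[i, j] == c - 1)
          acc <- acc + m[i, j] * onehot * log(max(p[i, j, c], eps))
        }
      }
    }
    total <- total - acc / length(y)
  }
  total / N
}

# all-pairs boundary-distance 95th percentile (boundary: foreground pixel
# with an 8-neighbor background pixel)
h95Oracle <- function(pred, gt, spacing = c(1, 1)) {
  boundary <- function(m) {
    out <- NULL
    for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
      if (m[y, x] == 0) next
      nb <- m[max(1, y - 1):min(nrow(m), y + 1),
              max(1, x - 1):min(ncol(m), x + 1)]
      if (any(nb == 0)) out <- rbind(out, c(y, x))
    }
    out
  }
  bp <- boundary(pred); bg <- boundary(gt)
  dmat <- matrix(0, nrow(bp), nrow(bg))
  for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bg)))
    dmat[i, j] <- sqrt(sum(((bp[i, ] - bg[j, ]) * spacing)^2))
  max(quantile(apply(dmat, 1, min), 0.95, names = FALSE),
      quantile(apply(dmat, 2, min), 0.95, names = FALSE))
}
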