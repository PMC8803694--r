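# Internal helpers shared across modules.

# World coordinates (mm) of voxel centers: voxel i (1-based) spans
# [(i-1)*s, i*s], center at (i-0.5)*s. Returns an n x 3 matrix for the given
# 1-based array indices (n x 3 integer matrix or linear indices).
voxelCentersMM <- function(idx, dim, spacing) {
  if (is.null(dim(idx))) idx <- arrayInd(idx, dim)
  sweep(idx - 0.5, 2, spacing, "*")
}

# Connected components of `mask` (26- or 6-connectivity); optionally voxels
# only join when `values` agree (grey-level zones). Returns an integer array
# the same shape as mask with components labelled 1..k in scan order.
labelComponents <- function(mask, connectivity = 26L, values = NULL) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  if (is.null(values)) {
    values <- integer(length(mask))
  } else {
    values <- as.integer(values)
  }
  lab <- .label_components(as.logical(mask), values, as.integer(d),
                           as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  dim(lab) <- d
  attr(lab, "n_components") <- ncomp
  lab
}

# Bounding box (list of index ranges) of a logical mask, with optional margin
# clamped to the array. NULL when the mask is empty.
maskBoundingBox <- function(mask, margin = 0L) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  co <- arrayInd(idx, d)
  lapply(seq_len(3), function(a) {
    lo <- max(1L, min(co[, a]) - margin)
    hi <- min(d[a], max(co[, a]) + margin)
    lo:hi
  })
}

cropToBox <- function(arr, box) arr[box[[1]], box[[2]], box[[3]], drop = FALSE]

# Surface voxels of a mask: voxels with at least one 6-neighbour outside the
# mask (array boundary counts as outside).
surfaceVoxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  inner <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE] &
        pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE] &
        pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L), drop = FALSE] &
        pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L), drop = FALSE] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3], drop = FALSE] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L), drop = FALSE]
  inner & !nb
}

# Maximum pairwise Euclidean distance between rows of an n x 3 coordinate
# matrix, computed exactly in chunks to bound memory.
maxPairwiseDistance <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    a <- pts[rows, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(pts^2), "+") - 2 * tcrossprod(a, pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# Sample skewness (moment estimator m3 / m2^(3/2)).
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a
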