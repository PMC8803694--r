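#' Conventional PET features
#'
#' The five conventional quantifiers of FDG-avid disease, computed on the
#' original image grid (no resampling): metabolic tumor volume (MTV, mL),
#' SUVmax, SUVpeak, SUVmean and total lesion glycolysis
#' (TLG = SUVmean x MTV). The mask may be a single lesion or the
#' patient-level VOI.
#'
#' SUVpeak is the maximum, over candidate sphere centers restricted to mask
#' voxels, of the mean SUV inside a 1.0 cm^3 sphere centered on the voxel;
#' the sphere may extend outside the mask (but not outside the image).
#'
#' @param img A \linkS4class{SuvImage}.
#' @param mask Logical array, same shape as the image; non-empty.
#' @return A named list: \code{mtv_ml}, \code{suv_max}, \code{suv_peak},
#'   \code{suv_mean}, \code{tlg}, \code{n_voxels}, and
#'   \code{suvmax_location_mm} (center of the voxel attaining the maximum,
#'   first in scan order on ties).
#' @examples
#' arr <- array(0, c(12, 12, 12)); arr[4:9, 4:9, 4:9] <- 5
#' f <- conventionalFeatures(SuvImage(arr, c(2, 2, 2)), arr > 0)
#' f$mtv_ml; f$tlg
#' @export
conventionalFeatures <- function(img, mask) {
  stopifnot(is(img, "SuvImage"))
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  vals <- img@voxels[idx]
  vv <- voxelVolumeML(img)
  mtv <- length(idx) * vv
  suv_mean <- mean(vals)
  imax <- idx[which.max(vals)]
  list(
    mtv_ml = mtv,
    suv_max = max(vals),
    suv_peak = suvPeak(img, mask),
    suv_mean = suv_mean,
    tlg = suv_mean * mtv,
    n_voxels = length(idx),
    suvmax_location_mm = as.numeric(
      voxelCentersMM(matrix(arrayInd(imax, dim(img@voxels)), 1),
                     dim(img@voxels), img@spacing))
  )
}

# Offsets (index space) of voxels whose centers lie within the 1 cm^3 sphere.
sphereKernelOffsets <- function(spacing, volume_mm3 = 1000) {
  r <- (3 * volume_mm3 / (4 * pi))^(1 / 3)
  reach <- floor(r / spacing)
  off <- as.matrix(expand.grid(
    dx = -reach[1]:reach[1], dy = -reach[2]:reach[2], dz = -reach[3]:reach[3]
  ))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
        (off[, 3] * spacing[3])^2
  off[d2 <= r^2, , drop = FALSE]
}

#' @rdname conventionalFeatures
#' @export
suvPeak <- function(img, mask) {
  stopifnot(is(img, "SuvImage"))
  if (!any(mask)) stop("empty mask")
  d <- dim(img@voxels)
  off <- sphereKernelOffsets(img@spacing)
  reach <- apply(abs(off), 2, max)
  box <- maskBoundingBox(mask, margin = 0L)
  # pad the crop with `reach` zero layers; a parallel validity indicator
  # marks which padded voxels exist in the image, so sphere means near the
  # image border average only over in-image voxels
  lo <- vapply(box, min, integer(1)); hi <- vapply(box, max, integer(1))
  plo <- pmax(1L, lo - reach); phi <- pmin(d, hi + reach)
  sub <- img@voxels[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3], drop = FALSE]
  pd <- dim(sub) + 2L * reach
  vals <- array(0, pd)
  valid <- array(0, pd)
  core <- lapply(seq_len(3), function(a) {
    (reach[a] + 1L):(reach[a] + dim(sub)[a])
  })
  vals[core[[1]], core[[2]], core[[3]]] <- sub
  # mark real image voxels (the crop may touch the image border, where
  # plo/phi already clamp; anything beyond the image stays invalid)
  valid[core[[1]], core[[2]], core[[3]]] <- 1
  sums <- array(0, dim(sub))
  cnts <- array(0, dim(sub))
  for (k in seq_len(nrow(off))) {
    sx <- core[[1]] + off[k, 1]
    sy <- core[[2]] + off[k, 2]
    sz <- core[[3]] + off[k, 3]
    sums <- sums + vals[sx, sy, sz, drop = FALSE]
    cnts <- cnts + valid[sx, sy, sz, drop = FALSE]
  }
  means <- sums / cnts
  submask <- mask[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3], drop = FALSE]
  max(means[submask])
}

#' Trilinear resampling to an isotropic grid
#'
#' Resamples an SUV image to a target voxel size (default 2 x 2 x 2 mm) by
#' trilinear interpolation, the preprocessing step before morphology/texture
#' feature calculation. Voxel centers follow the corner-aligned convention
#' (center of voxel i at (i - 0.5) x spacing), so an image already on the
#' target grid is returned unchanged up to float tolerance. Sample points
#' outside the input center lattice are clamped to the border (nearest-edge
#' extension), keeping output values within the input range.
#'
#' @param img A \linkS4class{SuvImage}.
#' @param new_spacing numeric(3) target spacing in mm (default 2 mm
#'   isotropic).
#' @return A \linkS4class{SuvImage} on the target grid.
#' @export
resampleTrilinear <- function(img, new_spacing = c(2, 2, 2)) {
  stopifnot(is(img, "SuvImage"))
  d <- dim(img@voxels)
  extent <- d * img@spacing
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  # continuous input-grid coordinates of output voxel centers
  ax <- lapply(seq_len(3), function(a) {
    ((seq_len(nd[a]) - 0.5) * new_spacing[a]) / img@spacing[a] + 0.5
  })
  interpAxis <- function(coord, n) {
    coord <- pmin(pmax(coord, 1), n)  # clamp to border
    lo <- pmin(floor(coord), n - 1L)
    if (n == 1L) lo <- rep(1, length(coord))
    w <- coord - lo
    list(lo = as.integer(lo), w = w)
  }
  ix <- interpAxis(ax[[1]], d[1]); iy <- interpAxis(ax[[2]], d[2])
  iz <- interpAxis(ax[[3]], d[3])
  v <- img@voxels
  out <- array(0, nd)
  # accumulate the 8 corner contributions with outer-product weights
  hi <- function(i, n) pmin(i + 1L, n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - ix$w else ix$w
    wy <- if (cy == 0) 1 - iy$w else iy$w
    wz <- if (cz == 0) 1 - iz$w else iz$w
    xs <- if (cx == 0) ix$lo else hi(ix$lo, d[1])
    ys <- if (cy == 0) iy$lo else hi(iy$lo, d[2])
    zs <- if (cz == 0) iz$lo else hi(iz$lo, d[3])
    w3 <- outer(outer(wx, wy), wz)
    out <- out + w3 * v[xs, ys, zs, drop = FALSE]
  }
  SuvImage(out, spacing = new_spacing, patientId = img@patientId)
}

#' Fixed-bin-size SUV discretization
#'
#' Discretizes SUV values inside a mask into grey levels with a fixed bin
#' size anchored at SUV 0: level(v) = floor(v / bin) + 1 for v > 0, so SUV
#' 4.0 falls in level 17 at the default 0.25-SUV bin. Voxels outside the
#' mask get level 0.
#'
#' @param img A \linkS4class{SuvImage}.
#' @param mask Logical array; the volume of interest.
#' @param bin_size_suv Bin width in SUV (default 0.25).
#' @return A list: \code{levels} (integer array, 0 outside mask),
#'   \code{bin_size_suv}, \code{n_levels} (maximum level inside the mask).
#' @export
discretizeFixedBin <- function(img, mask, bin_size_suv = 0.25) {
  stopifnot(is(img, "SuvImage"), bin_size_suv > 0)
  lev <- array(0L, dim(img@voxels))
  idx <- which(mask)
  v <- img@voxels[idx]
  l <- ifelse(v > 0, floor(v / bin_size_suv) + 1, 0)
  lev[idx] <- as.integer(l)
  list(levels = lev, bin_size_suv = bin_size_suv,
       n_levels = if (length(idx)) max(lev[idx]) else 0L)
}
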