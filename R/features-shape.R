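# Mesh-based shape features.
#
# The sphericity surface is a triangulated isosurface of the mask at
# iso-level 0.5: marching tetrahedra with linear edge interpolation on a
# 3x3x3 box-smoothed indicator field (the smoothing turns the staircase
# boundary into a sub-voxel ramp, removing the large surface-area
# overestimate a jagged binary midpoint mesh would give). For masks too
# small to survive smoothing the raw binary field is meshed instead, where
# every crossing sits at a half-voxel offset. Mesh volume comes from the
# divergence theorem over the closed, outward-oriented triangle set, so V
# and A always refer to the same surface.

# 6-tetrahedra decomposition of the unit cube around the main diagonal 0-7.
.tetDecomp <- matrix(c(
  0, 1, 3, 7,
  0, 3, 2, 7,
  0, 2, 6, 7,
  0, 6, 4, 7,
  0, 4, 5, 7,
  0, 5, 1, 7
), ncol = 4, byrow = TRUE)

.cubeCorner <- matrix(c(
  0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
  0, 0, 1,  1, 0, 1,  0, 1, 1,  1, 1, 1
), ncol = 3, byrow = TRUE)

# 3x3x3 box filter of a (zero-padded) numeric array.
boxSmooth3 <- function(arr) {
  d <- dim(arr)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
  out <- array(0, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    out <- out + pad[(1L + dx):(d[1] + dx), (1L + dy):(d[2] + dy),
                     (1L + dz):(d[3] + dz), drop = FALSE]
  }
  out / 27
}

# Triangulate the 0.5-isosurface of a numeric field (already padded with a
# zero border so the surface closes). Returns triangle vertex matrices
# (p1, p2, p3; each n x 3, in mm, outward-oriented) or NULL.
marchingTetrahedra <- function(field, spacing, iso = 0.5) {
  pd <- dim(field)
  cd <- pd - 1L  # cell grid
  corner <- matrix(0, prod(cd), 8L)
  for (j in 1:8) {
    o <- .cubeCorner[j, ]
    corner[, j] <- field[(1L + o[1]):(cd[1] + o[1]),
                         (1L + o[2]):(cd[2] + o[2]),
                         (1L + o[3]):(cd[3] + o[3])]
  }
  inside <- corner > iso
  s <- rowSums(inside)
  mixed <- which(s > 0L & s < 8L)
  if (!length(mixed)) return(NULL)
  corner <- corner[mixed, , drop = FALSE]
  inside <- inside[mixed, , drop = FALSE]
  # voxel-center coordinates (mm) of corner 0 of each mixed cell, on the
  # padded grid (padded index i corresponds to original voxel i - 1)
  cellIdx <- arrayInd(mixed, cd)
  base <- sweep(cellIdx - 1.5, 2, spacing, "*")
  p1 <- list(); p2 <- list(); p3 <- list()
  for (t in seq_len(nrow(.tetDecomp))) {
    vids <- .tetDecomp[t, ] + 1L
    ins <- inside[, vids, drop = FALSE]
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    active <- which(code > 0L & code < 15L)
    if (!length(active)) next
    P <- lapply(1:4, function(j) {
      off <- .cubeCorner[vids[j], ]
      sweep(base[active, , drop = FALSE], 2, off * spacing, "+")
    })
    FV <- lapply(1:4, function(j) corner[active, vids[j]])
    cd4 <- code[active]
    for (cc in unique(cd4)) {
      rows <- which(cd4 == cc)
      insideSet <- which(bitwAnd(cc, c(1L, 2L, 4L, 8L)) > 0L)
      outsideSet <- setdiff(1:4, insideSet)
      Pi <- lapply(P, function(m) m[rows, , drop = FALSE])
      Fi <- lapply(FV, function(v) v[rows])
      tri <- .tetTriangles(Pi, Fi, insideSet, outsideSet, iso)
      p1 <- c(p1, tri$p1); p2 <- c(p2, tri$p2); p3 <- c(p3, tri$p3)
    }
  }
  list(p1 = do.call(rbind, p1), p2 = do.call(rbind, p2),
       p3 = do.call(rbind, p3))
}

# Oriented triangles (normals pointing inside -> outside) for one
# tetrahedron case. Pi: 4 corner coordinate matrices; Fi: 4 corner value
# vectors. Crossing points are linearly interpolated to the iso-level.
.tetTriangles <- function(Pi, Fi, insideSet, outsideSet, iso) {
  cross_pt <- function(a, b) {
    t <- (iso - Fi[[a]]) / (Fi[[b]] - Fi[[a]])
    t <- pmin(pmax(t, 0), 1)
    Pi[[a]] + t * (Pi[[b]] - Pi[[a]])
  }
  orient <- function(q1, q2, q3) {
    inC <- Reduce("+", Pi[insideSet]) / length(insideSet)
    outC <- Reduce("+", Pi[outsideSet]) / length(outsideSet)
    n <- .rowCross(q2 - q1, q3 - q1)
    flip <- rowSums(n * (outC - inC)) < 0
    fm <- matrix(flip, length(flip), 3)
    list(p1 = q1, p2 = ifelse(fm, q3, q2), p3 = ifelse(fm, q2, q3))
  }
  if (length(insideSet) == 1L) {
    a <- insideSet
    tri <- orient(cross_pt(a, outsideSet[1]), cross_pt(a, outsideSet[2]),
                  cross_pt(a, outsideSet[3]))
    list(p1 = list(tri$p1), p2 = list(tri$p2), p3 = list(tri$p3))
  } else if (length(insideSet) == 3L) {
    a <- outsideSet
    tri <- orient(cross_pt(insideSet[1], a), cross_pt(insideSet[2], a),
                  cross_pt(insideSet[3], a))
    list(p1 = list(tri$p1), p2 = list(tri$p2), p3 = list(tri$p3))
  } else {
    a <- insideSet[1]; b <- insideSet[2]
    c1 <- outsideSet[1]; c2 <- outsideSet[2]
    m_ac <- cross_pt(a, c1); m_ad <- cross_pt(a, c2)
    m_bc <- cross_pt(b, c1); m_bd <- cross_pt(b, c2)
    t1 <- orient(m_ac, m_ad, m_bd)
    t2 <- orient(m_ac, m_bd, m_bc)
    list(p1 = list(t1$p1, t2$p1), p2 = list(t1$p2, t2$p2),
         p3 = list(t1$p3, t2$p3))
  }
}

.rowCross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Surface area (mm^2) and enclosed volume (mm^3) of the triangulated mask
# isosurface. The indicator field is box-smoothed before meshing; masks
# that vanish under smoothing fall back to the raw binary field.
meshAreaVolume <- function(mask, spacing) {
  d <- dim(mask)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  smooth <- boxSmooth3(pad)
  field <- if (any(smooth > 0.5)) smooth else pad
  mesh <- marchingTetrahedra(field, spacing)
  if (is.null(mesh)) return(list(area = 0, volume = 0))
  n <- .rowCross(mesh$p2 - mesh$p1, mesh$p3 - mesh$p1)
  area <- sum(sqrt(rowSums(n^2))) / 2
  vol <- abs(sum(rowSums(mesh$p1 * .rowCross(mesh$p2, mesh$p3))) / 6)
  list(area = area, volume = vol)
}

# Exposed voxel-face surface area (mm^2) of a mask: fallback surface for
# masks too thin to mesh meaningfully.
voxelFaceArea <- function(mask, spacing) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  faceArea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2])
  total <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[(2 + s[1]):(d[1] + 1 + s[1]),
              (2 + s[2]):(d[2] + 1 + s[2]),
              (2 + s[3]):(d[3] + 1 + s[3]), drop = FALSE]
    exposed <- mask & !nb
    total <- total + sum(exposed) * faceArea[which(s != 0)]
  }
  total
}

#' Sphericity of a voxel mask
#'
#' Sphericity = pi^(1/3) (6V)^(2/3) / A, where V and A are the volume and
#' surface area of a triangulated isosurface of the mask (marching
#' tetrahedra at iso-level 0.5 on a box-smoothed indicator field; crossings
#' on a raw binary field sit at half-voxel offsets). The value is 1 for a
#' perfect sphere and decreases for elongated or irregular shapes; mesh
#' tolerance can push a near-sphere slightly above 1, so the result is
#' capped at 1.
#'
#' Masks thinner than 2 voxels along some axis cannot be meshed
#' meaningfully; for those the exposed voxel-face area is used instead and
#' the result carries attribute \code{method = "voxel-face"} (a single
#' voxel gives 0.806).
#'
#' @param mask Logical 3-D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return Sphericity in (0, 1], with attribute \code{method} one of
#'   \code{"mesh"} or \code{"voxel-face"}.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' sphericity(m, c(2, 2, 2))  # 0.806
#' @export
sphericity <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask")
  box <- maskBoundingBox(mask)
  extent <- vapply(box, length, integer(1))
  if (any(extent < 2L)) {
    V <- sum(mask) * prod(spacing)
    A <- voxelFaceArea(mask, spacing)
    method <- "voxel-face"
  } else {
    av <- meshAreaVolume(cropToBox(mask, box), spacing)
    V <- av$volume
    A <- av$area
    method <- "mesh"
  }
  s <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  structure(min(s, 1), method = method)
}

#' Bulky disease flag
#'
#' TRUE when any lesion's maximum 3-D diameter -- the largest pairwise
#' distance between surface-voxel centers (maximum Feret diameter) -- is at
#' least 10 cm, the conventional bulky-disease cut-off.
#'
#' @param seg A \linkS4class{LesionSegmentation}.
#' @param threshold_mm Diameter cut-off in mm (default 100).
#' @return logical(1).
#' @export
bulkyDisease <- function(seg, threshold_mm = 100) {
  stopifnot(is(seg, "LesionSegmentation"))
  for (id in lesionIds(seg)) {
    if (lesionDiameterMM(seg, id) >= threshold_mm) return(TRUE)
  }
  FALSE
}

#' @rdname bulkyDisease
#' @param lesionId Integer lesion label.
#' @export
lesionDiameterMM <- function(seg, lesionId) {
  m <- lesionMask(seg, lesionId)
  surf <- surfaceVoxels(m)
  pts <- voxelCentersMM(which(surf), dim(m), seg@spacing)
  maxPairwiseDistance(pts)
}
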