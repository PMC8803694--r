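#' Grey-level size-zone matrix
#'
#' Zones are 26-connected components of voxels sharing the same grey level
#' inside a mask. The GLSZM entry s(i, j) counts zones of grey level i and
#' size j voxels; it is the basis of size-zone texture features such as
#' \code{\link{lzhge}}.
#'
#' @param levels Integer 3-D array of grey levels (0 outside the mask), e.g.
#'   from \code{\link{discretizeFixedBin}}.
#' @param mask Logical array delimiting the volume of interest.
#' @param connectivity 26 (default) or 6.
#' @return A data.frame with columns \code{level}, \code{size},
#'   \code{count} (one row per occupied (i, j) cell).
#' @export
glszm <- function(levels, mask, connectivity = 26L) {
  if (!any(mask)) stop("empty mask")
  box <- maskBoundingBox(mask)
  lev <- cropToBox(levels, box)
  msk <- cropToBox(mask, box)
  zones <- labelComponents(msk, connectivity, values = lev)
  nz <- attr(zones, "n_components")
  if (nz == 0L) stop("no zones found")
  zid <- zones[zones > 0L]
  zlev <- lev[zones > 0L]
  size <- tabulate(zid, nbins = nz)
  level <- zlev[match(seq_len(nz), zid)]
  key <- paste(level, size)
  counts <- table(key)
  parts <- do.call(rbind, strsplit(names(counts), " ", fixed = TRUE))
  out <- data.frame(level = as.integer(parts[, 1]),
                    size = as.integer(parts[, 2]),
                    count = as.integer(counts))
  out[order(out$level, out$size), , drop = FALSE]
}

#' Long-zone high grey-level emphasis (LZHGE)
#'
#' Size-zone texture feature weighting each zone by (grey level)^2 x
#' (zone size)^2 and normalizing by the number of zones:
#' LZHGE = (1 / N_zones) * sum_i sum_j s(i, j) i^2 j^2. Large, hot,
#' homogeneous regions dominate; the feature rises with both uptake and the
#' size of iso-intense regions.
#'
#' @inheritParams glszm
#' @return numeric(1).
#' @examples
#' lev <- array(0L, c(4, 4, 4)); lev[2:3, 2:3, 2:3] <- 5L
#' lzhge(lev, lev > 0)  # single zone: 5^2 * 8^2
#' @export
lzhge <- function(levels, mask, connectivity = 26L) {
  z <- glszm(levels, mask, connectivity)
  n_zones <- sum(z$count)
  sum(z$count * (z$level^2) * (z$size^2)) / n_zones
}
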