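#' Automated preselection of FDG-avid lesions
#'
#' Semi-automated lymphoma delineation starts from a fully automated
#' preselection: 26-connected components of the super-threshold region
#' \{SUV >= 4.0\} whose physical volume is at least 3 mL become candidate
#' lesions. Components below the volume floor are left for seed-based
#' addition (\code{\link{addLesionBySeed}}). Lesions are labelled in
#' decreasing-volume order, ties broken by smallest linear voxel index, so
#' the output is deterministic.
#'
#' @param img A \linkS4class{SuvImage}.
#' @param suv_threshold SUV cut-off defining FDG-avid voxels (default 4.0).
#' @param min_volume_mL Volume floor in mL for preselection (default 3).
#' @param connectivity 26 (default) or 6.
#' @return A \linkS4class{LesionSegmentation}. When no component passes, the
#'   segmentation is empty and carries the flag \code{"no FDG-avid lesions"}.
#' @examples
#' arr <- array(1, c(20, 20, 20))
#' arr[8:13, 8:13, 8:13] <- 6          # 216 voxels at 4 mm = 13.8 mL
#' seg <- preselectLesions(SuvImage(arr, c(4, 4, 4)))
#' lesionVolumesML(seg)
#' @export
preselectLesions <- function(img, suv_threshold = 4.0, min_volume_mL = 3.0,
                             connectivity = 26L) {
  stopifnot(is(img, "SuvImage"))
  mask <- img@voxels >= suv_threshold
  lab <- labelComponents(mask, connectivity)
  vv <- voxelVolumeML(img)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * vv >= min_volume_mL)
  relab <- relabelByVolume(lab, keep, counts)
  flags <- if (length(keep) == 0L) "no FDG-avid lesions" else character()
  prov <- data.frame(
    lesion_id = seq_along(keep),
    origin = rep("preselected", length(keep)),
    note = rep("", length(keep)),
    stringsAsFactors = FALSE
  )
  newSegmentation(relab, img@spacing, prov, flags)
}

# Relabel components `keep` (by original label) to 1..k in decreasing-volume
# order; ties broken by smallest linear voxel index of the component.
relabelByVolume <- function(lab, keep, counts) {
  d <- dim(lab)
  out <- array(0L, d)
  if (length(keep)) {
    first_idx <- vapply(keep, function(k) match(k, lab), integer(1))
    ord <- keep[order(-counts[keep], first_idx)]
    for (i in seq_along(ord)) out[lab == ord[i]] <- i
  }
  out
}

#' Add a lesion from a seed voxel
#'
#' Adds the SUV-threshold connected component containing \code{seed_voxel} as
#' a new lesion, mirroring the single-click addition of small (< 3 mL)
#' lymphoma lesions missed by the volume floor of automated preselection.
#' No volume floor applies. Idempotent when the seed already lies inside a
#' labelled lesion.
#'
#' @param seg A \linkS4class{LesionSegmentation}.
#' @param img The underlying \linkS4class{SuvImage}.
#' @param seed_voxel integer(3), 1-based voxel index of the click.
#' @param suv_threshold SUV cut-off (default 4.0); the seed voxel must be at
#'   or above it.
#' @param connectivity 26 (default) or 6.
#' @return The updated \linkS4class{LesionSegmentation}.
#' @export
addLesionBySeed <- function(seg, img, seed_voxel, suv_threshold = 4.0,
                            connectivity = 26L) {
  stopifnot(is(seg, "LesionSegmentation"), is(img, "SuvImage"))
  seed_voxel <- as.integer(seed_voxel)
  stopifnot(length(seed_voxel) == 3L)
  d <- dim(img@voxels)
  if (any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel outside image")
  if (img@voxels[seed_voxel[1], seed_voxel[2], seed_voxel[3]] < suv_threshold)
    stop("seed below threshold")
  lin <- seed_voxel[1] + d[1] * ((seed_voxel[2] - 1L) +
                                 d[2] * (seed_voxel[3] - 1L))
  if (seg@labels[lin] > 0L) return(seg)  # already labelled: idempotent
  mask <- img@voxels >= suv_threshold
  comp <- labelComponents(mask, connectivity)
  target <- comp[lin]
  newmask <- comp == target & seg@labels == 0L
  new_id <- max(0L, lesionIds(seg)) + 1L
  labels <- seg@labels
  labels[newmask] <- new_id
  prov <- rbind(seg@provenance, data.frame(
    lesion_id = new_id, origin = "seed-added",
    note = sprintf("seed voxel (%d,%d,%d)", seed_voxel[1], seed_voxel[2],
                   seed_voxel[3]),
    stringsAsFactors = FALSE
  ))
  flags <- setdiff(seg@flags, "no FDG-avid lesions")
  newSegmentation(labels, seg@spacing, prov, flags)
}

#' Remove a lesion or a subregion of a lesion
#'
#' \code{removeLesion} deletes a whole lesion (e.g. a physiological-uptake
#' structure wrongly preselected); \code{removeSubregion} deletes part of a
#' lesion (e.g. an adjacent kidney clipped off with a mask). Labels of the
#' other lesions are preserved; the label grid is then compacted to
#' consecutive integers. If a subregion removal splits a lesion into several
#' 26-connected fragments, the fragments become separate lesions and the
#' split is recorded in the provenance.
#'
#' @param seg A \linkS4class{LesionSegmentation}.
#' @param lesion_id Integer label of the lesion to edit.
#' @param mask Logical array (same shape as the label grid); must be a subset
#'   of the lesion's voxels.
#' @param connectivity 26 (default) or 6, for fragment relabelling.
#' @return The updated \linkS4class{LesionSegmentation}.
#' @export
removeLesion <- function(seg, lesion_id) {
  stopifnot(is(seg, "LesionSegmentation"))
  lesion_id <- as.integer(lesion_id)
  if (!lesion_id %in% lesionIds(seg))
    stop("unknown lesion id: ", lesion_id)
  labels <- seg@labels
  labels[labels == lesion_id] <- 0L
  prov <- seg@provenance[seg@provenance$lesion_id != lesion_id, ,
                         drop = FALSE]
  compactLabels(labels, seg@spacing, prov, seg@flags)
}

#' @rdname removeLesion
#' @export
removeSubregion <- function(seg, lesion_id, mask, connectivity = 26L) {
  stopifnot(is(seg, "LesionSegmentation"))
  lesion_id <- as.integer(lesion_id)
  if (!lesion_id %in% lesionIds(seg))
    stop("unknown lesion id: ", lesion_id)
  if (!identical(dim(mask), dim(seg@labels)))
    stop("mask shape does not match label grid")
  if (any(mask & seg@labels != lesion_id))
    stop("mask must be a subset of lesion ", lesion_id)
  labels <- seg@labels
  labels[mask] <- 0L
  remaining <- labels == lesion_id
  prov <- seg@provenance
  prov$note[prov$lesion_id == lesion_id] <-
    paste0(prov$note[prov$lesion_id == lesion_id], "; subregion removed")
  if (!any(remaining)) {
    prov <- prov[prov$lesion_id != lesion_id, , drop = FALSE]
    return(compactLabels(labels, seg@spacing, prov, seg@flags))
  }
  frag <- labelComponents(remaining, connectivity)
  nfrag <- attr(frag, "n_components")
  if (nfrag > 1L) {
    # fragments become new lesions appended after the existing labels
    base <- max(lesionIds(seg))
    row <- prov[prov$lesion_id == lesion_id, , drop = FALSE]
    prov <- prov[prov$lesion_id != lesion_id, , drop = FALSE]
    labels[remaining] <- 0L
    for (f in seq_len(nfrag)) {
      labels[frag == f] <- base + f
      nr <- row
      nr$lesion_id <- base + f
      nr$note <- paste0(nr$note, sprintf("; split fragment %d of lesion %d",
                                         f, lesion_id))
      prov <- rbind(prov, nr)
    }
  }
  compactLabels(labels, seg@spacing, prov, seg@flags)
}

# Renumber surviving labels to consecutive 1..k preserving relative order.
compactLabels <- function(labels, spacing, prov, flags) {
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  map <- integer(max(ids, 0L))
  map[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  prov <- prov[order(prov$lesion_id), , drop = FALSE]
  prov$lesion_id <- map[prov$lesion_id]
  rownames(prov) <- NULL
  newSegmentation(labels, spacing, prov, flags)
}

#' Apply a JSON-style edit script to a segmentation
#'
#' Replays a recorded list of manual edits: seed additions, lesion removals
#' and subregion removals. Seed coordinates are 0-based voxel indices, the
#' convention used in the on-disk edit scripts.
#'
#' @param seg A \linkS4class{LesionSegmentation}.
#' @param img The underlying \linkS4class{SuvImage}.
#' @param edits A list of edits; each edit is a list with \code{op} one of
#'   \code{"add_seed"} (field \code{voxel}, 0-based), \code{"remove_lesion"}
#'   (field \code{lesion_id}) or \code{"remove_subregion"} (fields
#'   \code{lesion_id} and \code{box}, a 0-based \code{[lo, hi)} index box).
#' @return The edited \linkS4class{LesionSegmentation}.
#' @export
applyEditScript <- function(seg, img, edits) {
  for (e in edits) {
    op <- e$op %||% stop("edit without op")
    seg <- switch(op,
      add_seed = addLesionBySeed(seg, img, unlist(e$voxel) + 1L),
      remove_lesion = removeLesion(seg, e$lesion_id),
      remove_subregion = {
        box <- e$box
        m <- array(FALSE, dim(seg@labels))
        m[(box[[1]][1] + 1L):box[[1]][2],
          (box[[2]][1] + 1L):box[[2]][2],
          (box[[3]][1] + 1L):box[[3]][2]] <- TRUE
        m <- m & (seg@labels == e$lesion_id)
        removeSubregion(seg, e$lesion_id, m)
      },
      stop("unknown edit op: ", op)
    )
  }
  seg
}
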