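# Feature-extraction orchestration: conventional features on the original
# grid, shape/texture on the 2 mm resampled grid, dissemination from
# original-grid SUVmax locations.

# Nearest-neighbour resampling of an integer label grid to a new spacing,
# with the same corner-aligned center convention as resampleTrilinear.
resampleNearest <- function(labels, spacing, new_spacing = c(2, 2, 2)) {
  d <- dim(labels)
  extent <- d * spacing
  nd <- pmax(1L, as.integer(round(extent / new_spacing)))
  ax <- lapply(seq_len(3), function(a) {
    coord <- ((seq_len(nd[a]) - 0.5) * new_spacing[a]) / spacing[a] + 0.5
    pmin(pmax(as.integer(round(coord)), 1L), d[a])
  })
  labels[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
}

# Shape + texture features for one mask, computed on a 2 mm resampled crop
# around the mask: sphericity from the mesh of the resampled mask, LZHGE
# from the 0.25-SUV discretized resampled image within the mask.
shapeTextureFeatures <- function(img, mask, target_spacing = c(2, 2, 2),
                                 bin_size_suv = 0.25) {
  box <- maskBoundingBox(mask, margin = 2L)
  sub <- SuvImage(cropToBox(img@voxels, box), img@spacing, img@patientId)
  submask <- cropToBox(mask, box)
  rimg <- resampleTrilinear(sub, target_spacing)
  rmask <- resampleNearest(submask, img@spacing, target_spacing) > 0
  if (!any(rmask)) {
    # degenerate: mask vanished under resampling; fall back to original grid
    rimg <- sub
    rmask <- submask
  }
  sph <- sphericity(rmask, voxelSpacing(rimg))
  disc <- discretizeFixedBin(rimg, rmask, bin_size_suv)
  list(sphericity = as.numeric(sph),
       sphericity_method = attr(sph, "method"),
       lzhge = lzhge(disc$levels, rmask))
}

#' Extract lesion- and patient-level features
#'
#' Runs the full feature-extraction stage for one patient: the five
#' conventional PET features (original grid) per lesion and for the
#' patient-level VOI, sphericity and long-zone high grey-level emphasis
#' (2 mm resampled grid, 0.25-SUV discretization), the five dissemination
#' features from original-grid SUVmax locations, the bulky-disease flag and
#' the largest/hottest index lesions.
#'
#' @param img A \linkS4class{SuvImage}.
#' @param seg A \linkS4class{LesionSegmentation} over the same grid.
#' @param height_cm Optional patient height for the height-corrected
#'   Dmax_bulk.
#' @param lesion_shape_texture Logical; also compute sphericity/LZHGE per
#'   lesion (needed for lesion-level models; the patient-level row always
#'   gets them).
#' @return A list with \code{patient} (one-row data.frame with columns
#'   \code{patient_id, mtv_ml, suv_max, suv_peak, suv_mean, tlg, n_lesions,
#'   dmax_patient_mm, dmax_bulk_mm, spread_patient_mm, spread_bulk_mm,
#'   sphericity, lzhge, bulky, largest_lesion_id, hottest_lesion_id,
#'   dmax_bulk_height_corrected}) and \code{lesions} (one row per lesion).
#' @export
extractPatientFeatures <- function(img, seg, height_cm = NA_real_,
                                   lesion_shape_texture = TRUE) {
  stopifnot(is(img, "SuvImage"), is(seg, "LesionSegmentation"))
  ids <- lesionIds(seg)
  if (length(ids) == 0L)
    stop("segmentation has no lesions for patient ", patientId(img))
  lesion_rows <- vector("list", length(ids))
  locs <- matrix(NA_real_, length(ids), 3)
  for (k in seq_along(ids)) {
    m <- lesionMask(seg, ids[k])
    cf <- conventionalFeatures(img, m)
    locs[k, ] <- cf$suvmax_location_mm
    st <- if (lesion_shape_texture) shapeTextureFeatures(img, m) else
      list(sphericity = NA_real_, lzhge = NA_real_)
    lesion_rows[[k]] <- data.frame(
      patient_id = patientId(img), lesion_id = ids[k],
      mtv_ml = cf$mtv_ml, suv_max = cf$suv_max, suv_peak = cf$suv_peak,
      suv_mean = cf$suv_mean, tlg = cf$tlg, n_voxels = cf$n_voxels,
      sphericity = st$sphericity, lzhge = st$lzhge,
      stringsAsFactors = FALSE
    )
  }
  lesions <- do.call(rbind, lesion_rows)
  voi <- patientVoi(seg)
  cfp <- conventionalFeatures(img, voi)
  stp <- shapeTextureFeatures(img, voi)
  dis <- disseminationFeatures(locs, lesions$mtv_ml)
  idx <- selectIndexLesions(lesions$mtv_ml, lesions$suv_max)
  patient <- data.frame(
    patient_id = patientId(img),
    mtv_ml = cfp$mtv_ml, suv_max = cfp$suv_max, suv_peak = cfp$suv_peak,
    suv_mean = cfp$suv_mean, tlg = cfp$tlg,
    n_lesions = dis$n_lesions,
    dmax_patient_mm = dis$dmax_patient_mm,
    dmax_bulk_mm = dis$dmax_bulk_mm,
    spread_patient_mm = dis$spread_patient_mm,
    spread_bulk_mm = dis$spread_bulk_mm,
    sphericity = stp$sphericity,
    lzhge = stp$lzhge,
    bulky = bulkyDisease(seg),
    largest_lesion_id = ids[idx$largest_lesion_id],
    hottest_lesion_id = ids[idx$hottest_lesion_id],
    dmax_bulk_height_corrected = if (is.na(height_cm)) NA_real_ else
      heightCorrectDmax(dis$dmax_bulk_mm, height_cm),
    stringsAsFactors = FALSE
  )
  list(patient = patient, lesions = lesions)
}
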