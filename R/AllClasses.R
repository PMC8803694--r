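#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lymphoradiomics, .registration = TRUE
NULL

#' SuvImage: a quantitative 3-D PET image
#'
#' Container for a 3-D standardized-uptake-value (SUV) grid together with its
#' voxel spacing. SUV is the unit of PET quantification (tissue tracer
#' concentration normalized by injected activity and body weight); all
#' downstream segmentation and feature extraction operates on this object.
#'
#' @slot voxels 3-D numeric array of SUV values, all finite and non-negative.
#' @slot spacing numeric(3), voxel edge lengths in mm, strictly positive.
#' @slot patientId character(1) identifier.
#'
#' @examples
#' img <- SuvImage(array(1, c(8, 8, 8)), spacing = c(4, 4, 4), patientId = "p1")
#' voxelSpacing(img)
#' @export
setClass("SuvImage",
  representation(
    voxels = "array",
    spacing = "numeric",
    patientId = "character"
  )
)

setValidity("SuvImage", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3-D array")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msgs <- c(msgs, "voxels must be finite")
  else if (any(object@voxels < 0))
    msgs <- c(msgs, "SUV values must be non-negative")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values (mm)")
  if (length(object@patientId) != 1L)
    msgs <- c(msgs, "patientId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SuvImage
#'
#' @param voxels 3-D numeric array of SUV values.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param patientId character(1) identifier.
#' @return A \linkS4class{SuvImage}.
#' @export
SuvImage <- function(voxels, spacing, patientId = "anonymous") {
  new("SuvImage", voxels = voxels, spacing = as.numeric(spacing),
      patientId = as.character(patientId))
}

#' LesionSegmentation: labelled lesion masks and the patient-level VOI
#'
#' Integer label grid over the voxels of a \linkS4class{SuvImage}: 0 is
#' background, k >= 1 the k-th lesion. Labels are disjoint by construction;
#' the patient-level volume of interest (VOI) is the union of all lesion
#' masks. Provenance records whether each lesion came from automated
#' preselection or from a seed click, and any edits applied.
#'
#' @slot labels 3-D integer array of lesion labels (0 = background).
#' @slot spacing numeric(3) voxel spacing in mm (copied from the image).
#' @slot provenance data.frame with columns \code{lesion_id}, \code{origin}
#'   (\code{"preselected"} or \code{"seed-added"}), \code{note}.
#' @slot flags character vector of segmentation-level flags, e.g.
#'   \code{"no FDG-avid lesions"}.
#' @export
setClass("LesionSegmentation",
  representation(
    labels = "array",
    spacing = "numeric",
    provenance = "data.frame",
    flags = "character"
  )
)

setValidity("LesionSegmentation", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3-D array")
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be integer")
  ids <- sort(unique(as.integer(object@labels)))
  ids <- ids[ids > 0L]
  if (length(ids) && !identical(ids, seq_along(ids)))
    msgs <- c(msgs, "lesion labels must be consecutive positive integers")
  if (!identical(sort(object@provenance$lesion_id), ids))
    msgs <- c(msgs, "provenance must list exactly the labels present")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values (mm)")
  if (length(msgs)) msgs else TRUE
})

newSegmentation <- function(labels, spacing, provenance = NULL,
                            flags = character()) {
  if (is.null(provenance)) {
    ids <- sort(unique(as.integer(labels)))
    ids <- ids[ids > 0L]
    provenance <- data.frame(
      lesion_id = ids,
      origin = rep("preselected", length(ids)),
      note = rep("", length(ids)),
      stringsAsFactors = FALSE
    )
  }
  new("LesionSegmentation", labels = labels, spacing = as.numeric(spacing),
      provenance = provenance, flags = flags)
}
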