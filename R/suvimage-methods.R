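#' Accessors for SuvImage
#'
#' \code{suvVoxels} returns the raw 3-D SUV array, \code{voxelSpacing} the
#' voxel spacing in mm, \code{patientId} the identifier and
#' \code{voxelVolumeML} the volume of a single voxel in mL.
#'
#' @param x A \linkS4class{SuvImage}.
#' @return See description.
#' @name SuvImage-accessors
NULL

#' @rdname SuvImage-accessors
#' @export
setMethod("suvVoxels", "SuvImage", function(x) x@voxels)

#' @rdname SuvImage-accessors
#' @export
setMethod("voxelSpacing", "SuvImage", function(x) x@spacing)

#' @rdname SuvImage-accessors
#' @export
setMethod("patientId", "SuvImage", function(x) x@patientId)

#' @rdname SuvImage-accessors
#' @export
setMethod("voxelVolumeML", "SuvImage", function(x) prod(x@spacing) / 1000)

setMethod("show", "SuvImage", function(object) {
  d <- dim(object@voxels)
  cat("SuvImage '", object@patientId, "': ",
      paste(d, collapse = " x "), " voxels at ",
      paste(format(object@spacing, trim = TRUE), collapse = " x "),
      " mm\n", sep = "")
  cat("  SUV range: ", format(min(object@voxels), digits = 4), " - ",
      format(max(object@voxels), digits = 4), "\n", sep = "")
})

#' Accessors for LesionSegmentation
#'
#' \code{lesionLabels} returns the integer label grid, \code{lesionIds} the
#' ordered lesion identifiers, \code{lesionCount} their number,
#' \code{patientVoi} the binary union-of-lesions grid, \code{lesionVolumesML}
#' the per-lesion physical volumes, \code{lesionMask} a single lesion's
#' binary mask, \code{segmentationProvenance} the per-lesion origin/edit
#' record and \code{segmentationFlags} any segmentation-level flags.
#'
#' @param x A \linkS4class{LesionSegmentation}.
#' @param lesionId Integer lesion label.
#' @return See description.
#' @name LesionSegmentation-accessors
NULL

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("lesionLabels", "LesionSegmentation", function(x) x@labels)

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("lesionIds", "LesionSegmentation", function(x) {
  ids <- sort(unique(as.integer(x@labels)))
  ids[ids > 0L]
})

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("lesionCount", "LesionSegmentation",
          function(x) length(lesionIds(x)))

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("patientVoi", "LesionSegmentation", function(x) {
  voi <- x@labels > 0L
  storage.mode(voi) <- "logical"
  voi
})

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("lesionVolumesML", "LesionSegmentation", function(x) {
  ids <- lesionIds(x)
  vv <- prod(x@spacing) / 1000
  counts <- tabulate(x@labels[x@labels > 0L], nbins = max(ids, 0L))
  stats::setNames(counts[ids] * vv, ids)
})

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("lesionMask", "LesionSegmentation", function(x, lesionId) {
  stopifnot(length(lesionId) == 1L)
  if (!lesionId %in% lesionIds(x))
    stop("unknown lesion id: ", lesionId)
  m <- x@labels == as.integer(lesionId)
  storage.mode(m) <- "logical"
  m
})

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("segmentationProvenance", "LesionSegmentation",
          function(x) x@provenance)

#' @rdname LesionSegmentation-accessors
#' @export
setMethod("segmentationFlags", "LesionSegmentation", function(x) x@flags)

setMethod("show", "LesionSegmentation", function(object) {
  n <- lesionCount(object)
  cat("LesionSegmentation: ", n, " lesion", if (n != 1) "s", "\n", sep = "")
  if (n > 0) {
    v <- lesionVolumesML(object)
    cat("  volumes (mL): ",
        paste(format(v, digits = 3, trim = TRUE), collapse = ", "), "\n",
        sep = "")
  }
  if (length(object@flags))
    cat("  flags: ", paste(object@flags, collapse = "; "), "\n", sep = "")
})

#' Read and write SUV images as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} keeping the voxel spacing in the header.
#' Images are written as float32, the conventional storage for SUV maps.
#'
#' @param path File path (\code{.nii} or \code{.nii.gz}).
#' @param patientId Identifier attached to the returned object.
#' @param img A \linkS4class{SuvImage}.
#' @return \code{readSuvImage} returns a \linkS4class{SuvImage};
#'   \code{writeSuvImage} returns \code{path} invisibly.
#' @export
readSuvImage <- function(path, patientId = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim(nii))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI volume: ", path)
  sp <- RNifti::pixdim(nii)[seq_len(3)]
  if (is.null(patientId))
    patientId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  SuvImage(arr, spacing = sp, patientId = patientId)
}

#' @rdname readSuvImage
#' @export
writeSuvImage <- function(img, path) {
  stopifnot(is(img, "SuvImage"))
  arr <- img@voxels
  attr(arr, "pixdim") <- img@spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' Read and write lesion label images as NIfTI-1
#'
#' @param path File path.
#' @param seg A \linkS4class{LesionSegmentation}.
#' @param spacing Optional spacing override (mm) when reading.
#' @return \code{readSegmentation} returns a
#'   \linkS4class{LesionSegmentation}; \code{writeSegmentation} returns
#'   \code{path} invisibly.
#' @export
readSegmentation <- function(path, spacing = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.integer(nii), dim(nii))
  if (is.null(spacing)) spacing <- RNifti::pixdim(nii)[seq_len(3)]
  newSegmentation(arr, spacing)
}

#' @rdname readSegmentation
#' @export
writeSegmentation <- function(seg, path) {
  stopifnot(is(seg, "LesionSegmentation"))
  arr <- seg@labels
  attr(arr, "pixdim") <- seg@spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}
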