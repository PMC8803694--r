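#' @rdname SuvImage-accessors
#' @export
setGeneric("suvVoxels", function(x) standardGeneric("suvVoxels"))

#' @rdname SuvImage-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname SuvImage-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname SuvImage-accessors
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("lesionIds", function(x) standardGeneric("lesionIds"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("lesionCount", function(x) standardGeneric("lesionCount"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("patientVoi", function(x) standardGeneric("patientVoi"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("lesionVolumesML", function(x) standardGeneric("lesionVolumesML"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("lesionMask", function(x, lesionId) standardGeneric("lesionMask"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("segmentationProvenance",
           function(x) standardGeneric("segmentationProvenance"))

#' @rdname LesionSegmentation-accessors
#' @export
setGeneric("segmentationFlags",
           function(x) standardGeneric("segmentationFlags"))
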