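#' Scan-level quality control metadata
#'
#' Bundle of the per-scan quantities the EANM-style QC rules inspect: mean
#' liver SUV, plasma glucose, the fraction of injected activity recovered in
#' the image, and completeness flags.
#'
#' @param liver_suv_mean Mean SUV of the liver reference region.
#' @param plasma_glucose_mmol_per_L Plasma glucose at injection (mmol/L).
#' @param total_image_activity_fraction Total image activity divided by
#'   injected activity; must lie in \code{[0, 1.5]}.
#' @param complete_scan Logical, whole-body coverage present.
#' @param dicom_fields_present Logical, essential acquisition metadata
#'   available.
#' @return A \code{QcMetadata} list.
#' @export
qcMetadata <- function(liver_suv_mean, plasma_glucose_mmol_per_L,
                       total_image_activity_fraction, complete_scan = TRUE,
                       dicom_fields_present = TRUE) {
  fields <- list(
    liver_suv_mean = liver_suv_mean,
    plasma_glucose_mmol_per_L = plasma_glucose_mmol_per_L,
    total_image_activity_fraction = total_image_activity_fraction,
    complete_scan = complete_scan,
    dicom_fields_present = dicom_fields_present
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != 1L || is.na(v))
      stop("QcMetadata field missing or invalid: ", nm)
  }
  if (total_image_activity_fraction < 0 ||
      total_image_activity_fraction > 1.5)
    stop("total_image_activity_fraction must lie in [0, 1.5]")
  structure(fields, class = "QcMetadata")
}

#' EANM-style scan quality control
#'
#' Applies the scan acceptability rules: (1) the scan must be complete,
#' (2) essential DICOM metadata must be present, (3) a liver SUVmean outside
#' 1.3--3.0 fails only when the total image activity fraction is also outside
#' 0.50--0.80 (the two sub-rules form one joint criterion; set
#' \code{strict = TRUE} to treat them as independent rules), and (4) plasma
#' glucose must be below 11 mmol/L.
#'
#' @param meta A \code{QcMetadata} from \code{\link{qcMetadata}}.
#' @param strict Logical; treat liver range and activity fraction as
#'   independent rules instead of a joint criterion.
#' @return A list with \code{pass} (logical) and \code{violations}
#'   (character vector naming every violated rule).
#' @examples
#' qcCheck(qcMetadata(2.0, 6.0, 0.65))
#' @export
qcCheck <- function(meta, strict = FALSE) {
  if (!inherits(meta, "QcMetadata"))
    stop("meta must be constructed with qcMetadata()")
  violations <- character()
  if (!isTRUE(meta$complete_scan))
    violations <- c(violations, "incomplete scan")
  if (!isTRUE(meta$dicom_fields_present))
    violations <- c(violations, "essential DICOM data missing")
  liver_out <- meta$liver_suv_mean < 1.3 || meta$liver_suv_mean > 3.0
  activity_out <- meta$total_image_activity_fraction < 0.50 ||
    meta$total_image_activity_fraction > 0.80
  if (strict) {
    if (liver_out)
      violations <- c(violations, "liver SUVmean outside 1.3-3.0")
    if (activity_out)
      violations <- c(violations, "image activity fraction outside 50-80%")
  } else if (liver_out && activity_out) {
    violations <- c(violations,
      "liver SUVmean outside 1.3-3.0 and image activity fraction outside 50-80%")
  }
  if (meta$plasma_glucose_mmol_per_L >= 11)
    violations <- c(violations, "plasma glucose >= 11 mmol/L")
  list(pass = length(violations) == 0L, violations = violations)
}
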