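#' Lesion dissemination features
#'
#' Patient-level metrics of how far disease is spread across the body,
#' computed from pairwise Euclidean distances (mm) between the SUVmax
#' locations of the lesions:
#' \itemize{
#'   \item \code{dmax_patient_mm}: distance between the two lesions furthest
#'     apart;
#'   \item \code{dmax_bulk_mm}: largest distance from the bulk lesion (the
#'     one with the largest MTV) to any other lesion;
#'   \item \code{spread_bulk_mm}: sum of distances from the bulk lesion to
#'     all other lesions;
#'   \item \code{spread_patient_mm}: sum of distances from all lesions to all
#'     the other lesions (ordered pairs by default, so each unordered pair
#'     counts twice; set \code{ordered_pairs = FALSE} for the unordered
#'     convention).
#' }
#' All four are 0 for a single-lesion patient.
#'
#' @param locations_mm n x 3 matrix of lesion SUVmax locations (mm).
#' @param mtv_ml numeric(n) lesion volumes, used to identify the bulk lesion
#'   (ties broken by lowest lesion index).
#' @param ordered_pairs Logical; see above.
#' @return Named list: \code{n_lesions}, \code{dmax_patient_mm},
#'   \code{dmax_bulk_mm}, \code{spread_patient_mm}, \code{spread_bulk_mm},
#'   \code{bulk_lesion}.
#' @examples
#' disseminationFeatures(rbind(c(0, 0, 0), c(30, 40, 0)), c(10, 2))
#' @export
disseminationFeatures <- function(locations_mm, mtv_ml,
                                  ordered_pairs = TRUE) {
  locations_mm <- as.matrix(locations_mm)
  if (anyNA(locations_mm)) stop("missing lesion locations")
  n <- nrow(locations_mm)
  stopifnot(length(mtv_ml) == n, n >= 1L)
  bulk <- which.max(mtv_ml)  # which.max takes the first on ties
  if (n == 1L) {
    return(list(n_lesions = 1L, dmax_patient_mm = 0, dmax_bulk_mm = 0,
                spread_patient_mm = 0, spread_bulk_mm = 0,
                bulk_lesion = bulk))
  }
  dm <- as.matrix(stats::dist(locations_mm))
  spread_patient <- sum(dm)
  if (!ordered_pairs) spread_patient <- spread_patient / 2
  list(
    n_lesions = n,
    dmax_patient_mm = max(dm),
    dmax_bulk_mm = max(dm[bulk, ]),
    spread_patient_mm = spread_patient,
    spread_bulk_mm = sum(dm[bulk, ]),
    bulk_lesion = bulk
  )
}

#' Height correction of Dmax_bulk
#'
#' Divides the bulk dissemination distance by patient height, removing the
#' trivial dependence of body-scale distances on patient size. Both
#' quantities are taken in the same unit, so the result is dimensionless
#' (mm/mm).
#'
#' @param dmax_bulk_mm Dmax_bulk in mm.
#' @param height_cm Patient height in cm (> 0).
#' @return numeric(1), dmax_bulk / height.
#' @export
heightCorrectDmax <- function(dmax_bulk_mm, height_cm) {
  if (any(height_cm <= 0)) stop("height must be positive")
  dmax_bulk_mm / (height_cm * 10)
}

#' Index lesions: largest and hottest
#'
#' Identifies the lesion with the largest MTV and the lesion with the
#' highest SUVmax; lesion-level radiomics models are built on these two
#' index lesions. Ties are broken by the lowest lesion label so the choice
#' is deterministic.
#'
#' @param mtv_ml numeric(n) lesion volumes.
#' @param suv_max numeric(n) lesion SUVmax values.
#' @return list with \code{largest_lesion_id} and \code{hottest_lesion_id}
#'   (1-based indices into the input vectors).
#' @export
selectIndexLesions <- function(mtv_ml, suv_max) {
  stopifnot(length(mtv_ml) == length(suv_max), length(mtv_ml) >= 1L)
  list(largest_lesion_id = which.max(mtv_ml),
       hottest_lesion_id = which.max(suv_max))
}
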