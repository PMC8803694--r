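# Pipeline orchestration: each stage reads validated inputs from disk,
# writes its outputs plus a config snapshot and tool version, and is
# deterministic given inputs + seed.

writeRunSnapshot <- function(dir, stage, params) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snap <- list(
    tool = "lymphoradiomics",
    version = as.character(utils::packageVersion("lymphoradiomics")),
    stage = stage,
    params = params,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(snap, file.path(dir, paste0("run_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(snap)
}

#' Pipeline stage: simulate a synthetic cohort
#'
#' Generates a phantom cohort to \code{out_dir} (NIfTI SUV images,
#' \code{clinical.csv}, \code{outcomes.csv}, \code{truth.csv},
#' \code{manifest.json}) and records a config snapshot.
#'
#' @param out_dir Output directory.
#' @param n_patients Cohort size.
#' @param seed Cohort seed.
#' @param config Optional \code{\link{phantomConfig}} overriding
#'   \code{n_patients}/\code{seed}.
#' @param render Render SUV images (default TRUE).
#' @return Invisibly, the cohort list (see
#'   \code{\link{generatePhantomCohort}}).
#' @export
runSimulate <- function(out_dir, n_patients = 40L, seed = 1L,
                        config = NULL, render = TRUE) {
  cfg <- config %||% phantomConfig(n_patients = n_patients, seed = seed)
  writeRunSnapshot(out_dir, "simulate", unclass(cfg))
  generatePhantomCohort(cfg, dir = out_dir, render = render)
}

#' Pipeline stage: QC + segmentation
#'
#' Runs scan quality control and SUV-threshold lesion preselection for
#' every NIfTI image in \code{image_dir}, optionally applying a JSON edit
#' script per patient, and writes label images plus a per-patient decision
#' log (\code{segmentation_log.csv}) recording QC outcomes and
#' segmentation flags such as \code{"no FDG-avid lesions"}.
#'
#' @param image_dir Directory of \code{<patient_id>.nii(.gz)} SUV images.
#' @param out_dir Output directory for \code{<patient_id>_labels.nii.gz}.
#' @param clinical_csv Optional clinical table carrying QC columns
#'   (\code{liver_suv_mean}, \code{plasma_glucose},
#'   \code{activity_fraction}, \code{complete_scan}, \code{dicom_ok});
#'   patients failing QC are flagged and skipped.
#' @param edits Optional named list (patient id -> edit list) in the
#'   \code{\link{applyEditScript}} format, or a path to such a JSON file.
#' @return Invisibly, the decision-log data.frame.
#' @export
runSegment <- function(image_dir, out_dir, clinical_csv = NULL,
                       edits = NULL) {
  paths <- sort(list.files(image_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(paths)) stop("no NIfTI images found in ", image_dir)
  if (is.character(edits)) edits <- jsonlite::read_json(edits)
  qc_tab <- if (!is.null(clinical_csv))
    utils::read.csv(clinical_csv, stringsAsFactors = FALSE) else NULL
  writeRunSnapshot(out_dir, "segment",
                   list(image_dir = image_dir, n_images = length(paths)))
  log <- list()
  for (p in paths) {
    img <- readSuvImage(p)
    pid <- patientId(img)
    qc_pass <- TRUE; qc_reasons <- ""
    if (!is.null(qc_tab) && pid %in% qc_tab$patient_id) {
      row <- qc_tab[qc_tab$patient_id == pid, ][1, ]
      qc <- qcCheck(qcMetadata(row$liver_suv_mean, row$plasma_glucose,
                               row$activity_fraction,
                               isTRUE(row$complete_scan),
                               isTRUE(row$dicom_ok)))
      qc_pass <- qc$pass
      qc_reasons <- paste(qc$violations, collapse = "; ")
    }
    n_lesions <- NA_integer_; flags <- ""
    if (qc_pass) {
      seg <- preselectLesions(img)
      if (!is.null(edits) && pid %in% names(edits))
        seg <- applyEditScript(seg, img, edits[[pid]])
      writeSegmentation(seg, file.path(out_dir,
                                       paste0(pid, "_labels.nii.gz")))
      n_lesions <- lesionCount(seg)
      flags <- paste(segmentationFlags(seg), collapse = "; ")
    }
    log[[pid]] <- data.frame(patient_id = pid, qc_pass = qc_pass,
                             qc_reasons = qc_reasons,
                             n_lesions = n_lesions, flags = flags,
                             stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, c(log, list(make.row.names = FALSE)))
  utils::write.csv(log, file.path(out_dir, "segmentation_log.csv"),
                   row.names = FALSE)
  invisible(log)
}

#' Pipeline stage: feature extraction
#'
#' Computes the lesion-level and patient-level feature tables for every
#' patient with a label image, writing \code{features_patient.csv} and
#' \code{features_lesion.csv} (tidy CSVs, one row per patient / lesion).
#'
#' @param image_dir Directory of SUV images.
#' @param label_dir Directory of \code{<patient_id>_labels.nii.gz} images.
#' @param out_dir Output directory.
#' @param clinical_csv Optional clinical table providing \code{height_cm}
#'   for the height-corrected Dmax_bulk.
#' @return Invisibly, list(patient, lesion) of data.frames.
#' @export
runExtract <- function(image_dir, label_dir, out_dir, clinical_csv = NULL) {
  lpaths <- sort(list.files(label_dir, pattern = "_labels\\.nii(\\.gz)?$",
                            full.names = TRUE))
  if (!length(lpaths)) stop("no label images found in ", label_dir)
  heights <- NULL
  if (!is.null(clinical_csv)) {
    cl <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
    heights <- stats::setNames(cl$height_cm, cl$patient_id)
  }
  writeRunSnapshot(out_dir, "extract",
                   list(image_dir = image_dir, label_dir = label_dir))
  pat <- list(); les <- list()
  for (lp in lpaths) {
    pid <- sub("_labels\\.nii(\\.gz)?$", "", basename(lp))
    ip <- file.path(image_dir, paste0(pid, ".nii.gz"))
    if (!file.exists(ip)) ip <- file.path(image_dir, paste0(pid, ".nii"))
    if (!file.exists(ip)) stop("missing SUV image for patient ", pid)
    img <- readSuvImage(ip, patientId = pid)
    seg <- readSegmentation(lp)
    h <- if (!is.null(heights) && pid %in% names(heights))
      heights[[pid]] else NA_real_
    fx <- extractPatientFeatures(img, seg, height_cm = h)
    if (anyNA(fx$patient[, c("mtv_ml", "suv_max", "suv_peak", "suv_mean",
                             "tlg", "sphericity", "lzhge")]))
      stop("NaN features for patient ", pid)
    pat[[pid]] <- fx$patient
    les[[pid]] <- fx$lesions
  }
  patient <- do.call(rbind, c(pat, list(make.row.names = FALSE)))
  lesion <- do.call(rbind, c(les, list(make.row.names = FALSE)))
  utils::write.csv(patient, file.path(out_dir, "features_patient.csv"),
                   row.names = FALSE)
  utils::write.csv(lesion, file.path(out_dir, "features_lesion.csv"),
                   row.names = FALSE)
  invisible(list(patient = patient, lesion = lesion))
}

#' Pipeline stage: model fitting and evaluation
#'
#' Runs the six-model evaluation (\code{\link{runModelSuite}}) on the
#' primary 2-year TTP endpoint and the 2-year PFS sensitivity analysis,
#' writing \code{table4.csv}, \code{table4_pfs.csv} and \code{report.json}.
#'
#' @param features_csv,lesion_features_csv,clinical_csv,outcomes_csv Input
#'   tables (as written by \code{\link{runExtract}} /
#'   \code{\link{runSimulate}}).
#' @param out_dir Output directory.
#' @param cv_repeats,seed See \code{\link{runModelSuite}}.
#' @param models Integer subset of 1:6.
#' @return Invisibly, list(ttp, pfs) of \code{ModelSuiteReport}s.
#' @export
runModel <- function(features_csv, lesion_features_csv, clinical_csv,
                     outcomes_csv, out_dir, cv_repeats = 200L, seed = 1L,
                     models = 1:6) {
  features <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  lesions <- utils::read.csv(lesion_features_csv, stringsAsFactors = FALSE)
  clinical <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(outcomes_csv, stringsAsFactors = FALSE)
  # bulky flag travels with the image-derived features
  if ("bulky" %in% names(features) && !"bulky" %in% names(clinical))
    clinical <- merge(clinical, features[, c("patient_id", "bulky")],
                      by = "patient_id", sort = FALSE)
  writeRunSnapshot(out_dir, "model",
                   list(cv_repeats = cv_repeats, seed = seed,
                        models = models))
  ttp <- runModelSuite(features, lesions, clinical, outcomes,
                       endpoint = "TTP2y", cv_repeats = cv_repeats,
                       seed = seed, models = models)
  pfs <- runModelSuite(features, lesions, clinical, outcomes,
                       endpoint = "PFS2y", cv_repeats = cv_repeats,
                       seed = seed, models = models)
  utils::write.csv(ttp$table4, file.path(out_dir, "table4.csv"),
                   row.names = FALSE)
  utils::write.csv(pfs$table4, file.path(out_dir, "table4_pfs.csv"),
                   row.names = FALSE)
  report <- list(
    endpoint_primary = "TTP2y",
    n_evaluable = ttp$n_evaluable,
    n_events = ttp$n_events,
    table4 = ttp$table4,
    table4_pfs = pfs$table4,
    delong_p = as.data.frame(ttp$delong_p)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(ttp = ttp, pfs = pfs))
}

#' Pipeline stage: human-readable report
#'
#' Summarizes a \code{report.json} produced by \code{\link{runModel}} as
#' text.
#'
#' @param report_json Path to \code{report.json}.
#' @param file Optional output file; default prints to the console.
#' @return Invisibly, the character vector of report lines.
#' @export
runReport <- function(report_json, file = NULL) {
  rep <- jsonlite::read_json(report_json, simplifyVector = TRUE)
  lines <- c(
    sprintf("lymphoradiomics report (%s)", rep$endpoint_primary),
    sprintf("evaluable patients: %d, events: %d", rep$n_evaluable,
            rep$n_events),
    "",
    sprintf("%-8s %-18s %6s %6s %6s %6s %6s %6s", "model", "estimator",
            "AUC", "CV-AUC", "sens", "spec", "PPV", "NPV")
  )
  t4 <- rep$table4
  for (i in seq_len(nrow(t4))) {
    lines <- c(lines, sprintf("%-8s %-18s %6.3f %6.3f %6.3f %6.3f %6.3f %6.3f",
                              t4$model[i], t4$estimator[i], t4$auc[i],
                              t4$cv_auc[i], t4$sens[i], t4$spec[i],
                              t4$ppv[i], t4$npv[i]))
  }
  if (is.null(file)) cat(lines, sep = "\n") else
    writeLines(lines, file)
  invisible(lines)
}
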