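#' Configuration for the synthetic PET cohort generator
#'
#' Defines the study conditions emulated by the phantom module: a body-scale
#' SUV grid, a liver reference region, multi-lesion Gaussian-profile uptake
#' with controllable count/volume/intensity/spatial spread, clinical
#' covariates correlated with tumor burden, and 2-year time-to-progression
#' outcomes drawn from a logistic model on ln(MTV), ln(SUVpeak), Dmax_bulk,
#' WHO performance status >= 1 and age > 60, with death-without-progression
#' and loss-to-follow-up censoring so that TTP and PFS endpoints differ.
#'
#' Defaults are calibrated once so that, at large n, the 2-year event
#' prevalence is close to 16\% and the covariate mix (age > 60 about two
#' thirds, elevated LDH about two thirds, advanced stage predominant,
#' multi-lesion disease with a heavy-tailed volume distribution) resembles a
#' typical first-line DLBCL trial population.
#'
#' @param n_patients Number of patients.
#' @param grid_shape integer(3) voxel grid (default 96 x 96 x 192).
#' @param voxel_spacing_mm numeric(3) voxel spacing (default 4 mm isotropic;
#'   2 mm is supported but slower).
#' @param lesion_count_dist list(size, mu): lesion count is
#'   1 + negative-binomial(size, mu), so support is >= 1.
#' @param lesion_volume_dist_mL list(meanlog, sdlog, min, max): truncated
#'   log-normal nominal super-threshold volumes (mL).
#' @param lesion_peak_suv_dist list(meanlog, sdlog, min, max): truncated
#'   log-normal lesion peak SUV; the minimum stays above the 4.0 segmentation
#'   threshold so every planted lesion is segmentable.
#' @param background_suv list(mean, sd) of soft-tissue background SUV.
#' @param liver_suv_mean Mean SUV of the liver ellipsoid (inside the EANM
#'   1.3--3.0 window).
#' @param dissemination_scale_mm Standard deviation scale of lesion-center
#'   placement; larger values spread lesions further apart.
#' @param outcome_coefs Named numeric: \code{intercept}, \code{ln_mtv},
#'   \code{ln_suvpeak}, \code{dmax_bulk} (per mm), \code{who_ge1},
#'   \code{age_gt60}.
#' @param censoring list(death_wo_progression_prob, ltfu_prob,
#'   admin_censor_months, late_event_prob, late_event_scale_months).
#' @param seed Integer cohort seed.
#' @return A \code{PhantomConfig} list.
#' @export
phantomConfig <- function(
  n_patients = 100L,
  grid_shape = c(96L, 96L, 192L),
  voxel_spacing_mm = c(4, 4, 4),
  lesion_count_dist = list(size = 0.9, mu = 7),
  lesion_volume_dist_mL = list(meanlog = log(18), sdlog = 1.1,
                               min = 4, max = 600),
  lesion_peak_suv_dist = list(meanlog = log(12), sdlog = 0.5,
                              min = 5, max = 50),
  background_suv = list(mean = 1.0, sd = 0.12),
  liver_suv_mean = 2.2,
  dissemination_scale_mm = 110,
  outcome_coefs = c(intercept = .defaultIntercept, ln_mtv = 0.6,
                    ln_suvpeak = 1.0, dmax_bulk = 0.005, who_ge1 = 0.8,
                    age_gt60 = 0.7),
  censoring = list(death_wo_progression_prob = 0.04, ltfu_prob = 0.02,
                   admin_censor_months = 36, late_event_prob = 0.15,
                   late_event_scale_months = 18),
  seed = 1L
) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    lesion_count_dist = lesion_count_dist,
    lesion_volume_dist_mL = lesion_volume_dist_mL,
    lesion_peak_suv_dist = lesion_peak_suv_dist,
    background_suv = background_suv,
    liver_suv_mean = liver_suv_mean,
    dissemination_scale_mm = dissemination_scale_mm,
    outcome_coefs = outcome_coefs,
    censoring = censoring,
    seed = as.integer(seed)
  )
  validatePhantomConfig(cfg)
  structure(cfg, class = "PhantomConfig")
}

validatePhantomConfig <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1L,
    length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 8L),
    all(cfg$voxel_spacing_mm > 0),
    cfg$lesion_count_dist$size > 0, cfg$lesion_count_dist$mu >= 0,
    cfg$lesion_volume_dist_mL$min > 0,
    cfg$lesion_volume_dist_mL$max > cfg$lesion_volume_dist_mL$min,
    cfg$lesion_peak_suv_dist$min > 4.0,
    cfg$background_suv$mean >= 0, cfg$background_suv$sd >= 0,
    cfg$dissemination_scale_mm >= 0,
    all(c("intercept", "ln_mtv", "ln_suvpeak", "dmax_bulk", "who_ge1",
          "age_gt60") %in% names(cfg$outcome_coefs)),
    cfg$censoring$death_wo_progression_prob >= 0,
    cfg$censoring$ltfu_prob >= 0,
    cfg$censoring$admin_censor_months > 24
  )
  # the placement envelope must fit inside the physical grid
  extent <- cfg$grid_shape * cfg$voxel_spacing_mm
  if (2 * cfg$dissemination_scale_mm > max(extent))
    stop("dissemination_scale_mm too large for the grid extent")
  invisible(cfg)
}

# Calibration constants for the default configuration, frozen once:
# moments of ln(total nominal MTV) under the default lesion count/volume
# distributions (used to standardize tumor burden when drawing correlated
# clinical covariates), and the logistic intercept giving ~16% 2-year event
# prevalence under the default coefficients.
.lnMtvMoments <- c(mean = 5.01, sd = 1.27)
.defaultIntercept <- -10.68

# Per-patient RNG streams: patient seeds are drawn from the master cohort
# stream, so streams of different patients (and of different cohorts) are
# decorrelated even for adjacent cohort seeds or patient indices.
phantomPatientSeeds <- function(cfg, n) {
  set.seed(cfg$seed)
  sample.int(.Machine$integer.max - 1L, n)
}

truncLognormal <- function(n, meanlog, sdlog, min, max) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= min & draw <= max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Liver ellipsoid parameters (mm, relative to grid extent).
liverGeometry <- function(cfg) {
  extent <- cfg$grid_shape * cfg$voxel_spacing_mm
  list(center = extent * c(0.32, 0.42, 0.64),
       semiaxes = c(75, 55, 65))
}

# Radius (mm) at which a Gaussian blob of given peak crosses the SUV-4
# threshold once the expected background is added.
blobThresholdRadius <- function(volume_mL) (3 * volume_mL * 1000 / (4 * pi))^(1 / 3)

blobSigma <- function(volume_mL, peak, bg_mean, threshold = 4.0) {
  r <- blobThresholdRadius(volume_mL)
  r / sqrt(2 * log(peak / (threshold - bg_mean)))
}

# Draw non-overlapping lesion centers. Proposals are Gaussian around the
# torso center with per-axis sd (0.35, 0.35, 1) x dissemination_scale_mm;
# when proposals keep colliding (including the degenerate scale-0 case) the
# proposal sd is gradually inflated, which enforces a minimum separation.
placeLesionCenters <- function(cfg, radii_mm, patient_index) {
  extent <- cfg$grid_shape * cfg$voxel_spacing_mm
  torso <- extent * c(0.5, 0.5, 0.45)
  liver <- liverGeometry(cfg)
  axis_sd <- c(0.35, 0.35, 1) * cfg$dissemination_scale_mm
  centers <- matrix(NA_real_, length(radii_mm), 3)
  for (i in seq_along(radii_mm)) {
    placed <- FALSE
    for (attempt in seq_len(600L)) {
      if (attempt <= 60L) {
        inflate <- 1 + 0.15 * (attempt - 1)
        sd_eff <- pmax(axis_sd * inflate, 4 * (attempt - 1))
        prop <- torso + stats::rnorm(3) * sd_eff
      } else {
        # crowded patient: fall back to uniform proposals over the grid
        m <- radii_mm[i] + 8
        prop <- stats::runif(3, m, extent - m)
      }
      margin <- radii_mm[i] + 8
      if (any(prop < margin) || any(prop > extent - margin)) next
      # keep clear of the liver ellipsoid
      rel <- (prop - liver$center) / (liver$semiaxes + radii_mm[i] + 8)
      if (sum(rel^2) < 1) next
      if (i > 1L) {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        dmin <- sqrt(rowSums(sweep(prev, 2, prop)^2))
        sep <- radii_mm[i] + radii_mm[seq_len(i - 1L)]
        if (any(dmin < sep + pmax(12, 0.35 * sep))) next
      }
      centers[i, ] <- prop
      placed <- TRUE
      break
    }
    if (!placed)
      stop("lesion placement failed for patient ", patient_index,
           " (lesion ", i, " of ", length(radii_mm), ")")
  }
  centers
}

# Render the SUV grid: background noise + liver ellipsoid + one
# Gaussian-profile blob per lesion. Returns the SuvImage plus, per lesion,
# the noise-free digitized super-threshold volume (the planted ground truth
# segmentation should recover).
renderPhantomImage <- function(cfg, lesions, patient_id) {
  d <- cfg$grid_shape
  sp <- cfg$voxel_spacing_mm
  bg <- cfg$background_suv
  vox <- array(pmax(0, stats::rnorm(prod(d), bg$mean, bg$sd)), d)
  ax <- lapply(seq_len(3), function(a) (seq_len(d[a]) - 0.5) * sp[a])
  # liver
  liver <- liverGeometry(cfg)
  lb <- lapply(seq_len(3), function(a) {
    which(abs(ax[[a]] - liver$center[a]) <= liver$semiaxes[a])
  })
  if (all(lengths(lb) > 0)) {
    rel2 <- outer(outer(((ax[[1]][lb[[1]]] - liver$center[1]) /
                           liver$semiaxes[1])^2,
                        ((ax[[2]][lb[[2]]] - liver$center[2]) /
                           liver$semiaxes[2])^2, "+"),
                  ((ax[[3]][lb[[3]]] - liver$center[3]) /
                     liver$semiaxes[3])^2, "+")
    inside <- rel2 < 1
    block <- vox[lb[[1]], lb[[2]], lb[[3]], drop = FALSE]
    block[inside] <- pmax(0, stats::rnorm(sum(inside), cfg$liver_suv_mean,
                                          0.15))
    vox[lb[[1]], lb[[2]], lb[[3]]] <- block
  }
  digitized_mL <- numeric(nrow(lesions))
  vv <- prod(sp) / 1000
  taper_mm <- 6
  for (i in seq_len(nrow(lesions))) {
    ctr <- as.numeric(lesions[i, c("cx", "cy", "cz")])
    peak <- lesions$peak_suv[i]
    r_thr <- blobThresholdRadius(lesions$volume_mL[i])
    sigma <- blobSigma(lesions$volume_mL[i], peak, bg$mean)
    reach <- r_thr + taper_mm
    box <- lapply(seq_len(3), function(a) {
      which(abs(ax[[a]] - ctr[a]) <= reach)
    })
    if (any(lengths(box) == 0)) next
    d2 <- outer(outer((ax[[1]][box[[1]]] - ctr[1])^2,
                      (ax[[2]][box[[2]]] - ctr[2])^2, "+"),
                (ax[[3]][box[[3]]] - ctr[3])^2, "+")
    dd <- sqrt(d2)
    # Gaussian profile inside the threshold radius; outside, a short linear
    # taper down to zero so lesions have compact support and cannot push a
    # neighbour's threshold boundary outwards (the minimum surface
    # separation enforced at placement exceeds the taper width)
    blob <- peak * exp(-d2 / (2 * sigma^2))
    edge <- peak * exp(-r_thr^2 / (2 * sigma^2))
    outside <- dd > r_thr
    blob[outside] <- edge * pmax(0, 1 - (dd[outside] - r_thr) / taper_mm)
    digitized_mL[i] <- sum(blob + bg$mean >= 4.0) * vv
    vox[box[[1]], box[[2]], box[[3]]] <-
      vox[box[[1]], box[[2]], box[[3]]] + blob
  }
  list(image = SuvImage(vox, sp, patient_id), digitized_mL = digitized_mL)
}

#' Generate one synthetic patient
#'
#' Draws lesion ground truth (count, nominal volumes, peak SUVs, centers),
#' clinical covariates correlated with ln(MTV), a 2-year
#' time-to-progression outcome from the configured logistic model, and
#' (optionally) renders the SUV phantom image.
#'
#' @param cfg A \code{PhantomConfig}.
#' @param patient_index 1-based index; combined with the cohort seed it
#'   determines the patient's private RNG stream.
#' @param render Logical; render the SUV image (set \code{FALSE} for fast
#'   covariate/outcome-only cohorts used in model-level simulations).
#' @param patient_seed Optional pre-computed patient seed (supplied by
#'   \code{\link{generatePhantomCohort}}); when NULL it is re-derived from
#'   the cohort seed.
#' @return A \code{PhantomPatient} list: \code{patient_id}, \code{image}
#'   (NULL when not rendered), \code{true_lesions} (data.frame with centers,
#'   nominal and digitized volumes, peak SUV), \code{clinical},
#'   \code{qc}, \code{outcome}, \code{truth} (true model covariates),
#'   \code{linear_predictor}.
#' @export
generatePhantomPatient <- function(cfg, patient_index = 1L, render = TRUE,
                                   patient_seed = NULL) {
  validatePhantomConfig(cfg)
  if (is.null(patient_seed))
    patient_seed <- phantomPatientSeeds(cfg, patient_index)[patient_index]
  set.seed(patient_seed)
  pid <- sprintf("P%04d", patient_index)

  cd <- cfg$lesion_count_dist
  n_lesions <- 1L + stats::rnbinom(1L, size = cd$size, mu = cd$mu)
  n_lesions <- min(n_lesions, 60L)
  vd <- cfg$lesion_volume_dist_mL
  volumes <- truncLognormal(n_lesions, vd$meanlog, vd$sdlog, vd$min, vd$max)
  pdist <- cfg$lesion_peak_suv_dist
  peaks <- truncLognormal(n_lesions, pdist$meanlog, pdist$sdlog,
                          pdist$min, pdist$max)
  radii <- blobThresholdRadius(volumes)
  centers <- placeLesionCenters(cfg, radii, patient_index)
  lesions <- data.frame(
    lesion = seq_len(n_lesions),
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    volume_mL = volumes, peak_suv = peaks, radius_mm = radii
  )

  # true model covariates from the planted ground truth
  mtv <- sum(volumes)
  ln_mtv <- log(mtv)
  ln_suvpeak <- log(max(peaks))
  bulk <- which.max(volumes)
  dmax_bulk <- if (n_lesions > 1L) {
    max(sqrt(rowSums(sweep(centers, 2, centers[bulk, ])^2)))
  } else 0

  # clinical covariates correlated with standardized tumor burden
  z <- (ln_mtv - .lnMtvMoments["mean"]) / .lnMtvMoments["sd"]
  z <- as.numeric(z)
  age <- round(min(max(stats::rnorm(1, 65, 11), 20), 85))
  who_latent <- 0.8 * z + stats::rnorm(1)
  who_ps <- findInterval(who_latent, c(0.19, 1.44, 2.98, 3.8))
  stage_latent <- 1.0 * z + stats::rnorm(1)
  stage <- findInterval(stage_latent,
                        stats::qnorm(c(0.04, 0.18, 0.38),
                                     sd = sqrt(2))) + 1L
  ldh_uln <- 250
  ldh <- ldh_uln * exp(stats::rnorm(1, 0.25 + 0.3 * z, 0.45))
  extranodal <- stats::rpois(1, exp(0.3 + 0.35 * z))
  sex <- if (stats::runif(1) < 0.51) "M" else "F"
  height <- round(stats::rnorm(1, if (sex == "M") 178 else 166, 7))

  cf <- cfg$outcome_coefs
  lp <- unname(cf["intercept"] + cf["ln_mtv"] * ln_mtv +
               cf["ln_suvpeak"] * ln_suvpeak + cf["dmax_bulk"] * dmax_bulk +
               cf["who_ge1"] * (who_ps >= 1) + cf["age_gt60"] * (age > 60))
  event2y <- stats::runif(1) < logistic(lp)

  cs <- cfg$censoring
  if (event2y) {
    outcome <- list(time_months = stats::runif(1, 0, 24),
                    event_type = "progression")
  } else {
    u <- stats::runif(1)
    if (u < cs$death_wo_progression_prob) {
      outcome <- list(time_months = stats::runif(1, 0, 24),
                      event_type = "death_without_progression")
    } else if (u < cs$death_wo_progression_prob + cs$ltfu_prob) {
      outcome <- list(time_months = stats::runif(1, 0, 24),
                      event_type = "lost_to_followup")
    } else if (stats::runif(1) < cs$late_event_prob) {
      t_late <- 24 + stats::rexp(1, 1 / cs$late_event_scale_months)
      if (t_late < cs$admin_censor_months) {
        outcome <- list(time_months = t_late, event_type = "progression")
      } else {
        outcome <- list(time_months = cs$admin_censor_months,
                        event_type = "administrative_censor")
      }
    } else {
      outcome <- list(time_months = cs$admin_censor_months,
                      event_type = "administrative_censor")
    }
  }

  qc <- list(
    liver_suv_mean = round(min(max(stats::rnorm(1, cfg$liver_suv_mean, 0.2),
                                   1.4), 2.9), 3),
    plasma_glucose = round(max(stats::rnorm(1, 5.6, 1.2), 3), 2),
    activity_fraction = round(stats::runif(1, 0.55, 0.75), 3),
    complete_scan = TRUE,
    dicom_ok = TRUE
  )

  rendered <- if (render) renderPhantomImage(cfg, lesions, pid) else NULL
  if (render) lesions$digitized_mL <- rendered$digitized_mL

  list(
    patient_id = pid,
    image = if (render) rendered$image else NULL,
    true_lesions = lesions,
    clinical = list(age_years = age, sex = sex, ann_arbor_stage = stage,
                    ldh = round(ldh, 1), ldh_uln = ldh_uln,
                    extranodal_sites = extranodal, who_ps = who_ps,
                    height_cm = height),
    qc = qc,
    outcome = outcome,
    truth = list(n_lesions = n_lesions, mtv_ml = mtv, ln_mtv = ln_mtv,
                 ln_suvpeak = ln_suvpeak, dmax_bulk_mm = dmax_bulk,
                 who_ge1 = as.integer(who_ps >= 1),
                 age_gt60 = as.integer(age > 60),
                 event2y = as.integer(event2y)),
    linear_predictor = lp
  )
}

#' Generate a synthetic cohort
#'
#' Generates \code{n_patients} phantom patients deterministically from the
#' cohort seed and optionally writes them to disk as one NIfTI SUV image per
#' patient plus \code{clinical.csv}, \code{outcomes.csv}, \code{truth.csv}
#' and a \code{manifest.json} carrying the configuration, seed and file
#' checksums (byte-identical on rerun).
#'
#' @param cfg A \code{PhantomConfig}.
#' @param dir Output directory (created if needed); NULL keeps everything in
#'   memory.
#' @param render Logical; render SUV images (see
#'   \code{\link{generatePhantomPatient}}).
#' @return Invisibly, a list with \code{patients} (list of PhantomPatient),
#'   \code{clinical}, \code{outcomes}, \code{truth} (data.frames) and
#'   \code{manifest}.
#' @export
generatePhantomCohort <- function(cfg, dir = NULL, render = TRUE) {
  validatePhantomConfig(cfg)
  pseeds <- phantomPatientSeeds(cfg, cfg$n_patients)
  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    patients[[i]] <- generatePhantomPatient(cfg, i, render = render,
                                            patient_seed = pseeds[i])
  }
  clinical <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, as.data.frame(p$clinical),
               as.data.frame(p$qc), stringsAsFactors = FALSE)
  }))
  outcomes <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id,
               time_months = p$outcome$time_months,
               event_type = p$outcome$event_type, stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, as.data.frame(p$truth),
               linear_predictor = p$linear_predictor,
               stringsAsFactors = FALSE)
  }))
  manifest <- list(
    tool = "lymphoradiomics",
    version = as.character(utils::packageVersion("lymphoradiomics")),
    seed = cfg$seed,
    n_patients = cfg$n_patients,
    config = unclass(cfg)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    img_dir <- file.path(dir, "images")
    if (render) dir.create(img_dir, showWarnings = FALSE)
    for (p in patients) {
      if (!is.null(p$image))
        writeSuvImage(p$image, file.path(img_dir,
                                         paste0(p$patient_id, ".nii.gz")))
    }
    utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes, file.path(dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    files <- c("clinical.csv", "outcomes.csv", "truth.csv")
    if (render) files <- c(files, file.path("images",
                                            paste0(clinical$patient_id,
                                                   ".nii.gz")))
    sums <- tools::md5sum(file.path(dir, files))
    manifest$checksums <- stats::setNames(unname(sums), files)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(patients = patients, clinical = clinical,
                 outcomes = outcomes, truth = truth, manifest = manifest))
}
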