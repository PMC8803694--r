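#' Candidate feature sets of the six prediction models
#'
#' Returns the named candidate-feature list for each model: (1) the IPI
#' score alone; (2) the clinical model (IPI components dual-coded plus
#' bulky disease); (3) MTV alone; (4) the limited radiomics model
#' (conventional PET, dissemination and sphericity features at patient
#' level); (5) the implemented lesion-level features of the largest and
#' hottest lesion (fitted with LASSO); (6) the combined clinical +
#' limited-radiomics model.
#'
#' @return Named list of character vectors (column names into the merged
#'   analysis table); model 5 columns carry \code{largest_}/\code{hottest_}
#'   prefixes.
#' @export
modelCandidates <- function() {
  clinical <- c("stage34", "stage_cat", "age_years", "age_gt60",
                "who_ge1", "who_ge2", "en_ge1", "en_gt1",
                "ldh_ratio", "ldh_elevated", "bulky")
  radiomics <- c("mtv_ml", "suv_max", "suv_peak", "suv_mean", "tlg",
                 "n_lesions", "dmax_patient_mm", "dmax_bulk_mm",
                 "spread_patient_mm", "spread_bulk_mm", "sphericity")
  lesion <- c("mtv_ml", "suv_max", "suv_peak", "suv_mean", "tlg",
              "sphericity", "lzhge")
  list(
    model1 = c("ipi_score"),
    model2 = clinical,
    model3 = c("mtv_ml"),
    model4 = radiomics,
    model5 = c(paste0("largest_", lesion), paste0("hottest_", lesion)),
    model6 = union(clinical, radiomics)
  )
}

# Merge patient-level features, index-lesion features, encoded clinical
# variables and endpoint labels into one analysis table.
buildAnalysisTable <- function(features, lesion_features, clinical,
                               outcomes, endpoint = "TTP2y") {
  # the bulky flag is image-derived; let the feature table supply it
  if ("bulky" %in% names(features)) {
    clinical$bulky <- features$bulky[match(clinical$patient_id,
                                           features$patient_id)]
    features <- features[, names(features) != "bulky", drop = FALSE]
  }
  enc <- encodeClinical(clinical)
  # index-lesion feature columns
  lesion_cols <- c("mtv_ml", "suv_max", "suv_peak", "suv_mean", "tlg",
                   "sphericity", "lzhge")
  idx <- features[, c("patient_id", "largest_lesion_id",
                      "hottest_lesion_id")]
  grab <- function(which_id, prefix) {
    rows <- lesion_features[match(
      paste(idx$patient_id, idx[[which_id]]),
      paste(lesion_features$patient_id, lesion_features$lesion_id)), ,
      drop = FALSE]
    out <- rows[, lesion_cols, drop = FALSE]
    names(out) <- paste0(prefix, lesion_cols)
    out
  }
  tab <- cbind(features, grab("largest_lesion_id", "largest_"),
               grab("hottest_lesion_id", "hottest_"))
  tab <- merge(tab, enc, by = "patient_id", sort = FALSE)
  ep <- deriveEndpoints(outcomes, endpoint)
  tab <- merge(tab, ep, by = "patient_id", sort = FALSE)
  tab[order(tab$patient_id), , drop = FALSE]
}

#' Fit and evaluate the six prediction models
#'
#' The full model-evaluation stage: merges the radiomics feature table,
#' encoded clinical predictors and the chosen 2-year endpoint; fits each
#' model (logistic backward selection for models 1-4 and 6, standardized
#' LASSO for model 5) on the evaluable patients (those not censored before
#' the horizon); reports apparent AUC with DeLong 95\% CI, repeated
#' stratified CV-AUC with percentile CI, model log-likelihood,
#' prevalence-based sensitivity/specificity/PPV/NPV, pairwise DeLong
#' p-values, and the survival contrast (Kaplan--Meier + log-rank +
#' univariate Cox with Schoenfeld check) for a high-risk group holding the
#' top \code{km_fraction} of predicted risks (the IPI model uses its
#' high-risk group instead).
#'
#' @param features Patient-level feature table
#'   (\code{\link{extractPatientFeatures}} rows, or equivalent columns).
#' @param lesion_features Lesion-level feature table.
#' @param clinical Clinical covariate table.
#' @param outcomes Outcome table (\code{patient_id}, \code{time_months},
#'   \code{event_type}).
#' @param endpoint \code{"TTP2y"} (primary) or \code{"PFS2y"} (sensitivity
#'   analysis).
#' @param cv_repeats,cv_folds Cross-validation settings (defaults 200 x 5;
#'   2000 repeats reproduces the full analysis setting).
#' @param km_fraction Fraction of patients forming the KM high-risk group
#'   (default 0.16, the event prevalence).
#' @param seed Seed for all CV resampling.
#' @param models Integer subset of 1:6 (default all).
#' @return A \code{ModelSuiteReport} list: \code{table4} (one row per
#'   model: auc, auc_lo, auc_hi, cv_auc, cv_lo, cv_hi, loglik, spec, sens,
#'   npv, ppv, hr, hr_lo, hr_hi, logrank_p, schoenfeld_p), \code{delong_p}
#'   (pairwise matrix), \code{fits}, \code{risks}, \code{endpoint},
#'   \code{n_evaluable}, \code{n_events}.
#' @export
runModelSuite <- function(features, lesion_features, clinical, outcomes,
                          endpoint = c("TTP2y", "PFS2y"),
                          cv_repeats = 200L, cv_folds = 5L,
                          km_fraction = 0.16, seed = 1L,
                          models = 1:6) {
  endpoint <- match.arg(endpoint)
  tab <- buildAnalysisTable(features, lesion_features, clinical, outcomes,
                            endpoint)
  cand <- modelCandidates()[models]
  evaluable <- !is.na(tab$y)
  y <- tab$y[evaluable]
  n_events <- sum(y)
  rows <- list()
  fits <- list()
  risks_eval <- list()
  for (mi in seq_along(cand)) {
    mname <- names(cand)[mi]
    cols <- cand[[mi]]
    missing_cols <- setdiff(cols, names(tab))
    if (length(missing_cols))
      stop(mname, ": missing candidate columns ",
           paste(missing_cols, collapse = ", "))
    X <- tab[evaluable, cols, drop = FALSE]
    is_lasso <- mname == "model5"
    fitter <- if (is_lasso) makeLassoFitter(seed = seed) else
      makeBackwardFitter()
    fit_obj <- fitter(X, y)
    fit <- fit_obj$fit
    risks <- fit_obj$predict(X)
    ad <- aucDelong(risks, y)
    cv <- repeatedStratifiedCV(X, y, fitter, folds = cv_folds,
                               repeats = cv_repeats,
                               seed = seed + 1000L * mi)
    strat <- if (mname == "model1") {
      stratifyByPrevalence(risks, y,
                           high_risk = tab$ipi_group[evaluable] == "high")
    } else {
      stratifyByPrevalence(risks, y, k_high = n_events)
    }
    # survival contrast on all patients (KM uses the censored too)
    risks_all <- fit_obj$predict(tab[, cols, drop = FALSE])
    high_all <- if (mname == "model1") {
      tab$ipi_group == "high"
    } else {
      k <- max(1L, round(km_fraction * nrow(tab)))
      ordg <- order(-risks_all, seq_along(risks_all))
      h <- logical(nrow(tab)); h[ordg[seq_len(k)]] <- TRUE
      h
    }
    km <- kmLogrank(tab$survival_time, tab$survival_event, high_all)
    cx <- coxUnivariate(tab$survival_time, tab$survival_event, high_all)
    rows[[mname]] <- data.frame(
      model = mname,
      estimator = if (is_lasso) "lasso" else "logistic_backward",
      auc = ad$auc, auc_lo = ad$ci[1], auc_hi = ad$ci[2],
      cv_auc = cv$cv_auc, cv_lo = cv$ci[1], cv_hi = cv$ci[2],
      loglik = fit$loglik,
      spec = strat$specificity, sens = strat$sensitivity,
      npv = strat$npv, ppv = strat$ppv,
      hr = cx$hr, hr_lo = cx$ci[1], hr_hi = cx$ci[2],
      logrank_p = km$logrank_p, schoenfeld_p = cx$schoenfeld_p,
      selected = paste(fit$selected, collapse = "+"),
      stringsAsFactors = FALSE
    )
    fits[[mname]] <- fit
    risks_eval[[mname]] <- risks
  }
  nm <- names(cand)
  dl <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    dl[i, j] <- if (i == j) 1 else
      delongCompare(risks_eval[[i]], risks_eval[[j]], y)$p
  }
  structure(list(
    table4 = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    delong_p = dl,
    fits = fits,
    risks = risks_eval,
    endpoint = endpoint,
    n_evaluable = sum(evaluable),
    n_events = n_events,
    analysis_table = tab
  ), class = "ModelSuiteReport")
}

#' @export
print.ModelSuiteReport <- function(x, ...) {
  cat("ModelSuiteReport (", x$endpoint, "): ", x$n_evaluable,
      " evaluable patients, ", x$n_events, " events\n\n", sep = "")
  t4 <- x$table4
  num <- vapply(t4, is.numeric, logical(1))
  t4[num] <- lapply(t4[num], function(v) round(v, 3))
  print(t4[, c("model", "auc", "cv_auc", "loglik", "spec", "sens",
               "npv", "ppv", "hr", "logrank_p")], row.names = FALSE)
  invisible(x)
}
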