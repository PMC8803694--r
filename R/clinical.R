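#' Derive a binary 2-year endpoint from an outcome record
#'
#' Converts a time-to-event record into the 2-year endpoint labels used by
#' the prediction models, together with the survival time/indicator used by
#' Kaplan--Meier and Cox analyses.
#'
#' Under 2-year TTP (time to progression), progression at or before 24
#' months is an event; death without progression is treated as censoring at
#' the date of death, so any censoring before 24 months (death without
#' progression, loss to follow-up, administrative) leads to exclusion from
#' the binary endpoint; everyone else is a non-event. Under 2-year PFS
#' (progression-free survival), progression or death at or before 24 months
#' is an event and only non-death censoring before 24 months excludes.
#'
#' @param time_months Non-negative event/censoring time in months.
#' @param event_type One of \code{"progression"},
#'   \code{"death_without_progression"}, \code{"lost_to_followup"},
#'   \code{"administrative_censor"}.
#' @param endpoint \code{"TTP2y"} (default) or \code{"PFS2y"}.
#' @param horizon_months Endpoint horizon (default 24).
#' @return A list: \code{label} (\code{"event"}, \code{"non_event"} or
#'   \code{"excluded"}), \code{survival_time}, \code{survival_event}
#'   (0/1 indicator under the endpoint's event definition).
#' @export
deriveEndpoint <- function(time_months, event_type,
                           endpoint = c("TTP2y", "PFS2y"),
                           horizon_months = 24) {
  endpoint <- match.arg(endpoint)
  if (is.na(time_months) || time_months < 0)
    stop("time_months must be non-negative")
  types <- c("progression", "death_without_progression", "lost_to_followup",
             "administrative_censor")
  if (!event_type %in% types)
    stop("unknown event_type: ", event_type)
  is_event <- if (endpoint == "TTP2y") {
    event_type == "progression"
  } else {
    event_type %in% c("progression", "death_without_progression")
  }
  label <- if (is_event && time_months <= horizon_months) {
    "event"
  } else if (!is_event && time_months < horizon_months) {
    "excluded"
  } else {
    "non_event"
  }
  list(label = label,
       survival_time = time_months,
       survival_event = as.integer(is_event))
}

#' @rdname deriveEndpoint
#' @param outcomes data.frame with columns \code{patient_id},
#'   \code{time_months}, \code{event_type}.
#' @return \code{deriveEndpoints} returns a data.frame with one row per
#'   patient: \code{patient_id}, \code{label}, \code{y} (1 event, 0
#'   non-event, NA excluded), \code{survival_time}, \code{survival_event}.
#' @export
deriveEndpoints <- function(outcomes, endpoint = c("TTP2y", "PFS2y"),
                            horizon_months = 24) {
  endpoint <- match.arg(endpoint)
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    e <- deriveEndpoint(outcomes$time_months[i], outcomes$event_type[i],
                        endpoint, horizon_months)
    data.frame(patient_id = outcomes$patient_id[i], label = e$label,
               y = switch(e$label, event = 1L, non_event = 0L,
                          excluded = NA_integer_),
               survival_time = e$survival_time,
               survival_event = e$survival_event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' International Prognostic Index (IPI)
#'
#' One adverse point each for age > 60 years, Ann Arbor stage III--IV,
#' LDH above the upper limit of normal, WHO performance status >= 2 and
#' more than one extranodal site. Groups: 0--1 low, 2 low-intermediate,
#' 3 high-intermediate, 4--5 high. A missing WHO performance status is
#' imputed as 0.
#'
#' @param age_years,ann_arbor_stage,ldh,ldh_uln,extranodal_sites,who_ps
#'   Clinical components; \code{who_ps} may be NA.
#' @return A list with \code{score} (0--5) and \code{group}.
#' @examples
#' ipiScore(70, 4, 375, 250, 1, 1)  # 3 adverse factors: high-intermediate
#' @export
ipiScore <- function(age_years, ann_arbor_stage, ldh, ldh_uln,
                     extranodal_sites, who_ps) {
  stopifnot(ldh_uln > 0, ann_arbor_stage %in% 1:4)
  if (is.na(who_ps)) who_ps <- 0L
  score <- (age_years > 60) + (ann_arbor_stage >= 3) + (ldh > ldh_uln) +
    (who_ps >= 2) + (extranodal_sites > 1)
  group <- c("low", "low", "low-intermediate", "high-intermediate",
             "high", "high")[score + 1L]
  list(score = as.integer(score), group = group)
}

#' Encode clinical predictors
#'
#' Emits the dual-coded clinical candidate features: Ann Arbor stage both
#' dichotomously (III--IV) and categorically, LDH both dichotomously
#' (> ULN) and continuously (LDH/ULN), extranodal involvement at the >= 1
#' and > 1 cut-offs, WHO performance status at the >= 1 and >= 2 cut-offs,
#' age continuously and dichotomized at 60 years, and the bulky-disease
#' flag. Missing WHO performance status is imputed as 0 (with a warning
#' listing the patients). Continuous columns are subject to the downstream
#' skewness-based log-transform rule.
#'
#' @param clinical data.frame with columns \code{patient_id},
#'   \code{age_years}, \code{ann_arbor_stage}, \code{ldh}, \code{ldh_uln},
#'   \code{extranodal_sites}, \code{who_ps}, and optionally \code{bulky}.
#' @return A data.frame of encoded features plus \code{ipi_score} and
#'   \code{ipi_group}.
#' @export
encodeClinical <- function(clinical) {
  req <- c("patient_id", "age_years", "ann_arbor_stage", "ldh", "ldh_uln",
           "extranodal_sites", "who_ps")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  who <- clinical$who_ps
  if (anyNA(who)) {
    warning("WHO performance status missing for ",
            sum(is.na(who)), " patient(s); imputed as 0: ",
            paste(clinical$patient_id[is.na(who)], collapse = ", "))
    who[is.na(who)] <- 0L
  }
  ipi <- mapply(function(a, s, l, u, e, w) {
    sc <- ipiScore(a, s, l, u, e, w)
    c(sc$score, sc$group)
  }, clinical$age_years, clinical$ann_arbor_stage, clinical$ldh,
     clinical$ldh_uln, clinical$extranodal_sites, who)
  data.frame(
    patient_id = clinical$patient_id,
    age_years = clinical$age_years,
    age_gt60 = as.integer(clinical$age_years > 60),
    stage34 = as.integer(clinical$ann_arbor_stage >= 3),
    stage_cat = factor(clinical$ann_arbor_stage, levels = 1:4),
    ldh_ratio = clinical$ldh / clinical$ldh_uln,
    ldh_elevated = as.integer(clinical$ldh > clinical$ldh_uln),
    en_ge1 = as.integer(clinical$extranodal_sites >= 1),
    en_gt1 = as.integer(clinical$extranodal_sites > 1),
    who_ge1 = as.integer(who >= 1),
    who_ge2 = as.integer(who >= 2),
    bulky = as.integer(clinical$bulky %||% rep(NA_integer_, nrow(clinical))),
    ipi_score = as.integer(ipi[1, ]),
    ipi_group = ipi[2, ],
    stringsAsFactors = FALSE
  )
}
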