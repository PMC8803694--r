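#' DeLong AUC with variance and confidence interval
#'
#' Nonparametric AUC (Mann--Whitney estimator, ties counted 1/2) with the
#' DeLong structural-component variance and a normal-approximation 95\%
#' confidence interval truncated to [0, 1].
#'
#' @param risks Numeric predicted risks (higher = more likely event).
#' @param labels Binary outcome (0/1 or logical); both classes must be
#'   present.
#' @return list: \code{auc}, \code{variance}, \code{ci} (length 2),
#'   \code{v10}, \code{v01} (structural components, used by the paired
#'   test).
#' @export
aucDelong <- function(risks, labels) {
  labels <- as.integer(labels)
  stopifnot(length(risks) == length(labels), all(labels %in% 0:1))
  x <- risks[labels == 1L]
  y <- risks[labels == 0L]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both outcome classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # per-event component
  v01 <- colMeans(psi)  # per-non-event component
  variance <- stats::var(v10) / m + stats::var(v01) / n
  if (m == 1L) variance <- stats::var(v01) / n
  if (n == 1L) variance <- stats::var(v10) / m
  if (m == 1L && n == 1L) variance <- 0
  se <- sqrt(max(variance, 0))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = auc, variance = variance, ci = ci, v10 = v10, v01 = v01)
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided z-test on the difference of two correlated AUCs computed from
#' the same patients, using the covariance of the DeLong structural
#' components. Comparing a model with itself gives p = 1.
#'
#' @param risks_a,risks_b Predicted risks of the two models on the same
#'   patients, in the same order.
#' @param labels Shared binary outcome.
#' @return list: \code{auc_a}, \code{auc_b}, \code{delta}, \code{z},
#'   \code{p}.
#' @export
delongCompare <- function(risks_a, risks_b, labels) {
  stopifnot(length(risks_a) == length(risks_b))
  a <- aucDelong(risks_a, labels)
  b <- aucDelong(risks_b, labels)
  m <- length(a$v10); n <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (var_d <= 0 || delta == 0) {
    z <- 0
    p <- if (delta == 0) 1 else 0
  } else {
    z <- delta / sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, z = z, p = p)
}

#' Repeated stratified cross-validation AUC
#'
#' Per repeat: a stratified k-fold split (events and non-events split
#' separately); the full fitting procedure -- skewness transform and
#' feature selection included -- is re-run inside each training fold; the
#' pooled out-of-fold risks give one AUC per repeat. The CV-AUC is the mean
#' over repeats with a 2.5/97.5 percentile interval across repeats. Splits
#' leaving a training fold without both classes are re-drawn (and counted).
#'
#' @param X data.frame of candidate features.
#' @param y Binary outcome.
#' @param fitter A fitting closure such as \code{\link{makeBackwardFitter}}
#'   or \code{\link{makeLassoFitter}}: called as \code{fitter(X_train,
#'   y_train)}, must return a list with a \code{predict(X_new)} function
#'   returning risks.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 200; 2000 reproduces the full
#'   analysis setting at matching cost).
#' @param seed Seed for the fold draws.
#' @return list: \code{cv_auc}, \code{ci}, \code{auc_per_repeat},
#'   \code{redraws}.
#' @export
repeatedStratifiedCV <- function(X, y, fitter = makeBackwardFitter(),
                                 folds = 5L, repeats = 200L, seed = 1L) {
  y <- as.integer(y)
  stopifnot(sum(y == 1L) >= folds, sum(y == 0L) >= folds)
  set.seed(seed)
  aucs <- numeric(repeats)
  redraws <- 0L
  for (r in seq_len(repeats)) {
    repeat {
      foldid <- stratifiedFolds(y, folds)
      ok <- all(vapply(seq_len(folds), function(f) {
        yt <- y[foldid != f]
        length(unique(yt)) == 2L
      }, logical(1)))
      if (ok) break
      redraws <- redraws + 1L
    }
    risks <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- fitter(X[tr, , drop = FALSE], y[tr])
      risks[!tr] <- fit$predict(X[!tr, , drop = FALSE])
    }
    aucs[r] <- aucDelong(risks, y)$auc
  }
  list(cv_auc = mean(aucs),
       ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
       auc_per_repeat = aucs,
       redraws = redraws)
}

#' Fitting closures for cross-validation
#'
#' \code{makeBackwardFitter} wraps the skewness log-transform plus logistic
#' backward selection; \code{makeLassoFitter} wraps the transform plus
#' standardized LASSO. Both return a function \code{(X, y) -> list(predict,
#' fit)} whose \code{predict} applies the training transforms to new data
#' (clamping at half the smallest positive training value before taking
#' logs, so zeros in unseen data cannot produce infinities).
#'
#' @param p_remove Backward-selection threshold.
#' @param skew_threshold Transform threshold.
#' @param nfolds,seed Internal LASSO CV settings.
#' @return A fitter closure.
#' @export
makeBackwardFitter <- function(p_remove = 0.05, skew_threshold = 0.5) {
  function(X, y) {
    tr <- transformSkewed(X, skew_threshold)
    fit <- fitLogisticBackward(tr$X, y, p_remove = p_remove)
    predictNew <- function(Xnew) {
      Xn <- applyTransformLog(Xnew, tr$log, X)
      df <- as.data.frame(expandDesign(Xn))
      as.numeric(stats::predict(fit$model, newdata = df,
                                type = "response"))
    }
    list(predict = predictNew, fit = fit)
  }
}

#' @rdname makeBackwardFitter
#' @export
makeLassoFitter <- function(skew_threshold = 0.5, nfolds = 5L, seed = 1L) {
  function(X, y) {
    tr <- transformSkewed(X, skew_threshold)
    fit <- fitLasso(tr$X, y, nfolds = nfolds, seed = seed)
    predictNew <- function(Xnew) {
      Xn <- applyTransformLog(Xnew, tr$log, X)
      M <- expandDesign(Xn)
      co <- fit$coefficients_raw
      beta <- co[-1][match(colnames(M), names(co[-1]))]
      beta[is.na(beta)] <- 0
      as.numeric(logistic(co[1] + as.numeric(M %*% beta)))
    }
    list(predict = predictNew, fit = fit)
  }
}

# Re-apply a training-set transform log to new data.
applyTransformLog <- function(Xnew, trlog, Xtrain) {
  Xnew <- as.data.frame(Xnew)
  if (is.null(trlog) || !nrow(trlog)) return(Xnew)
  for (i in seq_len(nrow(trlog))) {
    if (trlog$action[i] != "log-transformed") next
    nm <- trlog$feature[i]
    floorv <- min(Xtrain[[nm]][Xtrain[[nm]] > 0], na.rm = TRUE) / 2
    Xnew[[nm]] <- log(pmax(Xnew[[nm]], floorv))
    names(Xnew)[names(Xnew) == nm] <- paste0("ln_", nm)
  }
  Xnew
}

#' Prevalence-based risk stratification and diagnostic measures
#'
#' Defines the high-risk group as the \code{k_high} patients with the
#' highest predicted risk, where \code{k_high} defaults to the number of
#' observed events among the evaluable patients (the event prevalence
#' rule). Ties at the boundary are broken by stable patient order and
#' flagged. For an IPI-style model, pass \code{high_risk} directly (e.g.
#' the 4--5-adverse-factor group) instead of a risk cut.
#'
#' @param risks Predicted risks.
#' @param labels Binary outcome.
#' @param k_high High-risk group size (default: number of events).
#' @param high_risk Optional logical vector overriding the top-k rule.
#' @return list: \code{k_high}, \code{high_risk} (logical),
#'   \code{table} (2x2 counts TP/FP/FN/TN), \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{boundary_ties}.
#' @export
stratifyByPrevalence <- function(risks, labels, k_high = NULL,
                                 high_risk = NULL) {
  labels <- as.integer(labels)
  stopifnot(all(is.finite(risks)))
  n_events <- sum(labels == 1L)
  if (n_events == 0L) stop("no events")
  ties <- FALSE
  if (is.null(high_risk)) {
    if (is.null(k_high)) k_high <- n_events
    ord <- order(-risks, seq_along(risks))  # stable on ties
    high_risk <- logical(length(risks))
    high_risk[ord[seq_len(k_high)]] <- TRUE
    if (k_high > 0L && k_high < length(risks)) {
      cut <- risks[ord[k_high]]
      ties <- sum(risks == cut) > sum(risks[high_risk] == cut)
    }
  } else {
    k_high <- sum(high_risk)
  }
  tp <- sum(high_risk & labels == 1L)
  fp <- sum(high_risk & labels == 0L)
  fn <- sum(!high_risk & labels == 1L)
  tn <- sum(!high_risk & labels == 0L)
  list(
    k_high = k_high,
    high_risk = high_risk,
    table = c(TP = tp, FP = fp, FN = fn, TN = tn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    boundary_ties = ties
  )
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per risk group with a log-rank test,
#' via the \pkg{survival} package.
#'
#' @param times Follow-up times (months).
#' @param events 0/1 event indicators.
#' @param groups Group labels (e.g. high vs low risk).
#' @return list: \code{fit} (a \code{survfit} object), \code{logrank_p}.
#' @export
kmLogrank <- function(times, events, groups) {
  stopifnot(sum(events) >= 1L)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank needs two groups")
  df <- data.frame(t = times, e = events, g = droplevels(groups))
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  list(fit = fit, logrank_p = p)
}

#' Univariate Cox regression for a two-group contrast
#'
#' Hazard ratio (high vs low risk) with Wald 95\% CI, plus a
#' proportional-hazards check from scaled Schoenfeld residuals
#' (\code{survival::cox.zph}).
#'
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param group Logical or two-level factor (TRUE / second level = high
#'   risk).
#' @return list: \code{hr}, \code{ci}, \code{p}, \code{schoenfeld_p},
#'   \code{estimable} (FALSE when a group has no events).
#' @export
coxUnivariate <- function(times, events, group) {
  g <- if (is.logical(group)) factor(group, c(FALSE, TRUE)) else
    as.factor(group)
  df <- data.frame(t = times, e = events, g = g)
  by_g <- tapply(df$e, df$g, sum)
  estimable <- all(by_g > 0)
  fit <- survival::coxph(survival::Surv(t, e) ~ g, data = df)
  sm <- summary(fit)
  hr <- unname(sm$conf.int[1, "exp(coef)"])
  ci <- unname(sm$conf.int[1, c("lower .95", "upper .95")])
  p <- unname(sm$coefficients[1, "Pr(>|z|)"])
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  sch_p <- if (!is.null(zph)) unname(zph$table[1, "p"]) else NA_real_
  list(hr = hr, ci = ci, p = p, schoenfeld_p = sch_p,
       estimable = estimable)
}
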