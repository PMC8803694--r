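#' Skewness-based log transform of continuous features
#'
#' Continuous candidate features with sample skewness > 0.5 and strictly
#' positive values are replaced by their natural logarithm before model
#' fitting (the new column is named \code{ln_<name>}). Columns containing
#' zeros or negatives -- e.g. dissemination features of single-lesion
#' patients -- are left untransformed and noted as such in the log.
#' Binary (0/1) columns are never transformed.
#'
#' @param X data.frame or matrix of candidate features.
#' @param skew_threshold Skewness above which a column is transformed
#'   (default 0.5).
#' @return A list: \code{X} (transformed data.frame) and \code{log}
#'   (data.frame with columns \code{feature}, \code{skewness},
#'   \code{action}).
#' @export
transformSkewed <- function(X, skew_threshold = 0.5) {
  X <- as.data.frame(X)
  logrows <- list()
  for (nm in names(X)) {
    x <- X[[nm]]
    if (!is.numeric(x)) next
    ux <- unique(x[is.finite(x)])
    if (length(ux) <= 2L && all(ux %in% c(0, 1))) next  # binary
    sk <- sampleSkewness(x)
    if (sk > skew_threshold) {
      if (all(x > 0, na.rm = TRUE)) {
        X[[nm]] <- log(x)
        names(X)[names(X) == nm] <- paste0("ln_", nm)
        action <- "log-transformed"
      } else {
        action <- "skewed but contains non-positive values; left as is"
      }
    } else {
      action <- "untouched"
    }
    logrows[[nm]] <- data.frame(feature = nm, skewness = sk,
                                action = action, stringsAsFactors = FALSE)
  }
  list(X = X, log = do.call(rbind, logrows))
}

#' Multivariable logistic regression with backward selection
#'
#' Fits a binomial GLM and iteratively removes the predictor with the
#' largest Wald p-value at or above \code{p_remove}, refitting until every
#' retained predictor has p < \code{p_remove}. Factors are expanded to
#' dummy columns up front so each column is eliminated individually.
#' Exactly aliased columns (a hazard of dual-coded predictors such as stage
#' entered both dichotomously and categorically) are dropped before
#' selection starts and recorded in the elimination log
#' (\code{onAlias = "error"} raises instead, naming the columns).
#'
#' @param X data.frame/matrix of candidate predictors (numeric or factor).
#' @param y Binary response (0/1 or logical).
#' @param p_remove Removal threshold on the Wald p-value (default 0.05).
#' @param onAlias \code{"drop"} (default) or \code{"error"}.
#' @return A \code{FittedRiskModel} list: \code{selected} (character),
#'   \code{coefficients}, \code{initial_coefficients} (the full-model fit
#'   before any elimination), \code{wald_p}, \code{loglik}, \code{risks}
#'   (fitted probabilities), \code{elimination} (data.frame recording each
#'   drop), \code{separation} flag, \code{model} (the final \code{glm}).
#' @export
fitLogisticBackward <- function(X, y, p_remove = 0.05,
                                onAlias = c("drop", "error")) {
  onAlias <- match.arg(onAlias)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  M <- expandDesign(X)
  if (nrow(M) != length(y)) stop("X and y sizes differ")
  if (length(y) <= ncol(M))
    stop("need more observations than candidate features")
  elim <- list()
  # drop exactly aliased columns up front
  keep <- colnames(M)
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, M), y,
                                         family = stats::binomial()))
  aliased <- colnames(M)[is.na(fit$coefficients[-1])]
  if (length(aliased)) {
    if (onAlias == "error")
      stop("singular design; collinear columns: ",
           paste(aliased, collapse = ", "))
    for (a in aliased)
      elim[[length(elim) + 1L]] <- data.frame(step = 0L, feature = a,
                                              wald_p = NA_real_,
                                              reason = "aliased")
    keep <- setdiff(keep, aliased)
  }
  step <- 0L
  initial_coefs <- NULL
  repeat {
    df <- data.frame(y = y, M[, keep, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (is.null(initial_coefs)) initial_coefs <- fit$coefficients
    if (!length(keep)) break
    p <- sm[match(keep, rownames(sm)), "Pr(>|z|)"]
    names(p) <- keep
    worst <- which.max(p)
    if (p[worst] < p_remove) break
    step <- step + 1L
    elim[[length(elim) + 1L]] <- data.frame(step = step,
                                            feature = keep[worst],
                                            wald_p = unname(p[worst]),
                                            reason = "backward")
    keep <- keep[-worst]
  }
  separation <- any(abs(fit$coefficients[-1]) > 15) ||
    !fit$converged %||% FALSE
  coefs <- fit$coefficients
  sm <- summary(fit)$coefficients
  wald <- sm[, "Pr(>|z|)"]
  structure(list(
    estimator = "logistic_backward",
    selected = keep,
    coefficients = coefs,
    initial_coefficients = initial_coefs,
    wald_p = wald,
    loglik = as.numeric(stats::logLik(fit)),
    risks = as.numeric(stats::fitted(fit)),
    elimination = if (length(elim)) do.call(rbind, elim) else
      data.frame(step = integer(), feature = character(),
                 wald_p = numeric(), reason = character()),
    separation = separation,
    p_remove = p_remove,
    model = fit
  ), class = "FittedRiskModel")
}

# Expand a data.frame to a numeric design matrix (factors -> dummies,
# no intercept column).
expandDesign <- function(X) {
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

#' LASSO logistic regression
#'
#' L1-penalized logistic regression after mean-centering and scaling each
#' feature by its standard deviation. The penalty is chosen by internal
#' stratified k-fold cross-validation at the deviance optimum
#' (\code{lambda.min}). All-constant columns are dropped with a warning.
#'
#' @param X data.frame/matrix of features.
#' @param y Binary response.
#' @param nfolds Internal CV folds (default 5), stratified by outcome.
#' @param seed Seed for the internal fold assignment.
#' @return A \code{FittedRiskModel} list with the nonzero standardized
#'   coefficients (\code{coefficients}), the back-transformed coefficients
#'   on the original scale (\code{coefficients_raw}), \code{lambda},
#'   \code{risks} and \code{loglik}.
#' @export
fitLasso <- function(X, y, nfolds = 5L, seed = 1L) {
  y <- as.integer(y)
  M <- expandDesign(X)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping all-constant columns: ",
            paste(colnames(M)[sds == 0], collapse = ", "))
    M <- M[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(M)
  Z <- sweep(sweep(M, 2, mus), 2, sds, "/")
  set.seed(seed)
  foldid <- stratifiedFolds(y, nfolds)
  cv <- glmnet::cv.glmnet(Z, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(co) <- rownames(stats::coef(cv, s = "lambda.min"))
  nz <- co[-1][co[-1] != 0]
  risks <- as.numeric(stats::predict(cv, newx = Z, s = "lambda.min",
                                     type = "response"))
  eps <- 1e-12
  ll <- sum(y * log(pmax(risks, eps)) +
            (1 - y) * log(pmax(1 - risks, eps)))
  beta_raw <- co[-1] / sds
  a0_raw <- co[1] - sum(co[-1] * mus / sds)
  structure(list(
    estimator = "lasso",
    selected = names(nz),
    coefficients = c(`(Intercept)` = unname(co[1]), co[-1]),
    coefficients_raw = c(`(Intercept)` = unname(a0_raw), beta_raw),
    lambda = cv$lambda.min,
    risks = risks,
    loglik = ll,
    model = cv
  ), class = "FittedRiskModel")
}

# Stratified fold assignment: events and non-events are split into folds
# separately so every fold keeps both classes (as far as counts allow).
stratifiedFolds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' @export
print.FittedRiskModel <- function(x, ...) {
  cat("FittedRiskModel (", x$estimator, ")\n", sep = "")
  cat("  selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else
        "(intercept only)", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}
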