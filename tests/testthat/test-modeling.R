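test_that("skewness transform hits skewed positive columns only", {
  set.seed(4)
  X <- data.frame(
    expo = stats::rexp(400),          # skewness ~ 2
    symm = stats::rnorm(400),         # skewness ~ 0
    withzero = c(0, stats::rexp(399)),  # skewed but contains a zero
    flag = rbinom(400, 1, 0.3)        # binary, never transformed
  )
  tr <- transformSkewed(X)
  expect_true("ln_expo" %in% names(tr$X))
  expect_equal(tr$X$ln_expo, log(X$expo))
  expect_true("symm" %in% names(tr$X))
  expect_true("withzero" %in% names(tr$X))
  expect_true("flag" %in% names(tr$X))
  acts <- setNames(tr$log$action, tr$log$feature)
  expect_equal(unname(acts["expo"]), "log-transformed")
  expect_match(unname(acts["withzero"]), "non-positive")
})

test_that("MTV-like lognormal burden columns get log-transformed", {
  set.seed(9)
  X <- data.frame(mtv_ml = stats::rlnorm(300, 5, 1))
  tr <- transformSkewed(X)
  expect_true("ln_mtv_ml" %in% names(tr$X))
})

test_that("backward selection keeps a strong predictor and drops noise", {
  set.seed(12)
  n <- 600
  X <- data.frame(signal = stats::rnorm(n), n1 = stats::rnorm(n),
                  n2 = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * X$signal))
  fit <- fitLogisticBackward(X, y)
  expect_true("signal" %in% fit$selected)
  expect_true(all(fit$wald_p[fit$selected] < 0.05))
  # elimination order is recorded and bounded by the candidate count
  expect_lte(nrow(fit$elimination), ncol(X))
  # risks are proper probabilities
  expect_true(all(fit$risks > 0 & fit$risks < 1))
})

test_that("aliased dual-coded columns are dropped, or error in strict mode", {
  set.seed(3)
  n <- 200
  stage <- sample(2:4, n, replace = TRUE)
  X <- data.frame(stage_cat = factor(stage, levels = 1:4),
                  stage34 = as.integer(stage >= 3),
                  x = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + X$x))
  fit <- fitLogisticBackward(X, y)
  expect_true(any(fit$elimination$reason == "aliased"))
  expect_error(fitLogisticBackward(X, y, onAlias = "error"), "collinear")
})

test_that("backward selection needs more observations than features", {
  X <- data.frame(a = stats::rnorm(4), b = stats::rnorm(4),
                  c = stats::rnorm(4), d = stats::rnorm(4))
  expect_error(fitLogisticBackward(X, c(0, 1, 0, 1)), "more observations")
})

test_that("lasso shrinks to intercept-only under a huge penalty and
           splits duplicated columns stably", {
  set.seed(21)
  n <- 400
  X <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.2 * X$a))
  fit <- fitLasso(X, y)
  expect_true("a" %in% fit$selected)
  # manual huge-penalty fit via the stored glmnet object
  co <- as.numeric(stats::coef(fit$model$glmnet.fit, s = 100))
  expect_true(all(co[-1] == 0))
  # duplicated predictor: refitting with the same seed reproduces exactly
  X2 <- data.frame(X, a2 = X$a)
  f1 <- fitLasso(X2, y, seed = 5)
  f2 <- fitLasso(X2, y, seed = 5)
  expect_identical(f1$coefficients, f2$coefficients)
  # the duplicated pair carries the signal jointly on the raw scale
  beta <- f1$coefficients_raw
  expect_gt(beta[["a"]] + beta[["a2"]], 0.5)
  # constant columns are dropped with a warning
  expect_warning(fitLasso(data.frame(X, const = 1), y), "constant")
})
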