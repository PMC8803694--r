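test_that("DeLong AUC equals brute-force concordance and handles edges", {
  set.seed(41)
  r <- stats::runif(30)
  y <- stats::rbinom(30, 1, 0.4)
  expect_equal(aucDelong(r, y)$auc, bruteAuc(r, y))
  # perfect separation
  expect_equal(aucDelong(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # all tied risks
  expect_equal(aucDelong(rep(0.3, 20), rep(c(0, 1), 10))$auc, 0.5)
  expect_error(aucDelong(r, rep(1, 30)), "both")
})

test_that("DeLong variance and CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(40:120, 1)
    y <- stats::rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    r <- stats::runif(n) + y * stats::runif(1)
    ours <- aucDelong(r, y)
    roc <- pROC::roc(y, r, quiet = TRUE, direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(roc)))
    expect_equal(ours$variance, as.numeric(pROC::var(roc)))
    # paired comparison against pROC's DeLong test
    r2 <- stats::runif(n) + y * stats::runif(1)
    ours2 <- delongCompare(r, r2, y)
    theirs <- pROC::roc.test(roc, pROC::roc(y, r2, quiet = TRUE,
                                            direction = "<"),
                             method = "delong", paired = TRUE)
    expect_equal(ours2$p, as.numeric(theirs$p.value), tolerance = 1e-8)
  }
})

test_that("comparing a model with itself gives p = 1", {
  set.seed(2)
  r <- stats::runif(50)
  y <- stats::rbinom(50, 1, 0.3)
  expect_equal(delongCompare(r, r, y)$p, 1)
})

test_that("repeated stratified CV is seeded and honest about optimism", {
  set.seed(77)
  n <- 240
  X <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1.4 + 1.2 * X$a))
  cv1 <- repeatedStratifiedCV(X, y, repeats = 8, seed = 10)
  cv2 <- repeatedStratifiedCV(X, y, repeats = 8, seed = 10)
  expect_identical(cv1$cv_auc, cv2$cv_auc)
  expect_length(cv1$auc_per_repeat, 8)
  # CV-AUC does not exceed the apparent AUC by more than noise
  fit <- fitLogisticBackward(transformSkewed(X)$X, y)
  apparent <- aucDelong(fit$risks, y)$auc
  expect_lt(cv1$cv_auc, apparent + 0.05)
})

test_that("prevalence stratification reproduces the 2x2 bookkeeping", {
  # perfect ranking with k_high = #events: everything is 1
  risks <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  s <- stratifyByPrevalence(risks, labels)
  expect_equal(s$k_high, 3L)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  expect_equal(s$ppv, 1)
  expect_equal(s$npv, 1)
  # the worked 2x2 table: TP 23, FP 29, FN 29, TN 215
  set.seed(123)
  n_ev <- 52; n_non <- 244
  lab <- c(rep(1, n_ev), rep(0, n_non))
  rk <- numeric(n_ev + n_non)
  # place 23 events and 29 non-events on top
  rk[c(1:23, n_ev + 1:29)] <- stats::runif(52, 0.8, 1)
  rk[rk == 0] <- stats::runif(sum(rk == 0), 0, 0.5)
  s2 <- stratifyByPrevalence(rk, lab, k_high = 52)
  expect_equal(unname(s2$table), c(23, 29, 29, 215))
  expect_equal(s2$ppv, 23 / 52)
  expect_equal(s2$ppv, s2$sensitivity)  # k_high = #events identity
  expect_error(stratifyByPrevalence(runif(5), rep(0, 5)), "no events")
})

test_that("an explicit high-risk group (IPI rule) bypasses the top-k cut", {
  labels <- c(1, 0, 1, 0, 0)
  s <- stratifyByPrevalence(runif(5), labels,
                            high_risk = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$k_high, 2L)
  expect_equal(unname(s$table), c(1, 1, 1, 2))
})

test_that("Kaplan-Meier matches the hand-computed product-limit estimate", {
  # worked 6-patient set: times 1..6, events 1,1,0,1,0,1
  times <- 1:6
  events <- c(1, 1, 0, 1, 0, 1)
  df <- data.frame(t = times, e = events)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, data = df)
  # hand product-limit: S(1)=5/6, S(2)=5/6*4/5, S(4)=...*2/3, S(6)=...*0
  hand <- c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3, 0)
  expect_equal(summary(fit, times = c(1, 2, 4, 6))$surv, hand)
  # without censoring KM equals the empirical survival fraction
  fit2 <- survival::survfit(survival::Surv(t, e) ~ 1,
                            data = data.frame(t = 1:5, e = rep(1, 5)))
  expect_equal(fit2$surv, 1 - (1:5) / 5)
})

test_that("exchangeable groups give log-rank p ~ 1 and HR ~ 1", {
  times <- rep(c(3, 7, 11, 15, 20, 26), 2)
  events <- rep(c(1, 1, 0, 1, 0, 1), 2)
  groups <- rep(c("high", "low"), each = 6)
  km <- kmLogrank(times, events, groups)
  expect_gt(km$logrank_p, 0.99)
  cx <- coxUnivariate(times, events, groups == "high")
  expect_equal(cx$hr, 1, tolerance = 1e-6)
  expect_true(cx$estimable)
})

test_that("Cox HR approximates the rate ratio for exponential groups", {
  set.seed(15)
  n <- 400
  t1 <- stats::rexp(n, 0.05)
  t2 <- stats::rexp(n, 0.15)  # rate ratio 3
  cx <- coxUnivariate(c(t1, t2), rep(1, 2 * n),
                      rep(c(FALSE, TRUE), each = n))
  expect_equal(cx$hr, 3, tolerance = 0.35)
  expect_true(cx$ci[1] < 3 & 3 < cx$ci[2])
  expect_true(is.finite(cx$schoenfeld_p))
})
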