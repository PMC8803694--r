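test_that("a single planted lesion is recovered with its planted volume", {
  cfg <- phantomConfig(
    n_patients = 1, seed = 303,
    lesion_count_dist = list(size = 1e6, mu = 1e-9),  # degenerate at 1
    lesion_volume_dist_mL = list(meanlog = log(4.19), sdlog = 1e-6,
                                 min = 4.18, max = 4.20),
    lesion_peak_suv_dist = list(meanlog = log(8), sdlog = 1e-6,
                                min = 7.9, max = 8.1)
  )
  p <- generatePhantomPatient(cfg, 1)
  expect_equal(nrow(p$true_lesions), 1L)
  seg <- preselectLesions(p$image)
  expect_equal(lesionCount(seg), 1L)
  mtv <- lesionVolumesML(seg)[[1]]
  expect_lt(abs(mtv - 4.19) / 4.19, 0.15)
})

test_that("dissemination scale controls the spread of recovered lesions", {
  mean_dmax <- vapply(c(0, 300), function(scale) {
    cfg <- phantomConfig(n_patients = 12, seed = 11,
                         dissemination_scale_mm = scale)
    coh <- generatePhantomCohort(cfg, render = FALSE)
    mean(coh$truth$dmax_bulk_mm)
  }, numeric(1))
  expect_gt(mean_dmax[2], mean_dmax[1])
})

test_that("event prevalence follows the configured logistic intercept", {
  cfg <- phantomConfig(
    n_patients = 5000, seed = 99,
    outcome_coefs = c(intercept = qlogis(0.16), ln_mtv = 0,
                      ln_suvpeak = 0, dmax_bulk = 0, who_ge1 = 0,
                      age_gt60 = 0)
  )
  coh <- generatePhantomCohort(cfg, render = FALSE)
  expect_lt(abs(mean(coh$truth$event2y) - 0.16), 0.02)
})

test_that("default configuration is calibrated to ~16% 2-year prevalence", {
  coh <- generatePhantomCohort(phantomConfig(n_patients = 1500, seed = 55),
                               render = FALSE)
  expect_lt(abs(mean(coh$truth$event2y) - 0.16), 0.03)
})

test_that("the linear predictor equals the coefficients applied to truth", {
  cfg <- phantomConfig(n_patients = 5, seed = 2)
  coh <- generatePhantomCohort(cfg, render = FALSE)
  cf <- cfg$outcome_coefs
  with(coh$truth, {
    lp <- cf["intercept"] + cf["ln_mtv"] * ln_mtv +
      cf["ln_suvpeak"] * ln_suvpeak + cf["dmax_bulk"] * dmax_bulk_mm +
      cf["who_ge1"] * who_ge1 + cf["age_gt60"] * age_gt60
    expect_equal(unname(lp), coh$truth$linear_predictor)
  })
})

test_that("cohorts are reproducible and lesions never overlap the liver", {
  cfg <- phantomConfig(n_patients = 6, seed = 123)
  a <- generatePhantomCohort(cfg, render = FALSE)
  b <- generatePhantomCohort(cfg, render = FALSE)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$outcomes, b$outcomes)
  # all planted lesion peaks exceed the segmentation threshold
  for (p in a$patients) expect_true(all(p$true_lesions$peak_suv > 4))
})

test_that("written cohorts round-trip with a checksummed manifest", {
  dir1 <- file.path(tempdir(), "coh1")
  dir2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  cfg <- phantomConfig(n_patients = 2, seed = 77)
  generatePhantomCohort(cfg, dir = dir1)
  generatePhantomCohort(cfg, dir = dir2)
  m1 <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  expect_identical(m1$checksums, m2$checksums)
  # images round-trip through NIfTI with spacing intact
  img <- readSuvImage(file.path(dir1, "images", "P0001.nii.gz"))
  expect_equal(voxelSpacing(img), cfg$voxel_spacing_mm)
  expect_equal(dim(suvVoxels(img)), cfg$grid_shape)
})

test_that("refitting on true covariates is consistent with the truth", {
  cfg <- phantomConfig(n_patients = 2000, seed = 17)
  co <- generatePhantomCohort(cfg, render = FALSE)$truth
  X <- co[, c("ln_mtv", "ln_suvpeak", "dmax_bulk_mm", "who_ge1",
              "age_gt60")]
  fit <- stats::glm(co$event2y ~ ., data = X, family = stats::binomial())
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  truth <- unname(cfg$outcome_coefs[c("intercept", "ln_mtv", "ln_suvpeak",
                                      "dmax_bulk", "who_ge1", "age_gt60")])
  # every estimate within 3 standard errors of its generating value
  expect_true(all(abs(est - truth) < 3 * se))
})
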