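test_that("conventional features match closed forms on uniform uptake", {
  sp <- c(2, 2, 2)
  d <- c(16L, 16L, 16L)
  arr <- array(0, d)
  arr[2:6, 2:16, 2:6] <- 5.0  # 5 x 15 x 5 = 375 voxels = 3.0 mL
  img <- SuvImage(arr, sp)
  f <- conventionalFeatures(img, arr > 0)
  expect_equal(f$mtv_ml, 3.0)
  expect_equal(f$suv_mean, 5.0)
  expect_equal(f$suv_max, 5.0)
  expect_equal(f$tlg, 15.0)
  expect_equal(f$n_voxels, 375L)
})

test_that("TLG is SUVmean x MTV and the invariants hold on a phantom", {
  p <- cachedPhantomPatient()
  seg <- preselectLesions(p$image)
  f <- conventionalFeatures(p$image, patientVoi(seg))
  expect_equal(f$tlg, f$suv_mean * f$mtv_ml)
  expect_lte(f$suv_mean, f$suv_max)
  expect_lte(f$suv_peak, f$suv_max)
})

test_that("SUVpeak for an isolated voxel equals max / sphere voxel count", {
  sp <- c(2, 2, 2)
  d <- c(16L, 16L, 16L)
  arr <- array(0, d)
  arr[8, 8, 8] <- 10
  img <- SuvImage(arr, sp)
  # independent enumeration of the 1 cm^3 sphere kernel at 2 mm spacing
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  off <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  n_kernel <- sum(sqrt(rowSums((off * 2)^2)) <= r)
  expect_equal(suvPeak(img, arr > 0), 10 / n_kernel)
})

test_that("patient-level MTV is additive over disjoint lesions", {
  sp <- c(2, 2, 2)
  d <- c(40L, 20L, 20L)
  arr <- array(0, d)
  arr[2:11, 2:11, 2:11] <- 6   # 8 mL
  arr[25:34, 5:9, 5:14] <- 6   # 10*5*10 voxels = 4 mL
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 2L)
  per_lesion <- sum(vapply(lesionIds(seg), function(id) {
    conventionalFeatures(img, lesionMask(seg, id))$mtv_ml
  }, numeric(1)))
  patient <- conventionalFeatures(img, patientVoi(seg))$mtv_ml
  expect_equal(patient, per_lesion)
  expect_equal(patient, 12)
})

test_that("trilinear resampling is exact on constants, ramps and identity", {
  # constant image stays constant
  img <- SuvImage(array(3, c(12, 12, 12)), c(4, 4, 4))
  out <- resampleTrilinear(img)
  expect_equal(voxelSpacing(out), c(2, 2, 2))
  expect_equal(dim(suvVoxels(out)), c(24L, 24L, 24L))
  expect_true(all(abs(suvVoxels(out) - 3) < 1e-12))
  # linear ramp along x is preserved away from borders
  d <- c(20L, 8L, 8L)
  ramp <- array(rep((seq_len(d[1]) - 0.5) * 4, times = prod(d[2:3])), d)
  rimg <- resampleTrilinear(SuvImage(ramp, c(4, 4, 4)))
  expected <- (seq_len(40) - 0.5) * 2  # world coordinate of output centers
  got <- suvVoxels(rimg)[, 4, 4]
  interior <- 3:38
  expect_equal(got[interior], expected[interior], tolerance = 1e-12)
  # bounded by input range everywhere
  expect_true(all(suvVoxels(rimg) >= min(ramp) - 1e-12))
  expect_true(all(suvVoxels(rimg) <= max(ramp) + 1e-12))
  # an image already on the 2 mm grid is returned unchanged
  arr <- array(runif(10 * 10 * 10), c(10, 10, 10))
  same <- resampleTrilinear(SuvImage(arr, c(2, 2, 2)))
  expect_equal(suvVoxels(same), arr, tolerance = 1e-12)
})

test_that("fixed-bin discretization follows the floor rule anchored at 0", {
  img <- SuvImage(array(c(4.0, 0.10, 0.25, 3.99, 0, 7.6, 1, 1),
                        c(2, 2, 2)), c(2, 2, 2))
  mask <- array(TRUE, c(2, 2, 2))
  disc <- discretizeFixedBin(img, mask)
  expect_equal(disc$levels[1, 1, 1], 17L)   # SUV 4.0 -> level 17
  expect_equal(disc$levels[2, 1, 1], 1L)    # SUV 0.10 -> level 1
  expect_equal(disc$levels[1, 2, 1], 2L)    # SUV 0.25 -> level 2
  expect_equal(disc$levels[2, 2, 1], 16L)   # SUV 3.99 -> level 16
  expect_equal(disc$levels[1, 1, 2], 0L)    # SUV 0 stays level 0
  expect_equal(disc$n_levels, floor(7.6 / 0.25) + 1)
  # a uniform VOI occupies exactly one level
  u <- discretizeFixedBin(SuvImage(array(5.3, c(3, 3, 3)), c(2, 2, 2)),
                          array(TRUE, c(3, 3, 3)))
  expect_equal(length(unique(as.integer(u$levels))), 1L)
})
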