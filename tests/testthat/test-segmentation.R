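test_that("a digitized ball is preselected with near-analytic volume", {
  d <- c(24L, 24L, 24L)
  sp <- c(2, 2, 2)
  mask <- ballMask(d, sp, radius_mm = 10)
  img <- maskImage(mask, sp, inside = 6, background = 1)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 1L)
  # volume within one voxel shell of the analytic 4.19 mL
  shell <- sum(ballMask(d, sp, 12) & !ballMask(d, sp, 8)) * prod(sp) / 1000
  expect_lt(abs(lesionVolumesML(seg)[[1]] - 4.18879), shell)
  # and exactly the digitized super-threshold count
  expect_identical(sum(lesionLabels(seg) > 0), sum(mask))
})

test_that("components below the 3 mL floor are not preselected", {
  sp <- c(2, 2, 2)
  mask <- ballMask(c(16L, 16L, 16L), sp, radius_mm = 7.8)  # ~2 mL
  img <- maskImage(mask, sp, inside = 6)
  expect_lt(sum(mask) * prod(sp) / 1000, 3)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 0L)
  expect_true("no FDG-avid lesions" %in% segmentationFlags(seg))
})

test_that("an all-background image yields an empty flagged segmentation", {
  img <- SuvImage(array(2, c(10, 10, 10)), c(4, 4, 4))
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 0L)
  expect_true("no FDG-avid lesions" %in% segmentationFlags(seg))
})

test_that("lesions are labelled in decreasing-volume order deterministically", {
  sp <- c(2, 2, 2)
  d <- c(48L, 24L, 24L)
  arr <- array(1, d)
  arr[30:37, 2:9, 2:9] <- 6      # 512 voxels = 4.1 mL, later in scan order
  arr[2:11, 2:11, 2:11] <- 6     # 1000 voxels = 8 mL
  arr[40:42, 14:16, 14:16] <- 6  # 27 voxels = 0.2 mL, below floor
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  v <- lesionVolumesML(seg)
  expect_equal(lesionCount(seg), 2L)
  expect_equal(unname(v[["1"]]), 1000 * 8 / 1000)  # largest gets label 1
  expect_equal(unname(v[["2"]]), 512 * 8 / 1000)
})

test_that("seed clicks add sub-3-mL lesions and are idempotent", {
  sp <- c(2, 2, 2)
  d <- c(30L, 20L, 20L)
  arr <- array(1, d)
  arr[4:12, 4:12, 4:12] <- 6      # 729 voxels = 5.8 mL, preselected
  arr[20:24, 5:8, 5:8] <- 5       # 80 voxels = 0.64 mL, below floor
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 1L)
  seg2 <- addLesionBySeed(seg, img, c(22L, 6L, 6L))
  expect_equal(lesionCount(seg2), 2L)
  expect_equal(segmentationProvenance(seg2)$origin, c("preselected",
                                                      "seed-added"))
  expect_equal(unname(lesionVolumesML(seg2)[["2"]]), 80 * 8 / 1000)
  # idempotent on a voxel already labelled
  seg3 <- addLesionBySeed(seg2, img, c(22L, 6L, 6L))
  expect_identical(lesionLabels(seg3), lesionLabels(seg2))
  # seed in background errors
  expect_error(addLesionBySeed(seg, img, c(1L, 1L, 1L)), "below threshold")
})

test_that("removing a lesion or subregion conserves voxel accounting", {
  sp <- c(2, 2, 2)
  d <- c(30L, 20L, 20L)
  arr <- array(1, d)
  arr[4:12, 4:12, 4:12] <- 6
  arr[18:26, 4:12, 4:12] <- 7
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 2L)
  # remove whole lesion
  seg1 <- removeLesion(seg, 1L)
  expect_equal(lesionCount(seg1), 1L)
  expect_error(removeLesion(seg, 9L), "unknown lesion")
  # subregion removal: set difference of volumes
  m <- array(FALSE, d)
  m[4:6, 4:12, 4:12] <- lesionLabels(seg)[4:6, 4:12, 4:12] > 0
  target <- unique(lesionLabels(seg)[m])
  before <- lesionVolumesML(seg)[[as.character(target)]]
  seg2 <- removeSubregion(seg, target, m)
  after <- sum(lesionVolumesML(seg2)) - sum(lesionVolumesML(seg)) + before
  expect_equal(after, before - sum(m) * prod(sp) / 1000)
  # removing the only lesion empties the segmentation
  seg3 <- removeLesion(seg1, 1L)
  expect_equal(lesionCount(seg3), 0L)
})

test_that("a split lesion is relabelled as fragments with volume conserved", {
  sp <- c(2, 2, 2)
  d <- c(40L, 16L, 16L)
  arr <- array(1, d)
  arr[4:30, 6:9, 6:9] <- 6   # dumbbell bar
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  expect_equal(lesionCount(seg), 1L)
  total <- sum(lesionVolumesML(seg))
  m <- array(FALSE, d)
  m[16:18, , ] <- lesionLabels(seg)[16:18, , ] > 0
  seg2 <- removeSubregion(seg, 1L, m)
  expect_equal(lesionCount(seg2), 2L)
  expect_equal(sum(lesionVolumesML(seg2)),
               total - sum(m) * prod(sp) / 1000)
  expect_true(any(grepl("split fragment",
                        segmentationProvenance(seg2)$note)))
})

test_that("a JSON-style edit script replays seed adds and removals", {
  sp <- c(2, 2, 2)
  d <- c(30L, 20L, 20L)
  arr <- array(1, d)
  arr[4:12, 4:12, 4:12] <- 6   # preselected lesion
  arr[20:24, 5:8, 5:8] <- 5    # small blob, needs a seed click
  img <- SuvImage(arr, sp)
  seg <- preselectLesions(img)
  edits <- list(
    list(op = "add_seed", voxel = c(21L, 5L, 5L)),  # 0-based indices
    list(op = "remove_subregion", lesion_id = 1L,
         box = list(c(3L, 6L), c(3L, 12L), c(3L, 12L)))  # [lo, hi) 0-based
  )
  seg2 <- applyEditScript(seg, img, edits)
  expect_equal(lesionCount(seg2), 2L)
  # the seed added the 80-voxel blob; the box removed x-slices 4:6 of
  # lesion 1 (3 of its 9 slices)
  v <- lesionVolumesML(seg2)
  expect_true(any(abs(v - 80 * 8 / 1000) < 1e-9))
  expect_true(any(abs(v - 6 * 9 * 9 * 8 / 1000) < 1e-9))
})

test_that("volume conservation: lesion volumes sum to the patient VOI", {
  p <- cachedPhantomPatient()
  seg <- preselectLesions(p$image)
  vv <- prod(voxelSpacing(p$image)) / 1000
  expect_equal(sum(lesionVolumesML(seg)), sum(patientVoi(seg)) * vv)
})

test_that("raising the volume floor never increases the lesion count", {
  p <- cachedPhantomPatient()
  counts <- vapply(c(0.5, 3, 10, 50), function(fl) {
    lesionCount(preselectLesions(p$image, min_volume_mL = fl))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})
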