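test_that("dissemination features match hand calculations", {
  # 3-4-5 triangle: two lesions 50 mm apart
  f <- disseminationFeatures(rbind(c(0, 0, 0), c(30, 40, 0)), c(10, 2))
  expect_equal(f$dmax_patient_mm, 50)
  expect_equal(f$dmax_bulk_mm, 50)
  expect_equal(f$spread_bulk_mm, 50)
  expect_equal(f$spread_patient_mm, 100)  # ordered pairs: each pair twice
  expect_equal(f$bulk_lesion, 1L)
  # collinear lesions with the bulk in the middle
  g <- disseminationFeatures(rbind(c(0, 0, 0), c(50, 0, 0), c(120, 0, 0)),
                             c(2, 12, 3))
  expect_equal(g$dmax_patient_mm, 120)
  expect_equal(g$dmax_bulk_mm, 70)
  expect_equal(g$spread_bulk_mm, 50 + 70)
  expect_equal(g$spread_patient_mm, 2 * (50 + 120 + 70))
})

test_that("single-lesion patients have all dissemination features zero", {
  f <- disseminationFeatures(matrix(c(10, 20, 30), 1), 5)
  expect_equal(f$n_lesions, 1L)
  expect_equal(f$dmax_patient_mm, 0)
  expect_equal(f$dmax_bulk_mm, 0)
  expect_equal(f$spread_patient_mm, 0)
  expect_equal(f$spread_bulk_mm, 0)
})

test_that("dissemination matches the brute-force pairwise oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    locs <- matrix(stats::runif(3 * n, 0, 600), n)
    mtv <- stats::rlnorm(n, 2, 1)
    f <- disseminationFeatures(locs, mtv)
    b <- bruteDissemination(locs, mtv)
    expect_equal(f$dmax_patient_mm, b$dmax_patient_mm)
    expect_equal(f$dmax_bulk_mm, b$dmax_bulk_mm)
    expect_equal(f$spread_patient_mm, b$spread_patient_mm)
    expect_equal(f$spread_bulk_mm, b$spread_bulk_mm)
    # structural inequalities
    expect_lte(f$dmax_bulk_mm, f$dmax_patient_mm)
    expect_gte(f$spread_patient_mm, f$spread_bulk_mm)
    if (n == 2) expect_equal(f$dmax_bulk_mm, f$dmax_patient_mm)
  }
})

test_that("the unordered-pair convention halves spread_patient", {
  set.seed(8)
  locs <- matrix(stats::runif(12, 0, 100), 4)
  f1 <- disseminationFeatures(locs, 1:4, ordered_pairs = TRUE)
  f2 <- disseminationFeatures(locs, 1:4, ordered_pairs = FALSE)
  expect_equal(f1$spread_patient_mm, 2 * f2$spread_patient_mm)
})

test_that("height correction divides by height and keeps monotonicity", {
  expect_equal(heightCorrectDmax(444, 170), 444 / 1700)
  expect_equal(heightCorrectDmax(0, 180), 0)
  expect_lt(heightCorrectDmax(300, 190), heightCorrectDmax(300, 160))
  expect_error(heightCorrectDmax(300, 0), "positive")
})

test_that("index lesions pick largest by MTV and hottest by SUVmax", {
  idx <- selectIndexLesions(c(10, 2), c(8, 20))
  expect_equal(idx$largest_lesion_id, 1L)
  expect_equal(idx$hottest_lesion_id, 2L)
  # single lesion: both coincide
  one <- selectIndexLesions(5, 9)
  expect_equal(one$largest_lesion_id, one$hottest_lesion_id)
  # exact tie: lowest index wins
  tie <- selectIndexLesions(c(5, 5), c(7, 7))
  expect_equal(tie$largest_lesion_id, 1L)
  expect_equal(tie$hottest_lesion_id, 1L)
})
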