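# Shared in-code fixtures: digitized geometric phantoms and small cached
# synthetic patients. Everything is generated at test time; nothing is
# stored on disk.

# Digitized ball mask: voxels whose centers lie within radius_mm of the
# center (mm, defaults to the grid center).
ballMask <- function(dim, spacing, radius_mm, center_mm = NULL) {
  if (is.null(center_mm)) center_mm <- dim * spacing / 2
  co <- arrayInd(seq_len(prod(dim)), dim)
  x <- sweep(co - 0.5, 2, spacing, "*")
  array(sqrt(rowSums(sweep(x, 2, center_mm)^2)) <= radius_mm, dim)
}

# SUV image with a uniform value inside a mask and a background elsewhere.
maskImage <- function(mask, spacing, inside = 6, background = 1,
                      patientId = "fixture") {
  arr <- array(background, dim(mask))
  arr[mask] <- inside
  SuvImage(arr, spacing, patientId)
}

# One cached rendered phantom patient (built once per test run).
.fixtureEnv <- new.env(parent = emptyenv())
cachedPhantomPatient <- function() {
  if (is.null(.fixtureEnv$patient)) {
    cfg <- phantomConfig(n_patients = 1, seed = 4242)
    .fixtureEnv$patient <- generatePhantomPatient(cfg, 1, render = TRUE)
  }
  .fixtureEnv$patient
}

# Brute-force dissemination oracle: O(n^2) loops over ordered pairs.
bruteDissemination <- function(locs, mtv) {
  n <- nrow(locs)
  if (n == 1L) {
    return(list(dmax_patient_mm = 0, dmax_bulk_mm = 0,
                spread_patient_mm = 0, spread_bulk_mm = 0))
  }
  bulk <- which.max(mtv)
  dmax_p <- 0; dmax_b <- 0; spread_p <- 0; spread_b <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((locs[i, ] - locs[j, ])^2))
    dmax_p <- max(dmax_p, d)
    spread_p <- spread_p + d
    if (i == bulk) {
      dmax_b <- max(dmax_b, d)
      spread_b <- spread_b + d
    }
  }
  list(dmax_patient_mm = dmax_p, dmax_bulk_mm = dmax_b,
       spread_patient_mm = spread_p, spread_bulk_mm = spread_b)
}

# Brute-force AUC oracle: exhaustive concordance over event x non-event
# pairs, ties counted 1/2.
bruteAuc <- function(risks, labels) {
  x <- risks[labels == 1]
  y <- risks[labels == 0]
  total <- 0
  for (a in x) for (b in y) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x) * length(y))
}
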