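test_that("2-year endpoint labels follow the censoring semantics", {
  # progression inside the horizon is an event under both endpoints
  expect_equal(deriveEndpoint(10, "progression", "TTP2y")$label, "event")
  expect_equal(deriveEndpoint(10, "progression", "PFS2y")$label, "event")
  # death without progression: censored (excluded) under TTP, event under PFS
  d <- deriveEndpoint(12, "death_without_progression", "TTP2y")
  expect_equal(d$label, "excluded")
  expect_equal(d$survival_event, 0L)
  dp <- deriveEndpoint(12, "death_without_progression", "PFS2y")
  expect_equal(dp$label, "event")
  expect_equal(dp$survival_event, 1L)
  # administrative censoring past the horizon is a non-event under both
  expect_equal(deriveEndpoint(36, "administrative_censor", "TTP2y")$label,
               "non_event")
  expect_equal(deriveEndpoint(36, "administrative_censor", "PFS2y")$label,
               "non_event")
  # loss to follow-up before the horizon excludes under both
  expect_equal(deriveEndpoint(6, "lost_to_followup", "TTP2y")$label,
               "excluded")
  expect_equal(deriveEndpoint(6, "lost_to_followup", "PFS2y")$label,
               "excluded")
  # late progression counts as a non-event for the 2-year endpoint
  expect_equal(deriveEndpoint(30, "progression", "TTP2y")$label,
               "non_event")
  expect_error(deriveEndpoint(-1, "progression"), "non-negative")
})

test_that("PFS events dominate TTP events on any phantom cohort", {
  for (s in c(3, 14)) {
    coh <- generatePhantomCohort(phantomConfig(n_patients = 400, seed = s),
                                 render = FALSE)
    tt <- deriveEndpoints(coh$outcomes, "TTP2y")
    pf <- deriveEndpoints(coh$outcomes, "PFS2y")
    expect_gte(sum(pf$y, na.rm = TRUE), sum(tt$y, na.rm = TRUE))
    # all deaths without progression before 24 months are TTP-excluded
    dwp <- coh$outcomes$event_type == "death_without_progression" &
      coh$outcomes$time_months < 24
    expect_true(all(tt$label[dwp] == "excluded"))
  }
})

test_that("the IPI score counts its five adverse factors", {
  r <- ipiScore(70, 4, 375, 250, 1, 1)
  expect_equal(r$score, 3L)  # age, stage, LDH adverse; WHO 1 and EN 1 not
  expect_equal(r$group, "high-intermediate")
  r0 <- ipiScore(40, 2, 200, 250, 0, 0)
  expect_equal(r0$score, 0L)
  expect_equal(r0$group, "low")
  r5 <- ipiScore(75, 4, 500, 250, 3, 3)
  expect_equal(r5$score, 5L)
  expect_equal(r5$group, "high")
  # missing WHO performance status is treated as 0
  rm <- ipiScore(75, 4, 500, 250, 3, NA)
  expect_equal(rm$score, 4L)
})

test_that("clinical encoding emits the dual-coded predictors", {
  clin <- data.frame(
    patient_id = c("a", "b"),
    age_years = c(70, 45),
    ann_arbor_stage = c(2, 4),
    ldh = c(450, 200),
    ldh_uln = c(250, 250),
    extranodal_sites = c(0, 2),
    who_ps = c(1, NA),
    bulky = c(0, 1)
  )
  expect_warning(enc <- encodeClinical(clin), "imputed as 0")
  expect_equal(enc$ldh_ratio, c(1.8, 0.8))
  expect_equal(enc$ldh_elevated, c(1L, 0L))
  expect_equal(enc$who_ge1, c(1L, 0L))  # WHO 1 -> ge1 but not ge2; NA -> 0
  expect_equal(enc$who_ge2, c(0L, 0L))
  expect_equal(enc$stage34, c(0L, 1L))
  expect_equal(as.character(enc$stage_cat), c("2", "4"))
  expect_equal(enc$en_ge1, c(0L, 1L))
  expect_equal(enc$en_gt1, c(0L, 1L))
  expect_equal(enc$age_gt60, c(1L, 0L))
  expect_equal(enc$ipi_score, c(2L, 2L))
})
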