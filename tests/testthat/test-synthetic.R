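test_that("default configuration generates the full study-sized cohort", {
  cohort <- generate_cohort(cohort_config(seed = 11), KB)
  expect_equal(nrow(cohort), 249)
  expect_equal(ncol(cohort), 41)
  expect_true(all(c("patient_id", "gfr", "hba1c", "has_ckd", "has_t2dm",
                    "has_dialysis", "prescription") %in% names(cohort)))
  # study defaults: everyone diabetic, nobody on dialysis
  expect_true(all(cohort$has_t2dm == "Yes"))
  expect_true(all(cohort$has_dialysis == "No"))
})

test_that("the generator is deterministic given its seed", {
  a <- generate_cohort(cohort_config(n = 40, seed = 7), KB)
  b <- generate_cohort(cohort_config(n = 40, seed = 7), KB)
  c <- generate_cohort(cohort_config(n = 40, seed = 8), KB)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("generated GFRs always classify back to their sampled stage mix", {
  g5_only <- cohort_config(n = 60, seed = 2,
                           stage_mix = c(G1 = 0, G2 = 0, G3a = 0, G3b = 0,
                                         G4 = 0, G5 = 1))
  cohort <- generate_cohort(g5_only, KB)
  expect_true(all(cohort$gfr < 15))
  expect_true(all(classify_ckd_stage(cohort$gfr, KB) == "G5"))
})

test_that("a default-sized cohort covers all stages and all dose bands", {
  cohort <- generate_cohort(cohort_config(n = 249, seed = 5), KB)
  stages <- classify_ckd_stage(cohort$gfr, KB)
  expect_setequal(unique(stages), c("G1", "G2", "G3a", "G3b", "G4", "G5"))
  bands <- vapply(cohort$gfr, gfr_band, character(1), kb = KB)
  expect_setequal(unique(bands), c("high", "mid", "low"))
  # prescriptions draw real KB drugs within the configured size range
  rx <- parse_prescription(cohort$prescription)
  expect_true(all(lengths(rx) >= 1 & lengths(rx) <= 5))
  expect_true(all(unlist(rx) %in% KB$drugs$drug))
  # HbA1c consistent with the diabetes flag under default rates
  expect_true(all(cohort$hba1c >= 6.5))
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(cohort_config(n = 0), "invalid config")
  expect_error(cohort_config(stage_mix = c(G1 = 1)), "invalid config")
  expect_error(cohort_config(stage_mix = c(G1 = 0.5, G2 = 0.5, G3a = 0.5,
                                           G3b = 0, G4 = 0, G5 = 0)),
               "invalid config")
  expect_error(cohort_config(t2dm_rate = 1.5), "invalid config")
  expect_error(cohort_config(prescription_size = c(5, 1)), "invalid config")
})

test_that("a flip-free rater panel agrees with the system everywhere", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 9), KB)
  reports <- generate_reports(cohort, KB)
  panel <- simulate_rater_panel(reports, KB, raters = 3, flip_rate = 0,
                                seed = 1)
  expect_true(all(c("item_id", "patient_id", "category", "system_flag",
                    "rater_1", "rater_2", "rater_3") %in% names(panel)))
  # positives = report items; negatives exist in every category
  expect_equal(sum(panel$system_flag), nrow(reports))
  negs <- panel[!panel$system_flag, ]
  expect_setequal(unique(negs$category), c("drug_dose", "ddi", "k_raising"))
  # flip_rate 0: every rater endorses exactly the system's view
  for (k in 1:3) {
    expect_equal(panel[[paste0("rater_", k)]],
                 ifelse(panel$system_flag, "T", "F"))
  }
})

test_that("rater flips occur at close to the requested rate", {
  cohort <- generate_cohort(cohort_config(n = 60, seed = 13), KB)
  reports <- generate_reports(cohort, KB)
  flip_rate <- 0.1
  panel <- simulate_rater_panel(reports, KB, raters = 3,
                                flip_rate = flip_rate, seed = 4)
  correct <- ifelse(panel$system_flag, "T", "F")
  flips <- unlist(lapply(1:3, function(k) {
    panel[[paste0("rater_", k)]] != correct
  }))
  n <- length(flips)
  se <- sqrt(flip_rate * (1 - flip_rate) / n)
  expect_lt(abs(mean(flips) - flip_rate), 3 * se + 1e-12)

  all_flipped <- simulate_rater_panel(reports, KB, raters = 1, flip_rate = 1,
                                      seed = 4)
  expect_equal(all_flipped$rater_1,
               ifelse(all_flipped$system_flag, "F", "T"))
})

test_that("even rater panels and out-of-range flip rates are rejected", {
  reports <- generate_reports(generate_cohort(cohort_config(n = 2, seed = 1),
                                              KB), KB)
  expect_error(simulate_rater_panel(reports, KB, raters = 2), "odd")
  expect_error(simulate_rater_panel(reports, KB, flip_rate = 1.5),
               "flip_rate")
})
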