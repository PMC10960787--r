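test_that("majority voting takes the strict majority and demands odd panels", {
  expect_equal(majority_vote(c("T", "T", "F")), "T")
  expect_equal(majority_vote(c("F", "T", "F")), "F")
  expect_equal(majority_vote(c("T", "F", "F", "F", "T")), "F")
  expect_equal(majority_vote("T"), "T")
  expect_error(majority_vote(c("T", "F")), "odd")
  expect_error(majority_vote(character()), "odd")
  expect_error(majority_vote(c("T", "yes", "F")), "T.*F|'T'/'F'")
})

test_that("confusion counts tally a panel exactly as hand bookkeeping does", {
  panel <- tibble::tibble(
    item_id = paste0("i", 1:6),
    patient_id = "P1",
    category = "drug_dose",
    system_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    rater_1 = c("T", "T", "F", "F", "F", "T"),
    rater_2 = c("T", "F", "F", "F", "T", "T"),
    rater_3 = c("T", "T", "T", "F", "F", "T")
  )
  # majority truth: T T F F F T -> tp=2 (i1,i2), fn? system F & truth T: i6
  counts <- confusion_from_panel(panel)
  expect_equal(counts$tp, 2)
  expect_equal(counts$fp, 1)
  expect_equal(counts$tn, 2)
  expect_equal(counts$fn, 1)
  # single-rater truth
  counts1 <- confusion_from_panel(panel, truth = 1)
  expect_equal(counts1$tp, 2)
  expect_equal(counts1$fn, 1)
  expect_error(confusion_from_panel(panel, truth = 9), "no such rater")
})

test_that("metrics match their published formulas on worked counts", {
  counts <- confusion_counts(tp = 49, tn = 44, fp = 6, fn = 1)
  expect_equal(accuracy(counts), 93 / 100)
  expect_equal(sensitivity(counts), 49 / 50)
  expect_equal(specificity(counts), 44 / 50)
  expect_equal(precision(counts), 49 / 55)
})

test_that("zero-denominator metrics error rather than report 0", {
  no_neg <- confusion_counts(tp = 5, tn = 0, fp = 0, fn = 0)
  expect_error(specificity(no_neg), "zero denominator")
  no_pos <- confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_error(sensitivity(no_pos), "zero denominator")
  expect_error(precision(no_pos), "zero denominator")
  expect_error(confusion_counts(tp = -1, tn = 0, fp = 0, fn = 0),
               "non-negative")
})

test_that("mse follows its definition and rejects malformed input", {
  expect_equal(mse(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(mse(c(1, 0, 1), c(1, 1, 1)), 1 / 3)
  expect_equal(mse(c(1, 0), c(0, 1)), 1)
  expect_error(mse(c(1, 0), c(1)), "equal length")
  expect_error(mse(numeric(), numeric()), "at least one")
})

test_that("metric identities hold over random confusion counts", {
  withr::with_seed(99, {
    for (i in 1:50) {
      tp <- sample(1:80, 1); tn <- sample(1:80, 1)
      fp <- sample(1:80, 1); fn <- sample(1:80, 1)
      counts <- confusion_counts(tp = tp, tn = tn, fp = fp, fn = fn)
      total <- tp + tn + fp + fn
      # accuracy is the prevalence-weighted mean of sensitivity & specificity
      expect_equal(
        accuracy(counts),
        (sensitivity(counts) * (tp + fn) +
           specificity(counts) * (tn + fp)) / total
      )
      expect_true(precision(counts) >= 0 && precision(counts) <= 1)
    }
  })
})

test_that("over binary correctness indicators MSE equals 1 - accuracy", {
  cohort <- generate_cohort(cohort_config(n = 25, seed = 21), KB)
  reports <- generate_reports(cohort, KB)
  panel <- simulate_rater_panel(reports, KB, raters = 3, flip_rate = 0.15,
                                seed = 6)
  ev <- evaluate_cohort(reports, panel)
  expect_equal(ev$overall$mse, 1 - ev$overall$accuracy)
})

test_that("a flip-free evaluation is perfect and a full cohort run coheres", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 17), KB)
  reports <- generate_reports(cohort, KB)
  panel <- simulate_rater_panel(reports, KB, raters = 3, flip_rate = 0,
                                seed = 2)
  ev <- evaluate_cohort(reports, panel)
  expect_equal(ev$overall$accuracy, 1)
  expect_equal(ev$overall$sensitivity, 1)
  expect_equal(ev$overall$specificity, 1)
  expect_equal(ev$overall$precision, 1)
  expect_equal(ev$overall$mse, 0)
  # category counts conserve the panel
  expect_equal(sum(ev$per_category$tp + ev$per_category$tn +
                     ev$per_category$fp + ev$per_category$fn),
               ev$n_items)
  expect_setequal(ev$per_category$category,
                  c("drug_dose", "ddi", "k_raising"))
  # per-patient and curve shapes
  expect_equal(nrow(ev$per_patient), length(unique(panel$patient_id)))
  expect_equal(nrow(ev$mse_curve), length(unique(panel$patient_id)))
  expect_equal(ev$mse_curve$running_mse[nrow(ev$mse_curve)], 0)
  # broom-style accessors
  expect_equal(tidy(ev), ev$per_category)
  expect_equal(glance(ev)$n_items, ev$n_items)
})

test_that("evaluation is invariant to panel row order", {
  cohort <- generate_cohort(cohort_config(n = 15, seed = 23), KB)
  reports <- generate_reports(cohort, KB)
  panel <- simulate_rater_panel(reports, KB, raters = 3, flip_rate = 0.2,
                                seed = 8)
  shuffled <- panel[withr::with_seed(1, sample.int(nrow(panel))), ]
  a <- evaluate_cohort(reports, panel)
  b <- evaluate_cohort(reports, shuffled)
  expect_equal(a$overall, b$overall)
  expect_equal(dplyr::arrange(a$per_category, category),
               dplyr::arrange(b$per_category, category))
})

test_that("report/panel mismatches are a reconciliation error", {
  cohort <- generate_cohort(cohort_config(n = 5, seed = 31), KB)
  reports <- generate_reports(cohort, KB)
  panel <- simulate_rater_panel(reports, KB, raters = 3, seed = 3)
  expect_error(evaluate_cohort(reports[-1, ], panel), "reconciliation error")
  expect_error(evaluate_cohort(reports, panel[panel$system_flag == FALSE, ]),
               "reconciliation error")
})
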