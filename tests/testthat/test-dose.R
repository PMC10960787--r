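test_that("Acarbose at GFR 30 resolves to 50 mg t.i.d (50% of 100 mg)", {
  item <- resolve_ckd_dose("Acarbose", ckd_t2dm_profile(gfr = 30), KB)
  expect_equal(nrow(item), 1)
  expect_equal(item$record, "recommendation")
  expect_equal(item$kind, "fraction")
  expect_equal(item$band, "mid")
  expect_equal(item$fraction_lo, 50)
  expect_equal(item$dose_hi_mg, 50)
  expect_equal(item$dose_label, "50mg_tid")
})

test_that("Acebutolol at GFR 5 resolves to the absolute 180-300 mg dose", {
  item <- resolve_ckd_dose("Acebutolol", ckd_t2dm_profile(gfr = 5), KB)
  expect_equal(item$kind, "absolute")
  expect_equal(item$band, "low")
  expect_equal(item$dose_lo_mg, 180)
  expect_equal(item$dose_hi_mg, 300)
  expect_equal(item$dose_label, "180mg_300mg_q24hr_or_bid")
})

test_that("an avoid band yields a contraindication warning", {
  item <- resolve_ckd_dose("Amiloride", ckd_t2dm_profile(gfr = 5), KB)
  expect_equal(item$record, "warning")
  expect_equal(item$kind, "contraindicated")
})

test_that("dialysis always routes to a referral, never a GFR-band dose", {
  p <- ckd_t2dm_profile(gfr = 30, has_dialysis = "Yes")
  item <- resolve_ckd_dose("Acarbose", p, KB)
  expect_equal(item$kind, "dialysis_referral")
  expect_equal(item$record, "warning")
})

test_that("dose rules only fire on explicit flags (missing is not No)", {
  base <- ckd_t2dm_profile(gfr = 30)
  expect_equal(nrow(resolve_ckd_dose(
    "Acarbose", utils::modifyList(base, list(has_ckd = "No")), KB)), 0)
  expect_equal(nrow(resolve_ckd_dose(
    "Acarbose", utils::modifyList(base, list(has_ckd = NA)), KB)), 0)
  expect_equal(nrow(resolve_ckd_dose(
    "Acarbose", utils::modifyList(base, list(has_dialysis = NA)), KB)), 0)
})

test_that("unknown drugs error; known drugs without dose data warn", {
  expect_error(resolve_ckd_dose("NotADrug", ckd_t2dm_profile(), KB),
               "unknown drug")
  item <- resolve_ckd_dose("Metoprolol", ckd_t2dm_profile(gfr = 30), KB)
  expect_equal(item$kind, "no_data")
})

test_that("a 100% band is an explicit 'unchanged' recommendation", {
  item <- resolve_ckd_dose("Eprosartan", ckd_t2dm_profile(gfr = 75), KB)
  expect_equal(item$record, "recommendation")
  expect_equal(item$fraction_lo, 100)
  expect_equal(item$fraction_hi, 100)
})

test_that("range fractions stay ranges and arithmetic is to 2 decimals", {
  item <- resolve_ckd_dose("Benazepril", ckd_t2dm_profile(gfr = 5), KB)
  expect_equal(item$kind, "fraction")
  expect_equal(item$fraction_lo, 25)
  expect_equal(item$fraction_hi, 50)
  expect_lt(item$dose_lo_mg, item$dose_hi_mg)
  entry <- KB$dose_entries[KB$dose_entries$drug == "Benazepril" &
                             KB$dose_entries$band == "low", ]
  expect_equal(item$dose_lo_mg, round(entry$max_lo_mg * 0.25, 2))
  expect_equal(item$dose_hi_mg, round(entry$max_hi_mg * 0.50, 2))
})

test_that("adjusted maxima never increase as GFR falls (all-fraction drugs)", {
  frac_drugs <- KB$dose_entries |>
    dplyr::group_by(drug) |>
    dplyr::filter(all(kind == "fraction")) |>
    dplyr::pull(drug) |>
    unique()
  expect_gt(length(frac_drugs), 0)
  for (d in frac_drugs) {
    hi <- resolve_ckd_dose(d, ckd_t2dm_profile(gfr = 80), KB)$dose_hi_mg
    mid <- resolve_ckd_dose(d, ckd_t2dm_profile(gfr = 30), KB)$dose_hi_mg
    lo <- resolve_ckd_dose(d, ckd_t2dm_profile(gfr = 5), KB)$dose_hi_mg
    vals <- c(hi, mid, lo)
    vals <- vals[!is.na(vals)]
    expect_true(!is.unsorted(rev(vals)),
                info = paste("band maxima increase for", d))
  }
})

test_that("prescription scope resolves only prescribed drugs with dose entries", {
  p <- ckd_t2dm_profile(gfr = 30,
                        prescription = "Acarbose;Metoprolol;Candesartan")
  items <- recommend_ckd_doses(p, KB)
  # Metoprolol is in the KB but has no dose entry, so only 2 items
  expect_setequal(items$drug, c("Acarbose", "Candesartan"))
})

test_that("formulary scope resolves every KB dose entry once", {
  items <- recommend_ckd_doses(ckd_t2dm_profile(gfr = 30), KB,
                               scope = "full_kb")
  expect_equal(nrow(items), 22)
  expect_equal(anyDuplicated(items$drug), 0)
})

test_that("T2DM dose reductions fire per band only with an explicit flag", {
  mid <- recommend_t2dm_doses(ckd_t2dm_profile(gfr = 30), KB)
  expect_equal(nrow(mid), 1)
  expect_equal(mid$drug, "Lispro mix")
  expect_equal(mid$reduce_pct, 25)
  expect_equal(mid$dose_label, "Reduce_Dose_by_25_percent")

  low <- recommend_t2dm_doses(ckd_t2dm_profile(gfr = 5), KB)
  expect_equal(low$drug, "Aspart")
  expect_equal(low$reduce_pct, 50)

  high <- recommend_t2dm_doses(ckd_t2dm_profile(gfr = 80), KB)
  expect_equal(nrow(high), 0)

  no_flag <- recommend_t2dm_doses(
    utils::modifyList(ckd_t2dm_profile(gfr = 30), list(has_t2dm = NA)), KB)
  expect_equal(nrow(no_flag), 0)
})
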