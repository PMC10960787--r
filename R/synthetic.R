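#' Configuration for the synthetic cohort generator
#'
#' Captures the study-shape parameters: cohort size (default 249 patients,
#' the size of the diabetic-CKD cohort the engine is designed around), the
#' CKD stage mix, disease-flag rates and prescription-size range. Defaults
#' mirror the study conditions: every patient diabetic (`t2dm_rate = 1`), a
#' small minority without confirmed CKD (`ckd_rate = 0.9`), and no dialysis
#' patients (`dialysis_rate = 0`, end-stage renal disease excluded) -
#' overridable to exercise the dialysis-referral path. Feature values are
#' drawn uniformly within clinically plausible ranges; coverage, not realism,
#' is the goal (the source cohort publishes no distributions).
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param stage_mix Named proportions over the six CKD stages; must sum to 1.
#' @param t2dm_rate,ckd_rate,dialysis_rate Probabilities in `[0, 1]` of an
#'   explicit "Yes" flag.
#' @param prescription_size Integer range `c(min, max)` of drugs per patient.
#' @param feature_ranges Named list of `c(low, high)` ranges for the numeric
#'   features; see defaults.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n = 249,
                          seed = 1L,
                          stage_mix = c(G1 = 0.15, G2 = 0.25, G3a = 0.20,
                                        G3b = 0.18, G4 = 0.15, G5 = 0.07),
                          t2dm_rate = 1,
                          ckd_rate = 0.9,
                          dialysis_rate = 0,
                          prescription_size = c(1L, 5L),
                          feature_ranges = default_feature_ranges()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("invalid config: `n` must be a single integer >= 1")
  }
  if (length(stage_mix) != length(.stage_levels) ||
      !setequal(names(stage_mix), .stage_levels)) {
    abort("invalid config: `stage_mix` must name all six stages G1..G5")
  }
  if (any(stage_mix < 0) || abs(sum(stage_mix) - 1) > 1e-8) {
    abort("invalid config: `stage_mix` proportions must be >= 0 and sum to 1")
  }
  for (r in c(t2dm_rate, ckd_rate, dialysis_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) {
      abort("invalid config: rates must lie in [0, 1]")
    }
  }
  if (length(prescription_size) != 2 || prescription_size[1] < 0 ||
      prescription_size[1] > prescription_size[2]) {
    abort("invalid config: `prescription_size` must be c(min, max), min <= max")
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      stage_mix = stage_mix[.stage_levels],
      t2dm_rate = t2dm_rate, ckd_rate = ckd_rate,
      dialysis_rate = dialysis_rate,
      prescription_size = as.integer(prescription_size),
      feature_ranges = feature_ranges
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_feature_ranges <- function() {
  list(
    age = c(30, 85), bmi = c(18, 40),
    sbp = c(100, 180), dbp = c(60, 110), heart_rate = c(55, 110),
    weight_kg = c(50, 120), height_cm = c(150, 195),
    serum_potassium = c(3.2, 6.0), serum_sodium = c(130, 148),
    serum_calcium = c(8.0, 10.8), serum_phosphate = c(2.3, 6.5),
    bicarbonate = c(16, 30), bun = c(8, 80), uric_acid = c(3, 10),
    hemoglobin = c(8, 17), hematocrit = c(25, 50), albumin = c(2.5, 5.2),
    total_cholesterol = c(120, 300), ldl_cholesterol = c(50, 200),
    hdl_cholesterol = c(25, 80), triglycerides = c(60, 400),
    fasting_glucose = c(80, 260), urine_acr = c(5, 1500),
    crp = c(0.1, 15), diabetes_duration_years = c(0.5, 30),
    n_comorbidities = c(0, 6), follow_up_years = c(0.5, 8)
  )
}

#' Generate a reproducible synthetic cohort
#'
#' Draws `config$n` patients with the 41-column cohort shape: demographics,
#' vitals, labs, the three disease flags and a prescription sampled from the
#' KB drug list. Each patient is first assigned a CKD stage from
#' `stage_mix`; the GFR is then drawn uniformly inside that stage's eGFR
#' interval, so generated GFRs always classify back to their assigned stage.
#' HbA1c is drawn consistent with the diabetes flag. The same config (and
#' seed) yields a byte-identical cohort.
#'
#' @param config A [cohort_config()].
#' @param kb A `renal_kb` object (drug names for prescriptions).
#' @return Tibble with `config$n` rows and 41 columns.
#' @export
generate_cohort <- function(config = cohort_config(),
                            kb = load_knowledge_base()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  n <- config$n
  fr <- config$feature_ranges
  draw <- function(name, digits = 1) {
    round(runif(n, fr[[name]][1], fr[[name]][2]), digits)
  }
  run_seeded(config$seed, {
    stage <- sample(.stage_levels, n, replace = TRUE, prob = config$stage_mix)
    s <- kb$staging_rules[match(stage, kb$staging_rules$stage), ]
    upper <- ifelse(is.finite(s$upper), s$upper, 120)
    gfr <- round(runif(n, s$lower, upper), 1)
    # keep inside the half-open stage interval after rounding
    gfr <- pmin(gfr, upper - 0.1)
    gfr <- pmax(gfr, pmax(s$lower, 0.5))

    has_t2dm <- ifelse(runif(n) < config$t2dm_rate, "Yes", "No")
    has_ckd <- ifelse(runif(n) < config$ckd_rate, "Yes", "No")
    has_dialysis <- ifelse(runif(n) < config$dialysis_rate, "Yes", "No")
    hba1c <- round(ifelse(has_t2dm == "Yes", runif(n, 6.5, 10.5),
                          runif(n, 4.8, 6.3)), 1)
    # serum creatinine loosely inverse to GFR (coarse physiology, not a model)
    scr <- round(pmin(12, pmax(0.5, 85 / gfr * runif(n, 0.8, 1.2))), 2)

    drugs <- sort(kb$drugs$drug)
    sizes <- seq(config$prescription_size[1], config$prescription_size[2])
    rx_size <- sizes[sample.int(length(sizes), n, replace = TRUE)]
    prescription <- vapply(rx_size, function(k) {
      paste(sort(drugs[sample.int(length(drugs), k)]), collapse = ";")
    }, character(1))

    tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = draw("age", 0),
      gender = sample(c("Female", "Male"), n, replace = TRUE),
      bmi = draw("bmi"),
      hba1c = hba1c,
      gfr = gfr,
      scr = scr,
      has_ckd = has_ckd,
      has_t2dm = has_t2dm,
      has_dialysis = has_dialysis,
      prescription = prescription,
      sbp = draw("sbp", 0),
      dbp = draw("dbp", 0),
      heart_rate = draw("heart_rate", 0),
      weight_kg = draw("weight_kg"),
      height_cm = draw("height_cm"),
      serum_potassium = draw("serum_potassium", 2),
      serum_sodium = draw("serum_sodium", 0),
      serum_calcium = draw("serum_calcium"),
      serum_phosphate = draw("serum_phosphate"),
      bicarbonate = draw("bicarbonate", 0),
      bun = draw("bun", 0),
      uric_acid = draw("uric_acid"),
      hemoglobin = draw("hemoglobin"),
      hematocrit = draw("hematocrit"),
      albumin = draw("albumin"),
      total_cholesterol = draw("total_cholesterol", 0),
      ldl_cholesterol = draw("ldl_cholesterol", 0),
      hdl_cholesterol = draw("hdl_cholesterol", 0),
      triglycerides = draw("triglycerides", 0),
      fasting_glucose = draw("fasting_glucose", 0),
      urine_acr = draw("urine_acr", 0),
      crp = draw("crp"),
      diabetes_duration_years = draw("diabetes_duration_years"),
      n_comorbidities = round(draw("n_comorbidities", 0)),
      follow_up_years = draw("follow_up_years"),
      smoking = sample(c("Never", "Former", "Current"), n, replace = TRUE),
      alcohol = sample(c("Yes", "No"), n, replace = TRUE),
      family_history_dm = sample(c("Yes", "No"), n, replace = TRUE),
      insulin_use = sample(c("Yes", "No"), n, replace = TRUE),
      statin_use = sample(c("Yes", "No"), n, replace = TRUE)
    )
  })
}

#' Simulate a rater panel over system report items
#'
#' Emulates the evaluation protocol in which independent specialists mark
#' each system output True or False. Every report item becomes a panel item
#' with `system_flag = TRUE`; per patient, distractor items the system did
#' *not* assert (`system_flag = FALSE`) are added in each category so that
#' true negatives exist and specificity is defined. Each rater's judgment
#' starts from the correct one (agreeing with the system) and flips
#' independently with probability `flip_rate`.
#'
#' @param reports Item tibble from [generate_reports()].
#' @param kb A `renal_kb` object (for distractor sampling).
#' @param raters Number of raters; must be odd (majority voting).
#' @param flip_rate Per-rater probability in `[0, 1]` of flipping the correct
#'   judgment.
#' @param seed Integer seed for reproducibility.
#' @param n_distractors Distractor items per patient and category.
#' @return A panel tibble: `item_id`, `patient_id`, `category`,
#'   `system_flag`, and one `rater_<k>` column per rater with "T"/"F".
#' @export
simulate_rater_panel <- function(reports, kb = load_knowledge_base(),
                                 raters = 3, flip_rate = 0, seed = 1L,
                                 n_distractors = 1) {
  if (raters < 1 || raters %% 2 == 0) {
    abort("`raters` must be odd (majority voting requires an odd panel)")
  }
  if (flip_rate < 0 || flip_rate > 1) abort("`flip_rate` must lie in [0, 1]")

  category_of <- c(ckd_dose = "drug_dose", t2dm_dose = "drug_dose",
                   ddi = "ddi", k_raising = "k_raising")
  pos <- tibble(
    item_id = reports$item_id,
    patient_id = reports$patient_id,
    category = unname(category_of[reports$item_type]),
    system_flag = TRUE
  )

  run_seeded(seed, {
    kdrugs <- k_raising_drugs(kb)
    non_k <- sort(setdiff(kb$drugs$drug, kdrugs))
    dose_drugs <- sort(unique(kb$dose_entries$drug))
    all_pairs <- t(combn(sort(kb$drugs$drug), 2))
    pair_key <- paste(all_pairs[, 1], all_pairs[, 2], sep = "+")
    inert_pairs <- all_pairs[!pair_key %in%
                               paste(kb$ddi_pairs$drug1, kb$ddi_pairs$drug2,
                                     sep = "+"), , drop = FALSE]

    neg <- purrr::map_dfr(unique(reports$patient_id), function(pid) {
      own <- reports[reports$patient_id == pid, ]
      pool_dose <- setdiff(dose_drugs, own$drug)
      d_dose <- sort(pool_dose[sample.int(length(pool_dose),
                                          min(n_distractors, length(pool_dose)))])
      ij <- sample.int(nrow(inert_pairs), min(n_distractors, nrow(inert_pairs)))
      d_k <- sort(non_k[sample.int(length(non_k),
                                   min(n_distractors, length(non_k)))])
      dplyr::bind_rows(
        tibble(item_id = paste0(pid, ":neg:drug_dose:", d_dose),
               patient_id = pid, category = "drug_dose", system_flag = FALSE),
        tibble(item_id = paste0(pid, ":neg:ddi:", inert_pairs[ij, 1], "+",
                                inert_pairs[ij, 2]),
               patient_id = pid, category = "ddi", system_flag = FALSE),
        tibble(item_id = paste0(pid, ":neg:k_raising:", d_k),
               patient_id = pid, category = "k_raising", system_flag = FALSE)
      )
    })

    panel <- dplyr::bind_rows(pos, neg)
    for (k in seq_len(raters)) {
      flip <- runif(nrow(panel)) < flip_rate
      judgment <- xor(panel$system_flag, flip)
      panel[[paste0("rater_", k)]] <- ifelse(judgment, "T", "F")
    }
    panel
  })
}
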