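#' Resolve the GFR-adjusted dose of one CKD drug for one patient
#'
#' Implements the renal dose-adjustment rule family. A rule fires only for a
#' patient with explicit `has_ckd = "Yes"` and explicit `has_dialysis = "No"`
#' (missing flags never fire a dose rule; absence of evidence is not
#' evidence). A patient on dialysis gets a `dialysis_referral` warning
#' instead, whatever the drug. Otherwise the patient's GFR selects the dose
#' band and the drug's band adjustment resolves to:
#'
#' * `fraction` - a recommendation; adjusted starting and maximum doses are
#'   base dose x fraction / 100 (reported to 2 decimals); range fractions
#'   (e.g. 25-50%) stay ranges and are never collapsed,
#' * `absolute` - a recommendation with the published fixed dose,
#' * `avoid` - a `contraindicated` warning,
#' * `no_data` - a `no_data` warning.
#'
#' @param drug Drug name; must exist in the KB.
#' @param profile A one-row data frame or named list with at least `gfr`,
#'   `has_ckd`, `has_dialysis` (flags are "Yes"/"No"/missing).
#' @param kb A `renal_kb` object.
#' @return A tibble of report items (zero or one row) in the unified item
#'   schema (`item_type`, `record`, `kind`, `drug`, `band`, fraction and dose
#'   columns, `dose_label`, `rule_id`, `message`).
#' @examples
#' kb <- load_knowledge_base()
#' p <- list(gfr = 30, has_ckd = "Yes", has_dialysis = "No")
#' resolve_ckd_dose("Acarbose", p, kb)
#' @export
resolve_ckd_dose <- function(drug, profile, kb = load_knowledge_base()) {
  p <- as_profile(profile)
  if (!drug %in% kb$drugs$drug) {
    abort(paste0("unknown drug (not in KB): ", drug))
  }
  ckd <- yes_no(p$has_ckd)
  dialysis <- yes_no(p$has_dialysis)

  if (identical(dialysis, "Yes")) {
    return(item_row(
      item_type = "ckd_dose", record = "warning", kind = "dialysis_referral",
      drug = drug, rule_id = "dose_dialysis_referral",
      message = paste0(drug, ": patient on dialysis; dosing requires ",
                       "nephrology referral, GFR-band rules do not apply")
    ))
  }
  if (!identical(ckd, "Yes") || !identical(dialysis, "No")) {
    return(empty_items())
  }
  if (is.null(p$gfr) || is.na(p$gfr)) abort("profile has no GFR value")

  entry <- kb$dose_entries |> dplyr::filter(.data$drug == !!drug)
  if (nrow(entry) == 0) {
    return(item_row(
      item_type = "ckd_dose", record = "warning", kind = "no_data",
      drug = drug, rule_id = paste0("dose_", tolower(drug), "_none"),
      message = paste0(drug, ": no GFR-banded dose guidance in the KB")
    ))
  }

  band <- gfr_band(p$gfr, kb)
  adj <- entry |> dplyr::filter(.data$band == !!band)
  rule_id <- paste0("dose_", gsub("[^a-z0-9]+", "_", tolower(drug)), "_", band)

  if (adj$kind == "avoid") {
    return(item_row(
      item_type = "ckd_dose", record = "warning", kind = "contraindicated",
      drug = drug, band = band, rule_id = rule_id,
      message = paste0(drug, ": avoid at GFR band '", band, "'")
    ))
  }
  if (adj$kind == "no_data") {
    return(item_row(
      item_type = "ckd_dose", record = "warning", kind = "no_data",
      drug = drug, band = band, rule_id = rule_id,
      message = paste0(drug, ": no dose data for GFR band '", band, "'")
    ))
  }
  if (adj$kind == "absolute") {
    return(item_row(
      item_type = "ckd_dose", record = "recommendation", kind = "absolute",
      drug = drug, band = band,
      dose_lo_mg = adj$abs_lo_mg, dose_hi_mg = adj$abs_hi_mg,
      dose_label = adj$abs_label, rule_id = rule_id,
      message = paste0(drug, ": ", adj$abs_text)
    ))
  }

  # fraction of normal dose
  start_lo <- round(adj$start_lo_mg * adj$lo_pct / 100, 2)
  start_hi <- round(adj$start_hi_mg * adj$hi_pct / 100, 2)
  max_lo <- round(adj$max_lo_mg * adj$lo_pct / 100, 2)
  max_hi <- round(adj$max_hi_mg * adj$hi_pct / 100, 2)
  label <- dose_label_for(drug, adj, max_lo, max_hi)
  msg <- if (adj$lo_pct == 100 && adj$hi_pct == 100) {
    paste0(drug, ": normal dose (100%), unchanged")
  } else {
    pct <- if (adj$lo_pct == adj$hi_pct) paste0(adj$lo_pct, "%") else
      paste0(adj$lo_pct, "-", adj$hi_pct, "%")
    mx <- if (!is.na(max_hi)) {
      paste0(" (maximum ",
             if (!is.na(max_lo) && max_lo != max_hi)
               paste0(fmt_mg(max_lo), "-", fmt_mg(max_hi)) else fmt_mg(max_hi),
             " mg ", adj$max_freq, ")")
    } else ""
    paste0(drug, ": ", pct, " of normal dose", mx)
  }
  item_row(
    item_type = "ckd_dose", record = "recommendation", kind = "fraction",
    drug = drug, band = band,
    fraction_lo = adj$lo_pct, fraction_hi = adj$hi_pct,
    start_lo_mg = start_lo, start_hi_mg = start_hi,
    dose_lo_mg = max_lo, dose_hi_mg = max_hi,
    dose_label = label, rule_id = rule_id, message = msg
  )
}

# dose-individual label in the published style, e.g. "50mg_tid",
# "180mg_300mg_q24hr_or_bid", "25_50pct_of_normal" when no mg base exists
dose_label_for <- function(drug, adj, max_lo, max_hi) {
  if (!is.na(max_hi)) {
    f <- freq_label(adj$max_freq)
    if (!is.na(max_lo) && max_lo != max_hi) {
      paste0(fmt_mg(max_lo), "mg_", fmt_mg(max_hi), "mg_", f)
    } else {
      paste0(fmt_mg(max_hi), "mg_", f)
    }
  } else if (adj$lo_pct == 100 && adj$hi_pct == 100) {
    "unchanged"
  } else if (adj$lo_pct == adj$hi_pct) {
    paste0(adj$lo_pct, "pct_of_normal")
  } else {
    paste0(adj$lo_pct, "_", adj$hi_pct, "pct_of_normal")
  }
}

#' Recommend GFR-adjusted doses for all applicable CKD drugs
#'
#' Applies [resolve_ckd_dose()] across drugs. In `"prescription"` scope
#' (audit mode, the default) only drugs in the patient's prescription that
#' have a dose entry are resolved; in `"full_kb"` scope (formulary mode)
#' every KB dose entry is resolved, one item per entry.
#'
#' @param profile One-row data frame or named list (see [resolve_ckd_dose()]);
#'   in prescription scope it must carry a `prescription` field
#'   (semicolon-delimited string) or `prescription_drugs` character vector.
#' @param kb A `renal_kb` object.
#' @param scope `"prescription"` or `"full_kb"`.
#' @return Tibble of report items in canonical order (by drug, then rule id).
#' @export
recommend_ckd_doses <- function(profile, kb = load_knowledge_base(),
                                scope = c("prescription", "full_kb")) {
  scope <- match.arg(scope)
  p <- as_profile(profile)
  ckd <- yes_no(p$has_ckd)
  dialysis <- yes_no(p$has_dialysis)
  if (!identical(dialysis, "Yes") &&
      (!identical(ckd, "Yes") || !identical(dialysis, "No"))) {
    return(empty_items())
  }
  entry_drugs <- unique(kb$dose_entries$drug)
  drugs <- if (scope == "full_kb") {
    entry_drugs
  } else {
    rx <- unique(p$prescription_drugs %||% character())
    unknown <- setdiff(rx, kb$drugs$drug)
    if (length(unknown) > 0) {
      message("skipping unknown prescription drug(s): ",
              paste(unknown, collapse = ", "))
    }
    intersect(rx, entry_drugs)
  }
  if (length(drugs) == 0) return(empty_items())
  purrr::map_dfr(sort(drugs), resolve_ckd_dose, profile = p, kb = kb) |>
    arrange_items()
}

#' Recommend T2DM drug dose reductions
#'
#' Fires only for patients with explicit `has_t2dm = "Yes"`. The KB's T2DM
#' dose rules attach a percent reduction of the current dose to an agent in a
#' GFR band: in the bundled KB, Lispro mix insulin is reduced by 25% in the
#' mid band (GFR 10-50) and Aspart (NovoRapid) by 50% in the low band
#' (GFR < 10).
#'
#' @inheritParams recommend_ckd_doses
#' @return Tibble of report items (`item_type = "t2dm_dose"`, kind
#'   `"reduction"`, percent in `reduce_pct`).
#' @examples
#' kb <- load_knowledge_base()
#' recommend_t2dm_doses(list(gfr = 30, has_t2dm = "Yes"), kb)
#' @export
recommend_t2dm_doses <- function(profile, kb = load_knowledge_base()) {
  p <- as_profile(profile)
  if (!identical(yes_no(p$has_t2dm), "Yes")) return(empty_items())
  if (is.null(p$gfr) || is.na(p$gfr)) abort("profile has no GFR value")
  band <- gfr_band(p$gfr, kb)
  rules <- kb$t2dm_dose_rules |> dplyr::filter(.data$band == !!band)
  if (nrow(rules) == 0) return(empty_items())
  purrr::pmap_dfr(rules, function(rule_id, drug, band, reduce_pct) {
    item_row(
      item_type = "t2dm_dose", record = "recommendation", kind = "reduction",
      drug = drug, band = band, reduce_pct = reduce_pct,
      dose_label = paste0("Reduce_Dose_by_", reduce_pct, "_percent"),
      rule_id = rule_id,
      message = paste0(drug, ": reduce current dose by ", reduce_pct,
                       "% (GFR band '", band, "')")
    )
  }) |>
    arrange_items()
}
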