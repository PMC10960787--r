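#' Per-patient prescription report
#'
#' Assembles the full inference output for one patient: CKD stage, diabetes
#' status, GFR-adjusted CKD dose recommendations, T2DM dose reductions,
#' drug-drug interaction warnings and potassium-increase warnings. Output is
#' deterministic given (profile, KB) and items are in canonical order
#' (item family, then drug names, then rule id). Interaction and potassium
#' warnings are unconditional on the disease flags, matching the published
#' rule forms; dose rules are gated on the flags as documented in
#' [resolve_ckd_dose()] and [recommend_t2dm_doses()].
#'
#' @param profile One-row data frame or named list with `patient_id`, `gfr`,
#'   `hba1c`, the `has_ckd`/`has_t2dm`/`has_dialysis` flags and a
#'   `prescription` (semicolon-delimited string).
#' @param kb A `renal_kb` object.
#' @param scope Dose-recommendation scope, see [recommend_ckd_doses()].
#' @return A `patient_report` object: list with `patient_id`, `stage`,
#'   `t2dm_status`, `items` (unified item tibble with `item_id`), `scope`,
#'   `kb_version`.
#' @examples
#' kb <- load_knowledge_base()
#' p <- list(
#'   patient_id = "M001", gfr = 30, hba1c = 7.2, has_ckd = "Yes",
#'   has_t2dm = "Yes", has_dialysis = "No",
#'   prescription = "Acarbose;Candesartan;Ramipril"
#' )
#' generate_report(p, kb)
#' @export
generate_report <- function(profile, kb = load_knowledge_base(),
                            scope = c("prescription", "full_kb")) {
  scope <- match.arg(scope)
  p <- as_profile(profile)
  patient_id <- as.character(p$patient_id %||% "patient")
  if (is.null(p$gfr) || is.na(p$gfr)) abort("profile has no GFR value")

  stage <- classify_ckd_stage(p$gfr, kb)
  t2dm_status <- classify_t2dm_status(
    if (is.null(p$hba1c)) NA_real_ else as.numeric(p$hba1c), kb
  )
  rx <- p$prescription_drugs %||% character()

  items <- dplyr::bind_rows(
    recommend_ckd_doses(p, kb, scope = scope),
    recommend_t2dm_doses(p, kb),
    ddi_warnings(rx, kb),
    k_raising_warnings(rx, kb)
  ) |>
    arrange_items()
  items <- dplyr::bind_cols(
    tibble(patient_id = rep(patient_id, nrow(items))),
    items
  )
  items$item_id <- make_item_id(items$patient_id, items$item_type,
                                items$drug, items$drug2)

  structure(
    list(
      patient_id = patient_id,
      stage = stage,
      t2dm_status = t2dm_status,
      items = items,
      scope = scope,
      kb_version = kb$version
    ),
    class = "patient_report"
  )
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report>", x$patient_id, "\n")
  cat("  CKD stage   :", x$stage, "\n")
  cat("  T2DM status :", x$t2dm_status, "\n")
  n_rec <- sum(x$items$record == "recommendation")
  n_warn <- sum(x$items$record == "warning")
  cat("  items       :", n_rec, "recommendation(s),", n_warn, "warning(s)\n")
  if (nrow(x$items) > 0) {
    print(dplyr::select(x$items, "item_type", "record", "kind", "drug",
                        "drug2", "dose_label", "rule_id"))
  }
  invisible(x)
}

#' @describeIn generate_report Tidy the report into its item tibble (one row
#'   per recommendation/warning, stage and status carried as columns).
#' @param x A `patient_report`.
#' @param ... Unused.
#' @export
tidy.patient_report <- function(x, ...) {
  items <- x$items
  items$stage <- rep(x$stage, nrow(items))
  items$t2dm_status <- rep(x$t2dm_status, nrow(items))
  items
}

#' @describeIn generate_report One-row summary of the report.
#' @export
glance.patient_report <- function(x, ...) {
  tibble(
    patient_id = x$patient_id,
    stage = x$stage,
    t2dm_status = x$t2dm_status,
    n_items = nrow(x$items),
    n_recommendations = sum(x$items$record == "recommendation"),
    n_warnings = sum(x$items$record == "warning"),
    scope = x$scope,
    kb_version = x$kb_version
  )
}

#' Generate reports for a whole cohort
#'
#' @param cohort Tibble of patient rows (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param kb A `renal_kb` object.
#' @param scope Dose-recommendation scope, see [recommend_ckd_doses()].
#' @return A tibble of report items across all patients (unified item schema
#'   plus `patient_id`, `item_id`, `stage`, `t2dm_status`), in cohort order.
#' @export
generate_reports <- function(cohort, kb = load_knowledge_base(),
                             scope = c("prescription", "full_kb")) {
  scope <- match.arg(scope)
  out <- purrr::map(seq_len(nrow(cohort)), function(i) {
    tidy(generate_report(cohort[i, ], kb, scope = scope))
  })
  dplyr::bind_rows(out)
}

#' Write report items as a flat evaluation CSV
#'
#' The flat layout (`patient_id`, `item_type`, `drug`, `drug2`, `value`,
#' `rule_id`) is the sheet sent out for rater evaluation: `value` holds the
#' dose label for recommendations and the message for warnings.
#'
#' @param items Item tibble from [generate_reports()] or
#'   [tidy()][tidy.patient_report] of a single report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(items, path) {
  flat <- items |>
    dplyr::mutate(
      value = ifelse(.data$record == "recommendation",
                     .data$dose_label, .data$message)
    ) |>
    dplyr::select("patient_id", "item_type", "drug", "drug2", "value",
                  "rule_id")
  readr::write_csv(flat, path, na = "")
  invisible(path)
}
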