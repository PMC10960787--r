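#' Read a patient cohort from CSV
#'
#' Expects a UTF-8 CSV with a header row, one patient per row. Canonical
#' column names are `patient_id`, `age`, `gender`, `bmi`, `hba1c`, `gfr`,
#' `scr`, `has_ckd`, `has_t2dm`, `has_dialysis`, `prescription` (a
#' semicolon-delimited drug list); any further columns ride along untouched
#' as extra characteristics. Files with other headers are adapted through
#' `column_map`. Only `patient_id` and `gfr` are mandatory; everything else
#' may be absent or empty and is kept as missing (flags are never defaulted
#' to "No" - a dose rule must only fire on an explicit flag).
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(patient_id = "ID", gfr = "eGFR")`.
#' @return A tibble of patients, with a `provenance` attribute naming the
#'   source file.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df)) {
        abort(paste0("configuration error: mapped column '", src,
                     "' not present in ", path))
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  for (mandatory in c("patient_id", "gfr")) {
    if (!mandatory %in% names(df)) {
      abort(paste0("configuration error: mandatory column '", mandatory,
                   "' missing from ", path))
    }
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id) > 0) {
    abort(paste0("data error: duplicate patient_id in ", path, ": ",
                 paste(unique(df$patient_id[duplicated(df$patient_id)]),
                       collapse = ", ")))
  }
  # numeric vitals: unparseable cells become missing, with a log line
  for (col in intersect(c("age", "bmi", "hba1c", "gfr", "scr"), names(df))) {
    if (!is.numeric(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      n_bad <- sum(is.na(parsed) & !is.na(df[[col]]) & df[[col]] != "")
      if (n_bad > 0) {
        message(n_bad, " unparseable value(s) in column '", col,
                "' set to missing")
      }
      df[[col]] <- parsed
    }
  }
  for (col in intersect(c("has_ckd", "has_t2dm", "has_dialysis"), names(df))) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  df <- as_tibble(df)
  attr(df, "provenance") <- path
  df
}

#' Write a cohort to CSV
#'
#' Writes the same CSV dialect [read_cohort()] reads (UTF-8, header row,
#' semicolon-delimited prescription column, empty string for missing).
#'
#' @param cohort Tibble of patients.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Split semicolon-delimited prescription strings into drug-name vectors
#'
#' @param x Character vector of prescriptions ("DrugA;DrugB;...").
#' @return List of character vectors (empty for missing/blank input).
#' @export
parse_prescription <- function(x) {
  purrr::map(x, function(s) {
    if (length(s) == 0 || is.na(s) || !nzchar(trimws(s))) return(character())
    out <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
}

#' Validate one patient profile against the knowledge base
#'
#' Issues are data, not errors: out-of-range vitals, prescription drugs the
#' KB does not know, and contradictory flags (an explicit `has_ckd = "No"`
#' with a kidney-failure-range GFR below 15 is flagged as suspicious, not
#' fatal).
#'
#' @param profile One-row data frame or named list.
#' @param kb A `renal_kb` object.
#' @return Tibble with columns `field` and `issue`; zero rows when clean.
#' @export
validate_profile <- function(profile, kb = load_knowledge_base()) {
  p <- as_profile(profile)
  issues <- list()
  note <- function(field, issue) tibble(field = field, issue = issue)

  gfr <- p$gfr %||% NA_real_
  if (is.na(gfr) || !is.finite(gfr) || gfr <= 0) {
    issues <- c(issues, list(note("gfr", "gfr out of range (must be > 0)")))
  }
  hba1c <- p$hba1c %||% NA_real_
  if (!is.na(hba1c) && (hba1c <= 3 || hba1c >= 20)) {
    issues <- c(issues, list(note("hba1c", "hba1c out of range (3, 20)")))
  }
  for (fl in c("has_ckd", "has_t2dm", "has_dialysis")) {
    val <- yes_no(p[[fl]])
    if (!is.na(val) && !val %in% c("Yes", "No")) {
      issues <- c(issues, list(note(fl, paste0(fl, " must be Yes/No/missing, got '",
                                               val, "'"))))
    }
  }
  unknown <- setdiff(p$prescription_drugs, kb$drugs$drug)
  for (u in unknown) {
    issues <- c(issues, list(note("prescription", paste0("unknown drug: ", u))))
  }
  if (!is.na(gfr) && is.finite(gfr) && gfr > 0 &&
      identical(yes_no(p$has_ckd), "No") &&
      classify_ckd_stage(gfr, kb) %in% c("G4", "G5")) {
    issues <- c(issues, list(note(
      "has_ckd",
      paste0("suspicious: has_ckd is 'No' but gfr ", gfr,
             " falls in stage ", classify_ckd_stage(gfr, kb))
    )))
  }
  if (length(issues) == 0) {
    tibble(field = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
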