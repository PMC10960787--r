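#' Classify CKD stage from eGFR
#'
#' Assigns each eGFR value to exactly one of the six CKD stages (G1 best
#' kidney function through G5 kidney failure) using half-open intervals
#' `[lower, upper)`: G1 `[90, Inf)`, G2 `[60, 90)`, G3a `[45, 60)`,
#' G3b `[30, 45)`, G4 `[15, 30)`, G5 `[0, 15)`.
#'
#' @param gfr Numeric vector of eGFR values (mL/min/1.73 m^2), all positive.
#' @param kb A `renal_kb` object (defaults to the bundled KB).
#' @return Character vector of stage labels, same length as `gfr`.
#' @examples
#' classify_ckd_stage(c(95, 75, 14.9, 90))
#' @export
classify_ckd_stage <- function(gfr, kb = load_knowledge_base()) {
  if (length(gfr) == 0) return(character())
  if (any(!is.finite(gfr)) || any(gfr <= 0)) {
    abort("`gfr` must be positive and finite")
  }
  s <- dplyr::arrange(kb$staging_rules, .data$lower)
  breaks <- c(s$lower, Inf)
  as.character(cut(gfr, breaks = breaks, labels = s$stage, right = FALSE))
}

#' Classify diabetes status from HbA1c
#'
#' Applies the diagnostic thresholds: HbA1c below 5.7% is Normal, 5.7% up to
#' (but not including) 6.4% is Prediabetes, 6.4% and above is Diabetes.
#' Missing values map to "Unknown" rather than raising, since absence of a
#' lab result is expected in cohort data.
#'
#' @param hba1c Numeric vector of HbA1c values (percent); non-missing values
#'   must lie in (3, 20).
#' @param kb A `renal_kb` object supplying the thresholds.
#' @return Character vector: "Normal", "Prediabetes", "Diabetes" or "Unknown".
#' @examples
#' classify_t2dm_status(c(5.0, 6.0, 7.0, 5.7, NA))
#' @export
classify_t2dm_status <- function(hba1c, kb = load_knowledge_base()) {
  th <- kb$hba1c_thresholds
  ok <- is.na(hba1c) | (hba1c > 3 & hba1c < 20)
  if (!all(ok)) {
    abort("`hba1c` outside the plausible (3, 20) percent range")
  }
  dplyr::case_when(
    is.na(hba1c) ~ "Unknown",
    hba1c < th$normal_upper ~ "Normal",
    hba1c < th$diabetes_lower ~ "Prediabetes",
    TRUE ~ "Diabetes"
  )
}

#' Dose band for an eGFR value
#'
#' Maps eGFR to the three renal dosing bands: `low` `[0, 10)`, `mid`
#' `[10, 50]`, `high` `(50, Inf)` mL/min.
#'
#' @inheritParams classify_ckd_stage
#' @return Character vector of band labels ("high", "mid", "low").
#' @examples
#' gfr_band(c(80, 30, 5, 50, 10))
#' @export
gfr_band <- function(gfr, kb = load_knowledge_base()) {
  if (length(gfr) == 0) return(character())
  if (any(!is.finite(gfr)) || any(gfr < 0)) {
    abort("`gfr` must be non-negative and finite")
  }
  b <- kb$gfr_bands
  out <- rep(NA_character_, length(gfr))
  for (i in seq_len(nrow(b))) {
    lo_ok <- if (b$lower_closed[i]) gfr >= b$lower[i] else gfr > b$lower[i]
    hi_ok <- if (b$upper_closed[i]) gfr <= b$upper[i] else gfr < b$upper[i]
    out[lo_ok & hi_ok] <- b$label[i]
  }
  out
}
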