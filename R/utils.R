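# internal helpers shared across modules

# format a dose amount for labels: drop trailing zeros, keep up to 2 decimals
fmt_mg <- function(x) {
  x <- round(x, 2)
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 2))
}

# frequency codes as used in dose-individual labels
.freq_label <- c(
  "q24h" = "q24hr", "b.i.d" = "bid", "t.i.d" = "tid",
  "per-day" = "day", "variable" = "variable"
)

freq_label <- function(freq) {
  out <- unname(.freq_label[freq])
  out[is.na(out)] <- "variable"
  out
}

# one row of the unified report-item schema; every recommendation and
# warning across all rule families lands in this shape
item_row <- function(item_type, record, kind, drug,
                     drug2 = NA_character_, band = NA_character_,
                     fraction_lo = NA_real_, fraction_hi = NA_real_,
                     reduce_pct = NA_real_,
                     start_lo_mg = NA_real_, start_hi_mg = NA_real_,
                     dose_lo_mg = NA_real_, dose_hi_mg = NA_real_,
                     dose_label = NA_character_, rule_id = NA_character_,
                     message = NA_character_) {
  tibble(
    item_type = item_type, record = record, kind = kind,
    drug = drug, drug2 = drug2, band = band,
    fraction_lo = fraction_lo, fraction_hi = fraction_hi,
    reduce_pct = reduce_pct,
    start_lo_mg = start_lo_mg, start_hi_mg = start_hi_mg,
    dose_lo_mg = dose_lo_mg, dose_hi_mg = dose_hi_mg,
    dose_label = dose_label, rule_id = rule_id, message = message
  )
}

empty_items <- function() item_row(character(), character(), character(), character())

# canonical ordering for report items: by item family, then drug names, rule id
arrange_items <- function(items) {
  items |>
    dplyr::arrange(
      match(.data$item_type, .item_type_levels),
      .data$drug, .data$drug2, .data$rule_id
    )
}

# stable item identifier used to key rater panels to report items
make_item_id <- function(patient_id, item_type, drug, drug2) {
  paste0(
    patient_id, ":", item_type, ":", drug,
    ifelse(is.na(drug2) | drug2 == "", "", paste0("+", drug2))
  )
}

# normalize a profile argument (1-row data frame or named list) to a list
as_profile <- function(p) {
  if (is.data.frame(p)) {
    if (nrow(p) != 1) abort("`profile` must be a single patient (one row)")
    p <- as.list(p)
  }
  if (!is.list(p)) abort("`profile` must be a one-row data frame or named list")
  p$prescription_drugs <- parse_prescription(p$prescription %||% NA_character_)[[1]]
  p
}

yes_no <- function(x) {
  x <- x %||% NA_character_
  if (length(x) == 0 || is.na(x)) return(NA_character_)
  as.character(x)
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
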