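#' Drug-drug interaction warnings for a prescription
#'
#' Checks every unordered pair of prescribed drugs against the closed
#' (symmetric) interaction relation. In the bundled KB this relation is
#' exactly {ACE inhibitors x ARA} plus {Beta blockers x {Diltiazem,
#' Verapamil}}: an ACE inhibitor must not be co-prescribed with an
#' angiotensin receptor antagonist, and Diltiazem or Verapamil must not be
#' co-prescribed with any beta blocker. The result is independent of the
#' order in which prescription drugs are listed; each interacting pair is
#' reported once, drugs in sorted order.
#'
#' Drugs unknown to the KB are skipped with a message (profile validation
#' reports them; a warning engine should not fail an entire report over one
#' unrecognized name).
#'
#' @param prescription Character vector of drug names, or a single
#'   semicolon-delimited string.
#' @param kb A `renal_kb` object.
#' @return Tibble of report items (`item_type = "ddi"`), one row per
#'   interacting pair present, with `drug` < `drug2`.
#' @examples
#' kb <- load_knowledge_base()
#' ddi_warnings(c("Candesartan", "Benazepril"), kb)
#' @export
ddi_warnings <- function(prescription, kb = load_knowledge_base()) {
  rx <- normalize_prescription(prescription)
  unknown <- setdiff(rx, kb$drugs$drug)
  if (length(unknown) > 0) {
    message("skipping unknown prescription drug(s): ",
            paste(unknown, collapse = ", "))
    rx <- setdiff(rx, unknown)
  }
  if (length(rx) < 2 || nrow(kb$ddi_pairs) == 0) return(empty_items())
  pairs <- t(combn(sort(rx), 2))
  hits <- tibble(drug1 = pairs[, 1], drug2 = pairs[, 2]) |>
    dplyr::inner_join(kb$ddi_pairs, by = c("drug1", "drug2"))
  if (nrow(hits) == 0) return(empty_items())
  purrr::pmap_dfr(hits, function(drug1, drug2, rule_id) {
    item_row(
      item_type = "ddi", record = "warning", kind = "ddi",
      drug = drug1, drug2 = drug2, rule_id = rule_id,
      message = paste0("drug-drug interaction: ", drug1, " must not be used ",
                       "together with ", drug2)
    )
  }) |>
    arrange_items()
}

#' Potassium-increase warnings for a prescription
#'
#' One warning per prescribed drug covered by a potassium rule. The bundled
#' KB carries four rules: the ACE-inhibitor class, the ARA class, the
#' beta-blocker class, and Spironolactone, all of which raise serum
#' potassium and can precipitate hyperkalemia in renal impairment.
#'
#' @inheritParams ddi_warnings
#' @return Tibble of report items (`item_type = "k_raising"`), one row per
#'   matched drug.
#' @examples
#' kb <- load_knowledge_base()
#' k_raising_warnings(c("Ramipril", "Amlodipine"), kb)
#' @export
k_raising_warnings <- function(prescription, kb = load_knowledge_base()) {
  rx <- normalize_prescription(prescription)
  unknown <- setdiff(rx, kb$drugs$drug)
  if (length(unknown) > 0) {
    message("skipping unknown prescription drug(s): ",
            paste(unknown, collapse = ", "))
    rx <- setdiff(rx, unknown)
  }
  if (length(rx) == 0 || nrow(kb$k_raising_rules) == 0) return(empty_items())

  drug_rules <- kb$k_raising_rules |> dplyr::filter(.data$scope_type == "drug")
  class_rules <- kb$k_raising_rules |> dplyr::filter(.data$scope_type == "class")

  hits <- purrr::map_dfr(sort(rx), function(d) {
    rid <- if (d %in% drug_rules$scope) {
      drug_rules$rule_id[match(d, drug_rules$scope)]
    } else {
      cl <- kb$drugs$class[match(d, kb$drugs$drug)]
      if (cl %in% class_rules$scope) {
        class_rules$rule_id[match(cl, class_rules$scope)]
      } else {
        NA_character_
      }
    }
    if (is.na(rid)) return(empty_items())
    item_row(
      item_type = "k_raising", record = "warning", kind = "k_raising",
      drug = d, rule_id = rid,
      message = paste0(d, " raises serum potassium levels")
    )
  })
  arrange_items(hits)
}

normalize_prescription <- function(prescription) {
  if (length(prescription) == 1 && grepl(";", prescription %||% "")) {
    prescription <- parse_prescription(prescription)[[1]]
  }
  unique(prescription[!is.na(prescription) & prescription != ""])
}
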