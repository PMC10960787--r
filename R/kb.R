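#' Load the clinical knowledge base
#'
#' Reads the declarative knowledge base (drug classes, GFR-banded dose tables,
#' drug-drug interaction sets, potassium-raising rules, CKD staging thresholds
#' and HbA1c diagnostic thresholds) from a YAML file. The bundled default
#' covers seven CKD/T2DM drug classes and every drug, dose and rule the engine
#' knows about; users may point `path` at an extended file with the same
#' schema to add drugs without code changes.
#'
#' Interval conventions: staging rules are half-open `[lower, upper)` and the
#' six stages partition `[0, Inf)`; dose bands are `low [0,10)`, `mid [10,50]`
#' and `high (50, Inf)` mL/min, so every positive eGFR falls in exactly one
#' stage and one band.
#'
#' @param path Path to a KB YAML file. `NULL` (default) loads the bundled KB.
#' @return An object of class `renal_kb`: a list of tibbles
#'   (`drugs`, `classes`, `dose_entries`, `interaction_rules`, `ddi_pairs`,
#'   `k_raising_rules`, `staging_rules`, `gfr_bands`, `t2dm_dose_rules`)
#'   plus `hba1c_thresholds` and a `version` tag.
#' @examples
#' kb <- load_knowledge_base()
#' rule_counts(kb)
#' @export
load_knowledge_base <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kb.yaml", package = "renalrx")
  }
  if (!file.exists(path)) abort(paste0("KB file not found: ", path))
  raw <- yaml::read_yaml(path)

  need <- c(
    "version", "hba1c_thresholds", "gfr_bands", "staging_rules",
    "drug_classes", "dose_entries", "interaction_rules",
    "k_raising_rules", "t2dm_dose_rules"
  )
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("KB schema error: missing top-level field(s): ",
                 paste(missing, collapse = ", ")))
  }

  classes <- purrr::map_dfr(raw$drug_classes, function(cl) {
    if (is.null(cl$name) || is.null(cl$members) || length(cl$members) == 0) {
      abort(paste0("KB schema error in drug_classes record: ",
                   cl$name %||% "<unnamed>"))
    }
    tibble(class = cl$name, k_raising = isTRUE(cl$k_raising),
           n_members = length(cl$members))
  })
  drugs <- purrr::map_dfr(raw$drug_classes, function(cl) {
    tibble(drug = as.character(cl$members), class = cl$name,
           k_raising = isTRUE(cl$k_raising))
  })

  parse_dose_text <- function(d) {
    if (is.null(d)) {
      return(tibble(text = NA_character_, lo_mg = NA_real_, hi_mg = NA_real_,
                    freq = NA_character_))
    }
    tibble(
      text = d$text %||% NA_character_,
      lo_mg = as.numeric(d$lo_mg %||% NA),
      hi_mg = as.numeric(d$hi_mg %||% NA),
      freq = d$freq %||% NA_character_
    )
  }
  parse_adj <- function(a, drug, band) {
    if (is.null(a$kind)) {
      abort(paste0("KB schema error: dose entry for ", drug,
                   " band ", band, " lacks `kind`"))
    }
    tibble(
      band = band, kind = a$kind,
      lo_pct = as.numeric(a$lo_pct %||% NA),
      hi_pct = as.numeric(a$hi_pct %||% NA),
      abs_text = a$text %||% NA_character_,
      abs_lo_mg = as.numeric(a$lo_mg %||% NA),
      abs_hi_mg = as.numeric(a$hi_mg %||% NA),
      abs_label = a$label %||% NA_character_
    )
  }

  dose_entries <- purrr::map_dfr(raw$dose_entries, function(e) {
    if (is.null(e$drug) || is.null(e$class) || is.null(e$bands)) {
      abort(paste0("KB schema error in dose_entries record: ",
                   e$drug %||% "<unnamed>"))
    }
    start <- parse_dose_text(e$starting_dose)
    maxd <- parse_dose_text(e$maximum_dose)
    bands <- purrr::imap_dfr(e$bands, function(a, b) parse_adj(a, e$drug, b))
    dplyr::bind_cols(
      tibble(drug = e$drug, class = e$class,
             start_text = start$text, start_lo_mg = start$lo_mg,
             start_hi_mg = start$hi_mg, start_freq = start$freq,
             max_text = maxd$text, max_lo_mg = maxd$lo_mg,
             max_hi_mg = maxd$hi_mg, max_freq = maxd$freq)[rep(1, nrow(bands)), ],
      bands
    )
  })

  interaction_rules <- purrr::map_dfr(raw$interaction_rules, function(r) {
    if (is.null(r$rule_id) || is.null(r$subject) || length(r$interacts_with) == 0) {
      abort(paste0("KB schema error in interaction_rules record: ",
                   r$rule_id %||% "<unnamed>"))
    }
    tibble(rule_id = r$rule_id, subject = r$subject,
           interacts_with = list(as.character(r$interacts_with)))
  })

  k_raising_rules <- purrr::map_dfr(raw$k_raising_rules, function(r) {
    scope_type <- if (!is.null(r$scope_drug)) "drug" else "class"
    scope <- r$scope_drug %||% r$scope_class
    if (is.null(r$rule_id) || is.null(scope)) {
      abort(paste0("KB schema error in k_raising_rules record: ",
                   r$rule_id %||% "<unnamed>"))
    }
    tibble(rule_id = r$rule_id, scope_type = scope_type, scope = scope)
  })

  staging_rules <- purrr::map_dfr(raw$staging_rules, function(r) {
    tibble(stage = r$stage, lower = as.numeric(r$lower),
           upper = as.numeric(r$upper),
           rule_id = paste0("stage_", r$stage))
  })

  gfr_bands <- purrr::map_dfr(raw$gfr_bands, function(b) {
    tibble(label = b$label, lower = as.numeric(b$lower),
           lower_closed = isTRUE(b$lower_closed),
           upper = as.numeric(b$upper),
           upper_closed = isTRUE(b$upper_closed))
  })

  t2dm_dose_rules <- purrr::map_dfr(raw$t2dm_dose_rules, function(r) {
    tibble(rule_id = r$rule_id, drug = r$drug, band = r$band,
           reduce_pct = as.numeric(r$reduce_pct))
  })

  kb <- structure(
    list(
      version = as.character(raw$version),
      hba1c_thresholds = list(
        normal_upper = as.numeric(raw$hba1c_thresholds$normal_upper),
        diabetes_lower = as.numeric(raw$hba1c_thresholds$diabetes_lower)
      ),
      drugs = drugs,
      classes = classes,
      dose_entries = dose_entries,
      interaction_rules = interaction_rules,
      k_raising_rules = k_raising_rules,
      staging_rules = staging_rules,
      gfr_bands = gfr_bands,
      t2dm_dose_rules = t2dm_dose_rules
    ),
    class = "renal_kb"
  )
  kb$ddi_pairs <- ddi_pair_closure(kb)

  violations <- validate_knowledge_base(kb)
  if (nrow(violations) > 0) {
    abort(paste0(
      "KB integrity error (", nrow(violations), " violation(s)); first: ",
      violations$message[1]
    ))
  }
  kb
}

# symmetric closure of the stored one-sided interaction rules, as a canonical
# unordered pair table (drug1 < drug2 lexicographically)
ddi_pair_closure <- function(kb) {
  if (nrow(kb$interaction_rules) == 0) {
    return(tibble(drug1 = character(), drug2 = character(),
                  rule_id = character()))
  }
  kb$interaction_rules |>
    tidyr::unnest(cols = "interacts_with") |>
    dplyr::transmute(
      drug1 = pmin(.data$subject, .data$interacts_with),
      drug2 = pmax(.data$subject, .data$interacts_with),
      rule_id = .data$rule_id
    ) |>
    dplyr::distinct(.data$drug1, .data$drug2, .keep_all = TRUE) |>
    dplyr::arrange(.data$drug1, .data$drug2)
}

#' Validate a knowledge base
#'
#' Runs referential-integrity and consistency checks: unique class names,
#' non-empty classes, single class membership per drug, complete band
#' coverage of dose entries, fraction ranges in (0, 100], interaction rules
#' referencing known drugs with class-complete and mutually symmetric
#' interaction sets, staging rules and GFR bands partitioning the positive
#' eGFR axis, and potassium-rule scopes resolving to known drugs or classes.
#'
#' Violations are returned as data, not raised, so defective KBs can be
#' inspected; [load_knowledge_base()] refuses to return a KB with violations.
#'
#' @param kb A `renal_kb` object.
#' @return A tibble with columns `category`, `record`, `message`; zero rows
#'   for a valid KB.
#' @export
validate_knowledge_base <- function(kb) {
  v <- list()
  bad <- function(category, record, message) {
    tibble(category = category, record = record, message = message)
  }

  dup_class <- kb$classes$class[duplicated(kb$classes$class)]
  for (d in dup_class) v <- c(v, list(bad("classes", d, paste0("duplicate class name: ", d))))

  dup_drug <- unique(kb$drugs$drug[duplicated(kb$drugs$drug)])
  for (d in dup_drug) {
    v <- c(v, list(bad("classes", d,
                       paste0("duplicate class membership for drug: ", d))))
  }
  known <- unique(kb$drugs$drug)

  # dose entries: known drug/class, all three bands, sane payloads
  if (nrow(kb$dose_entries) > 0) {
    per_drug <- kb$dose_entries |>
      dplyr::group_by(.data$drug) |>
      dplyr::summarise(bands = list(sort(.data$band)), .groups = "drop")
    for (i in seq_len(nrow(per_drug))) {
      if (!identical(per_drug$bands[[i]], c("high", "low", "mid"))) {
        v <- c(v, list(bad("dose", per_drug$drug[i],
                           paste0("dose entry for ", per_drug$drug[i],
                                  " does not cover bands high/mid/low"))))
      }
    }
    for (i in seq_len(nrow(kb$dose_entries))) {
      row <- kb$dose_entries[i, ]
      if (!row$drug %in% known) {
        v <- c(v, list(bad("dose", row$drug,
                           paste0("dose entry for unknown drug: ", row$drug))))
      }
      if (!row$kind %in% c("fraction", "absolute", "avoid", "no_data")) {
        v <- c(v, list(bad("dose", row$drug,
                           paste0("invalid adjustment kind '", row$kind,
                                  "' for ", row$drug))))
      }
      if (row$kind == "fraction") {
        if (is.na(row$lo_pct) || is.na(row$hi_pct) ||
            row$lo_pct <= 0 || row$hi_pct > 100 || row$lo_pct > row$hi_pct) {
          v <- c(v, list(bad("dose", row$drug,
                             paste0("fraction out of (0,100] or inverted range for ",
                                    row$drug, " band ", row$band))))
        }
      }
    }
    # fraction adjustments must be non-increasing from high to low band
    # (avoid counts as 0, no_data is skipped)
    mono <- kb$dose_entries |>
      dplyr::filter(.data$kind %in% c("fraction", "avoid")) |>
      dplyr::mutate(value = ifelse(.data$kind == "avoid", 0, .data$hi_pct),
                    ord = match(.data$band, .band_levels)) |>
      dplyr::arrange(.data$drug, .data$ord) |>
      dplyr::group_by(.data$drug) |>
      dplyr::summarise(ok = !is.unsorted(rev(.data$value)), .groups = "drop")
    for (d in mono$drug[!mono$ok]) {
      v <- c(v, list(bad("dose", d,
                         paste0("band adjustments increase toward lower GFR for ", d))))
    }
  }

  # interaction rules: integrity, class coverage, cross-rule symmetry
  if (nrow(kb$interaction_rules) > 0) {
    for (i in seq_len(nrow(kb$interaction_rules))) {
      r <- kb$interaction_rules[i, ]
      targets <- r$interacts_with[[1]]
      if (!r$subject %in% known) {
        v <- c(v, list(bad("ddi", r$rule_id,
                           paste0("interaction subject unknown: ", r$subject))))
      }
      unknown_t <- setdiff(targets, known)
      for (u in unknown_t) {
        v <- c(v, list(bad("ddi", r$rule_id,
                           paste0("interaction target unknown: ", u))))
      }
      if (r$subject %in% targets) {
        v <- c(v, list(bad("ddi", r$rule_id,
                           paste0("drug listed as interacting with itself: ",
                                  r$subject))))
      }
      # class coverage: touching one member of a class implies the whole class
      tcl <- kb$drugs |> dplyr::filter(.data$drug %in% targets)
      for (cl in unique(tcl$class)) {
        members <- kb$drugs$drug[kb$drugs$class == cl]
        left_out <- setdiff(members, c(targets, r$subject))
        if (length(left_out) > 0) {
          v <- c(v, list(bad("ddi", r$rule_id,
                             paste0("asymmetric closure: rule ", r$rule_id,
                                    " covers class '", cl, "' but omits: ",
                                    paste(left_out, collapse = ", ")))))
        }
      }
    }
    # subjects with rules must list each other consistently
    subs <- kb$interaction_rules$subject
    for (i in seq_len(nrow(kb$interaction_rules))) {
      r <- kb$interaction_rules[i, ]
      for (s2 in intersect(r$interacts_with[[1]], subs)) {
        other <- kb$interaction_rules$interacts_with[[match(s2, subs)]]
        if (!r$subject %in% other) {
          v <- c(v, list(bad("ddi", r$rule_id,
                             paste0("asymmetric closure: ", s2, " does not list ",
                                    r$subject, " back"))))
        }
      }
    }
  }

  # staging rules partition [0, Inf)
  if (nrow(kb$staging_rules) > 0) {
    s <- dplyr::arrange(kb$staging_rules, .data$lower)
    if (s$lower[1] != 0 || !is.infinite(s$upper[nrow(s)]) ||
        (nrow(s) > 1 && any(s$upper[-nrow(s)] != s$lower[-1]))) {
      v <- c(v, list(bad("staging", "staging_rules",
                         "staging intervals do not partition [0, Inf)")))
    }
    if (is.unsorted(rev(match(s$stage, .stage_levels)))) {
      v <- c(v, list(bad("staging", "staging_rules",
                         "stage order is not monotone decreasing in eGFR")))
    }
  }

  # GFR bands partition [0, Inf): sorted by lower, bounds must meet with
  # exactly one closed side at each interior boundary
  if (nrow(kb$gfr_bands) > 0) {
    b <- dplyr::arrange(kb$gfr_bands, .data$lower)
    ok <- b$lower[1] == 0 && b$lower_closed[1] &&
      is.infinite(b$upper[nrow(b)])
    if (nrow(b) > 1) {
      for (i in seq_len(nrow(b) - 1)) {
        ok <- ok && b$upper[i] == b$lower[i + 1] &&
          xor(b$upper_closed[i], b$lower_closed[i + 1])
      }
    }
    if (!ok) {
      v <- c(v, list(bad("bands", "gfr_bands",
                         "GFR bands do not partition [0, Inf)")))
    }
  }

  if (nrow(kb$k_raising_rules) > 0) {
    for (i in seq_len(nrow(kb$k_raising_rules))) {
      r <- kb$k_raising_rules[i, ]
      pool <- if (r$scope_type == "drug") known else unique(kb$drugs$class)
      if (!r$scope %in% pool) {
        v <- c(v, list(bad("k_raising", r$rule_id,
                           paste0("potassium rule scope unknown: ", r$scope))))
      }
    }
  }

  if (nrow(kb$t2dm_dose_rules) > 0) {
    for (i in seq_len(nrow(kb$t2dm_dose_rules))) {
      r <- kb$t2dm_dose_rules[i, ]
      if (!r$drug %in% known) {
        v <- c(v, list(bad("t2dm_dose", r$rule_id,
                           paste0("T2DM dose rule for unknown drug: ", r$drug))))
      }
      if (!r$band %in% kb$gfr_bands$label) {
        v <- c(v, list(bad("t2dm_dose", r$rule_id,
                           paste0("T2DM dose rule with unknown band: ", r$band))))
      }
      if (is.na(r$reduce_pct) || r$reduce_pct <= 0 || r$reduce_pct >= 100) {
        v <- c(v, list(bad("t2dm_dose", r$rule_id,
                           "T2DM dose reduction outside (0, 100)")))
      }
    }
  }

  th <- kb$hba1c_thresholds
  if (!is.numeric(th$normal_upper) || !is.numeric(th$diabetes_lower) ||
      th$normal_upper >= th$diabetes_lower) {
    v <- c(v, list(bad("thresholds", "hba1c_thresholds",
                       "HbA1c thresholds inconsistent (normal_upper >= diabetes_lower)")))
  }

  if (length(v) == 0) {
    tibble(category = character(), record = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Rule counts per category
#'
#' @param kb A `renal_kb` object.
#' @return A tibble with columns `category` and `n`, one row per rule family:
#'   `staging`, `ddi`, `dose`, `k_raising`, `t2dm_dose`. The dose count is the
#'   number of drugs with a GFR-banded dose entry; the ddi count is the number
#'   of stored one-sided interaction rules.
#' @export
rule_counts <- function(kb) {
  tibble(
    category = c("staging", "ddi", "dose", "k_raising", "t2dm_dose"),
    n = c(
      nrow(kb$staging_rules),
      nrow(kb$interaction_rules),
      length(unique(kb$dose_entries$drug)),
      nrow(kb$k_raising_rules),
      nrow(kb$t2dm_dose_rules)
    )
  )
}

#' Drugs that carry a potassium-increase warning
#'
#' Resolves the potassium rules' scopes (whole classes or single drugs) to the
#' flat set of drug names they cover.
#'
#' @param kb A `renal_kb` object.
#' @return Character vector of drug names, sorted.
#' @export
k_raising_drugs <- function(kb) {
  if (nrow(kb$k_raising_rules) == 0) return(character())
  by_class <- kb$k_raising_rules |>
    dplyr::filter(.data$scope_type == "class")
  by_drug <- kb$k_raising_rules |>
    dplyr::filter(.data$scope_type == "drug")
  sort(unique(c(
    kb$drugs$drug[kb$drugs$class %in% by_class$scope],
    by_drug$scope
  )))
}

#' @export
print.renal_kb <- function(x, ...) {
  cat("<renal_kb> version", x$version, "\n")
  cat("  drug classes :", nrow(x$classes), "(",
      sum(x$classes$k_raising), "potassium-raising )\n")
  cat("  drugs        :", nrow(x$drugs), "\n")
  cat("  dose entries :", length(unique(x$dose_entries$drug)), "\n")
  cat("  ddi pairs    :", nrow(x$ddi_pairs), "(closed from",
      nrow(x$interaction_rules), "stored rules)\n")
  counts <- rule_counts(x)
  cat("  rules        :", paste(counts$category, counts$n, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}
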