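#' RDF namespace configuration
#'
#' The export vocabulary lives under a single configurable base IRI with
#' three prefixes: `kb:` (vocabulary - classes, predicates, stages), `pt:`
#' (patient individuals) and `drug:` (drug and dose individuals), plus the
#' standard `rdf:` prefix.
#'
#' @param base Base IRI; prefixed namespaces are derived from it.
#' @return Named character vector of prefix -> namespace IRI.
#' @export
rdf_namespaces <- function(base = "http://example.org/renalrx/") {
  c(
    kb = paste0(base, "vocab#"),
    pt = paste0(base, "patient#"),
    drug = paste0(base, "drug#"),
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  )
}

rdf_local <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

triple <- function(subject, predicate, object, literal = FALSE) {
  tibble(subject = subject, predicate = predicate, object = object,
         literal = literal)
}

empty_triples <- function() triple(character(), character(), character(),
                                   logical())

expand_curie <- function(x, ns) {
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", x))
  vapply(seq_along(x), function(i) {
    parts <- m[[i]]
    if (length(parts) == 3 && parts[2] %in% names(ns)) {
      paste0(ns[[parts[2]]], parts[3])
    } else {
      x[i]
    }
  }, character(1))
}

compact_iri <- function(iri, ns) {
  out <- iri
  for (p in names(ns)) {
    hit <- startsWith(iri, ns[[p]])
    out[hit] <- paste0(p, ":", substring(iri[hit], nchar(ns[[p]]) + 1))
  }
  out
}

#' Map cohort rows to RDF axioms
#'
#' Reproduces the spreadsheet-row-to-axioms pattern: each patient row yields
#' one type assertion (`pt:<id> rdf:type kb:Patient`) plus one property
#' assertion per non-missing mapped column (as a plain literal). Missing
#' values emit nothing.
#'
#' @param cohort Tibble of patients.
#' @param mapping Tibble with columns `column`, `predicate` (CURIEs);
#'   defaults to `kb:<column name>` for every cohort column.
#' @param ns Namespace vector from [rdf_namespaces()].
#' @param strict If `TRUE` (default), a cohort column absent from the mapping
#'   is an error; otherwise unmapped columns are skipped.
#' @return Triples tibble (`subject`, `predicate`, `object`, `literal`).
#' @export
cohort_to_axioms <- function(cohort, mapping = NULL, ns = rdf_namespaces(),
                             strict = TRUE) {
  if (nrow(cohort) == 0) return(empty_triples())
  if (is.null(mapping)) mapping <- default_column_mapping(cohort)
  unmapped <- setdiff(names(cohort), mapping$column)
  if (length(unmapped) > 0) {
    if (strict) {
      abort(paste0("unmapped cohort column(s): ",
                   paste(unmapped, collapse = ", ")))
    }
    cohort <- cohort[setdiff(names(cohort), unmapped)]
  }
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    subj <- paste0("pt:", rdf_local(as.character(row$patient_id)))
    cols <- names(row)[!vapply(row, function(v) is.na(v) | v == "", logical(1))]
    preds <- mapping$predicate[match(cols, mapping$column)]
    dplyr::bind_rows(
      triple(subj, "rdf:type", "kb:Patient"),
      triple(rep(subj, length(cols)), preds,
             unname(vapply(row[cols], as.character, character(1))),
             literal = TRUE)
    )
  })
}

#' @rdname cohort_to_axioms
#' @export
default_column_mapping <- function(cohort) {
  tibble(column = names(cohort),
         predicate = paste0("kb:", rdf_local(names(cohort))))
}

#' Convert a patient report to RDF triples
#'
#' Emits the rule-head assertions of the inference engine in RDF form, using
#' the predicate vocabulary of the rule heads: dose recommendations as
#' `kb:recommendedKidneyDrugDosage` pointing at a dose individual named in
#' the `<Drug>Dose_<amount>_<freq>` style (e.g. `drug:AcarboseDose_50mg_tid`),
#' T2DM reductions as `kb:recommendedDiabetesDrugDosage`, interaction
#' warnings as a symmetric pair of `kb:hasDrugDrugInteractionWarning`
#' triples between the two drug individuals, potassium warnings as
#' `kb:hasPotassiumLevelIncreaseWarning` with literal `"true"`, the stage as
#' `kb:hasCKDStage`, and dose warnings as dedicated warning predicates.
#'
#' @param report A `patient_report` from [generate_report()].
#' @param ns Namespace vector from [rdf_namespaces()].
#' @return Triples tibble.
#' @export
report_to_triples <- function(report, ns = rdf_namespaces()) {
  subj <- paste0("pt:", rdf_local(report$patient_id))
  out <- list(
    triple(subj, "rdf:type", "kb:Patient"),
    triple(subj, "kb:hasCKDStage", paste0("kb:", report$stage))
  )
  if (!identical(report$t2dm_status, "Unknown")) {
    out <- c(out, list(triple(subj, "kb:hasT2DMStatus",
                              paste0("kb:", report$t2dm_status))))
  }
  items <- report$items
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    drug_res <- paste0("drug:", rdf_local(it$drug))
    out <- c(out, list(switch(
      paste(it$item_type, it$kind, sep = "/"),
      "ckd_dose/fraction" = ,
      "ckd_dose/absolute" = triple(
        subj, "kb:recommendedKidneyDrugDosage",
        paste0("drug:", rdf_local(it$drug), "Dose_", rdf_local(it$dose_label))
      ),
      "ckd_dose/contraindicated" = triple(
        subj, "kb:hasContraindicationWarning", drug_res
      ),
      "ckd_dose/no_data" = triple(
        subj, "kb:hasNoDoseDataWarning", drug_res
      ),
      "ckd_dose/dialysis_referral" = triple(
        subj, "kb:hasDialysisReferral", drug_res
      ),
      "t2dm_dose/reduction" = triple(
        subj, "kb:recommendedDiabetesDrugDosage",
        paste0("drug:", rdf_local(it$drug), "_", rdf_local(it$dose_label))
      ),
      "ddi/ddi" = triple(
        c(drug_res, paste0("drug:", rdf_local(it$drug2))),
        "kb:hasDrugDrugInteractionWarning",
        c(paste0("drug:", rdf_local(it$drug2)), drug_res)
      ),
      "k_raising/k_raising" = triple(
        drug_res, "kb:hasPotassiumLevelIncreaseWarning", "true",
        literal = TRUE
      ),
      abort(paste0("no RDF mapping for item kind: ", it$kind))
    )))
  }
  dplyr::bind_rows(out) |> dplyr::distinct()
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Serialize a triple set to a file
#'
#' Supported formats: Turtle (`.ttl`), N-Triples (`.nt`) and RDF/XML
#' (`.rdf`). The output covers the subset the package emits (IRIs and plain
#' literals; no blank nodes) and round-trips exactly through [parse_graph()].
#'
#' @param triples Triples tibble (`subject`, `predicate`, `object`,
#'   `literal`), CURIEs resolvable under `ns`.
#' @param path Output file path.
#' @param format One of `"turtle"`, `"ntriples"`, `"rdfxml"`.
#' @param ns Namespace vector from [rdf_namespaces()].
#' @return `path`, invisibly.
#' @export
serialize_graph <- function(triples, path,
                            format = c("turtle", "ntriples", "rdfxml"),
                            ns = rdf_namespaces()) {
  format <- match.arg(format)
  if (length(ns) == 0 || is.null(names(ns)) || any(names(ns) == "")) {
    abort("degenerate namespace configuration: named prefixes required")
  }
  switch(format,
    ntriples = {
      s <- paste0("<", expand_curie(triples$subject, ns), ">")
      p <- paste0("<", expand_curie(triples$predicate, ns), ">")
      o <- ifelse(triples$literal,
                  paste0("\"", escape_literal(triples$object), "\""),
                  paste0("<", expand_curie(triples$object, ns), ">"))
      writeLines(paste(s, p, o, "."), path, useBytes = TRUE)
    },
    turtle = {
      header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .")
      o <- ifelse(triples$literal,
                  paste0("\"", escape_literal(triples$object), "\""),
                  triples$object)
      body <- paste(triples$subject, triples$predicate, o, ".")
      writeLines(c(header, "", body), path, useBytes = TRUE)
    },
    rdfxml = {
      # built as text over the restricted subset we emit; re-read with xml2
      xml_escape <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        x <- gsub(">", "&gt;", x, fixed = TRUE)
        gsub("\"", "&quot;", x, fixed = TRUE)
      }
      decls <- paste0("xmlns:", names(ns), "=\"", xml_escape(unname(ns)), "\"")
      out <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        paste0("<rdf:RDF ", paste(decls, collapse = " "), ">")
      )
      for (subj in unique(triples$subject)) {
        out <- c(out, paste0(
          "  <rdf:Description rdf:about=\"",
          xml_escape(expand_curie(subj, ns)), "\">"))
        rows <- triples[triples$subject == subj, ]
        for (i in seq_len(nrow(rows))) {
          if (rows$literal[i]) {
            out <- c(out, paste0(
              "    <", rows$predicate[i], ">", xml_escape(rows$object[i]),
              "</", rows$predicate[i], ">"))
          } else {
            out <- c(out, paste0(
              "    <", rows$predicate[i], " rdf:resource=\"",
              xml_escape(expand_curie(rows$object[i], ns)), "\"/>"))
          }
        }
        out <- c(out, "  </rdf:Description>")
      }
      out <- c(out, "</rdf:RDF>")
      writeLines(out, path, useBytes = TRUE)
    }
  )
  invisible(path)
}

#' Parse a serialized graph back to a triple set
#'
#' Inverse of [serialize_graph()] for the subset it writes. IRIs under the
#' configured namespaces come back as CURIEs, so
#' `parse_graph(serialize_graph(g))` equals `g` up to row order.
#'
#' @inheritParams serialize_graph
#' @param path File to parse.
#' @return Triples tibble sorted by subject, predicate, object.
#' @export
parse_graph <- function(path, format = c("turtle", "ntriples", "rdfxml"),
                        ns = rdf_namespaces()) {
  format <- match.arg(format)
  out <- switch(format,
    ntriples = {
      lines <- readLines(path, encoding = "UTF-8")
      lines <- lines[nzchar(trimws(lines))]
      m <- regmatches(lines, regexec(
        "^<([^>]*)> <([^>]*)> (?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\") \\.$",
        lines))
      purrr::map_dfr(seq_along(m), function(i) {
        parts <- m[[i]]
        if (length(parts) != 5) abort("malformed N-Triples line")
        lit <- grepl("\"", lines[i], fixed = TRUE)
        triple(compact_iri(parts[2], ns), compact_iri(parts[3], ns),
               if (lit) unescape_literal(parts[5]) else
                 compact_iri(parts[4], ns),
               literal = lit)
      })
    },
    turtle = {
      lines <- readLines(path, encoding = "UTF-8")
      pfx <- regmatches(lines, regexec(
        "^@prefix ([A-Za-z][A-Za-z0-9]*): <([^>]*)> \\.$", lines))
      ns_file <- ns
      for (parts in pfx) {
        if (length(parts) == 3) ns_file[parts[2]] <- parts[3]
      }
      body <- lines[!grepl("^@prefix", lines) & nzchar(trimws(lines))]
      m <- regmatches(body, regexec(
        "^(\\S+) (\\S+) (?:\"((?:[^\"\\\\]|\\\\.)*)\"|(\\S+)) \\.$", body))
      purrr::map_dfr(seq_along(m), function(i) {
        parts <- m[[i]]
        if (length(parts) != 5) abort("malformed Turtle line")
        lit <- grepl("\"", body[i], fixed = TRUE)
        triple(parts[2], parts[3],
               if (lit) unescape_literal(parts[4]) else parts[5],
               literal = lit)
      })
    },
    rdfxml = {
      doc <- xml2::read_xml(path)
      ns_doc <- xml2::xml_ns(doc)
      descs <- xml2::xml_find_all(
        doc, ".//*[local-name() = 'Description']")
      purrr::map_dfr(descs, function(d) {
        subj <- xml2::xml_attr(d, "about")
        kids <- xml2::xml_children(d)
        purrr::map_dfr(kids, function(k) {
          pred <- xml2::xml_name(k, ns = ns_doc)
          pred_iri <- expand_xml_name(pred, ns_doc)
          res <- xml2::xml_attr(k, "resource")
          if (!is.na(res)) {
            triple(compact_iri(subj, ns), compact_iri(pred_iri, ns),
                   compact_iri(res, ns))
          } else {
            triple(compact_iri(subj, ns), compact_iri(pred_iri, ns),
                   xml2::xml_text(k), literal = TRUE)
          }
        })
      })
    }
  )
  if (nrow(out) == 0) return(empty_triples())
  dplyr::arrange(out, .data$subject, .data$predicate, .data$object)
}

# resolve an xml2 "prefix:local" name against the document namespace map
expand_xml_name <- function(name, ns_doc) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% names(ns_doc)) {
    paste0(ns_doc[[parts[1]]], parts[2])
  } else {
    name
  }
}
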