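rdf_report <- function() {
  generate_report(list(
    patient_id = "M001", gfr = 32, hba1c = 7.2,
    has_ckd = "Yes", has_t2dm = "Yes", has_dialysis = "No",
    prescription = "Acarbose;Candesartan;Ramipril"
  ), KB)
}

test_that("each cohort row yields one type triple plus one per non-missing column", {
  cohort <- generate_cohort(cohort_config(n = 3, seed = 19), KB)
  triples <- cohort_to_axioms(cohort)
  # 41 columns, none missing in a generated cohort: 42 axioms per patient
  expect_equal(nrow(triples), 3 * 42)
  p1 <- triples[triples$subject == "pt:P001", ]
  expect_equal(sum(p1$predicate == "rdf:type" & p1$object == "kb:Patient"), 1)
  expect_equal(sum(!p1$literal), 1)
  # missing cells emit nothing
  cohort$hba1c[1] <- NA
  expect_equal(nrow(cohort_to_axioms(cohort)), 3 * 42 - 1)
  # zero rows map to zero triples; unmapped columns error in strict mode
  expect_equal(nrow(cohort_to_axioms(cohort[0, ])), 0)
  expect_error(cohort_to_axioms(cohort, mapping = default_column_mapping(
    cohort[, 1:5])), "unmapped")
})

test_that("report triples use the rule-head predicate vocabulary", {
  triples <- report_to_triples(rdf_report())
  expect_true(any(triples$predicate == "kb:hasCKDStage" &
                    triples$object == "kb:G3b"))
  expect_true(any(triples$predicate == "kb:recommendedKidneyDrugDosage" &
                    triples$object == "drug:AcarboseDose_50mg_tid"))
  expect_true(any(triples$predicate == "kb:recommendedDiabetesDrugDosage"))
  k <- triples[triples$predicate == "kb:hasPotassiumLevelIncreaseWarning", ]
  expect_equal(nrow(k), 2)
  expect_true(all(k$object == "true" & k$literal))
})

test_that("interaction warnings serialize as a symmetric pair of triples", {
  triples <- report_to_triples(rdf_report())
  ddi <- triples[triples$predicate == "kb:hasDrugDrugInteractionWarning", ]
  expect_equal(nrow(ddi), 2)
  expect_setequal(ddi$subject, c("drug:Candesartan", "drug:Ramipril"))
  expect_equal(sort(ddi$subject), sort(ddi$object))
})

test_that("all three serialization formats round-trip losslessly", {
  cohort <- generate_cohort(cohort_config(n = 2, seed = 29), KB)
  triples <- dplyr::distinct(dplyr::bind_rows(
    cohort_to_axioms(cohort),
    report_to_triples(rdf_report())
  ))
  canon <- dplyr::arrange(triples, subject, predicate, object)
  for (fmt in c("turtle", "ntriples", "rdfxml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    serialize_graph(triples, path, format = fmt)
    back <- parse_graph(path, format = fmt)
    expect_identical(back, canon, label = paste("round-trip", fmt))
  }
})

test_that("N-Triples output has exactly one line per triple, fully expanded", {
  triples <- report_to_triples(rdf_report())
  path <- withr::local_tempfile(fileext = ".nt")
  serialize_graph(triples, path, format = "ntriples")
  lines <- readLines(path)
  expect_equal(length(lines), nrow(triples))
  expect_true(all(grepl("^<http://", lines)))
  expect_true(all(grepl(" \\.$", lines)))
})

test_that("literals with quotes and backslashes survive serialization", {
  tricky <- dplyr::bind_rows(
    renalrx:::triple("pt:X", "kb:note", 'say "hi" \\ twice', literal = TRUE),
    renalrx:::triple("pt:X", "rdf:type", "kb:Patient")
  )
  for (fmt in c("turtle", "ntriples", "rdfxml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    serialize_graph(tricky, path, format = fmt)
    back <- parse_graph(path, format = fmt)
    expect_true('say "hi" \\ twice' %in% back$object, label = fmt)
  }
})

test_that("an independent RDF stack parses all three formats as the same graph", {
  cohort <- generate_cohort(cohort_config(n = 2, seed = 37), KB)
  triples <- dplyr::distinct(dplyr::bind_rows(
    cohort_to_axioms(cohort), report_to_triples(rdf_report())
  ))
  ttl <- withr::local_tempfile(fileext = ".ttl")
  nt <- withr::local_tempfile(fileext = ".nt")
  xml <- withr::local_tempfile(fileext = ".rdf")
  serialize_graph(triples, ttl, format = "turtle")
  serialize_graph(triples, nt, format = "ntriples")
  serialize_graph(triples, xml, format = "rdfxml")

  py <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdflib import Graph",
    "from rdflib.compare import isomorphic",
    "g1 = Graph(); g1.parse(sys.argv[1], format='turtle')",
    "g2 = Graph(); g2.parse(sys.argv[2], format='nt')",
    "g3 = Graph(); g3.parse(sys.argv[3], format='xml')",
    "print(len(g1), isomorphic(g1, g2), isomorphic(g1, g3))"
  ), py)
  out <- system2("python", c(py, ttl, nt, xml), stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), paste(nrow(triples), "True True"))
})
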