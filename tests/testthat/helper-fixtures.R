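# shared fixtures: the bundled KB is immutable within a test run
KB <- load_knowledge_base()

# a non-dialysis CKD + T2DM patient used across inference tests
ckd_t2dm_profile <- function(gfr = 30, prescription = "", ...) {
  utils::modifyList(
    list(
      patient_id = "M001", gfr = gfr, hba1c = 7.2,
      has_ckd = "Yes", has_t2dm = "Yes", has_dialysis = "No",
      prescription = prescription
    ),
    list(...)
  )
}

# independent staging oracle: literal interval membership, written without
# reference to classify_ckd_stage's cut() implementation
stage_oracle <- function(gfr) {
  ifelse(gfr >= 90, "G1",
  ifelse(gfr >= 60, "G2",
  ifelse(gfr >= 45, "G3a",
  ifelse(gfr >= 30, "G3b",
  ifelse(gfr >= 15, "G4", "G5")))))
}

# independent interaction oracle: class-product relation built directly from
# class membership, not from the KB's stored interaction rules
ddi_oracle_pairs <- function(kb) {
  cls <- function(name) kb$drugs$drug[kb$drugs$class == name]
  ace <- cls("ACE inhibitors")
  ara <- cls("ARA")
  bb <- cls("Beta blockers")
  fam1 <- expand.grid(a = ace, b = ara, stringsAsFactors = FALSE)
  fam2 <- expand.grid(a = bb, b = c("Diltiazem", "Verapamil"),
                      stringsAsFactors = FALSE)
  both <- rbind(fam1, fam2)
  sort(paste(pmin(both$a, both$b), pmax(both$a, both$b), sep = "+"))
}
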