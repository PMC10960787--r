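Package: renalrx
Title: Rule-Based Prescription Decision Support for Diabetic Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative clinical knowledge base and deterministic rule
    engine for medication safety in patients with type 2 diabetes mellitus
    (T2DM) and chronic kidney disease (CKD). Classifies CKD stage (G1-G5)
    from estimated glomerular filtration rate (eGFR), adjusts drug doses by
    GFR band, emits drug-drug interaction warnings (ACE inhibitor x
    angiotensin receptor antagonist; beta blocker x Diltiazem/Verapamil) and
    potassium-raising drug warnings, and scores recommendations against
    multi-rater ground truth with accuracy, sensitivity, specificity,
    precision and mean squared error. Includes a synthetic cohort generator,
    a rater-panel simulator, and RDF export (Turtle, N-Triples, RDF/XML) of
    patient data and inferred assertions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
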