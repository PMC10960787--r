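# renalrx

Rule-based prescription decision support for patients with type 2 diabetes
and chronic kidney disease (CKD).

Most drugs a diabetic CKD patient takes are cleared by the kidney, so as the
glomerular filtration rate (GFR) falls the usual dose becomes an overdose,
some drugs become contraindicated outright, and combinations that are merely
inadvisable in healthy patients (ACE inhibitor + angiotensin receptor
antagonist, beta blocker + Diltiazem/Verapamil, potassium-raising drugs on a
failing kidney) become dangerous. `renalrx` encodes this domain knowledge as
a declarative, validated knowledge base and a small forward-chaining
inference layer that audits a prescription against it, producing per-patient
dose recommendations and safety warnings. It also ships an evaluation
harness that scores the system against (simulated or real) expert rater
panels, a reproducible synthetic cohort generator, RDF export of both
patient data and inferred assertions, and a command-line interface.

## The model

* **Staging.** eGFR classifies patients into CKD stages G1–G5 on half-open
  intervals (`[90, ∞)`, `[60, 90)`, `[45, 60)`, `[30, 45)`, `[15, 30)`,
  `[0, 15)`); HbA1c classifies diabetes status at the 5.7 / 6.4 thresholds.
* **Dose banding.** Three GFR bands drive dosing: high (GFR > 50), mid
  (10 ≤ GFR ≤ 50), low (GFR < 10). Each of the 22 drugs with dose guidance
  carries a per-band adjustment: a fraction of the normal dose (possibly a
  range such as 25–50%), an absolute replacement dose, *avoid*
  (contraindication warning), or *no data*. Dose rules fire only for
  patients with an explicit CKD "Yes" flag who are explicitly not on
  dialysis; dialysis patients get a referral warning instead, and a missing
  flag never fires a rule.
* **Interactions.** A closed symmetric relation over drug pairs:
  {ACE inhibitors × angiotensin receptor antagonists} ∪
  {beta blockers × {Diltiazem, Verapamil}} — 62 unordered pairs derived
  from 5 stored one-sided rules. 30 drugs additionally carry
  potassium-increase warnings.
* **Diabetes dosing.** Percent reductions of the current insulin dose by
  GFR band (Lispro mix −25% in the mid band, Aspart −50% in the low band),
  gated on an explicit diabetes flag.
* **Evaluation.** Accuracy, sensitivity, specificity, precision and MSE
  against a rater panel with majority-vote ground truth; undefined metrics
  (zero denominators) raise errors rather than silently reporting 0.

The knowledge base lives in `inst/extdata/kb.yaml` and is structurally
validated on load (band coverage, monotone adjustments, symmetric
interaction closure, partition properties of stages and bands).

## Worked example

```r
library(renalrx)
kb <- load_knowledge_base()
p <- list(patient_id = "M001", gfr = 32, hba1c = 7.2, has_ckd = "Yes",
          has_t2dm = "Yes", has_dialysis = "No",
          prescription = "Acarbose;Candesartan;Ramipril")
generate_report(p, kb)
#> <patient_report> M001
#>   CKD stage   : G3b
#>   T2DM status : Diabetes
#>   items       : 3 recommendation(s), 3 warning(s)
#> # A tibble: 6 x 7
#>   item_type record         kind      drug        drug2    dose_label     rule_id
#> 1 ckd_dose  recommendation fraction  Acarbose    <NA>     50mg_tid       dose_a...
#> 2 ckd_dose  recommendation fraction  Candesartan <NA>     32mg_day       dose_c...
#> 3 t2dm_dose recommendation reduction Lispro mix  <NA>     Reduce_Dose_b...t2dm_l...
#> 4 ddi       warning        ddi       Candesartan Ramipril <NA>           ddi_ca...
#> 5 k_raising warning        k_raising Candesartan <NA>     <NA>           k_ara
#> 6 k_raising warning        k_raising Ramipril    <NA>     <NA>           k_ace_...
```

At GFR 32 (mid band) Acarbose is halved to 50 mg t.i.d and Candesartan
capped at 32 mg/day; the Lispro-mix insulin dose is cut by 25%; the
ACE-inhibitor/ARA pair triggers an interaction warning and both drugs a
potassium warning.

An end-to-end evaluation on a synthetic cohort with 10% simulated rater
error:

```r
cohort  <- generate_cohort(cohort_config(n = 249, seed = 1), kb)
reports <- generate_reports(cohort, kb)
panel   <- simulate_rater_panel(reports, kb, raters = 3,
                                flip_rate = 0.1, seed = 1)
glance(evaluate_cohort(reports, panel))
#>      tp    tn    fp    fn accuracy sensitivity specificity precision    mse n_items
#> 1   982   728    31    16    0.973       0.984       0.959     0.969 0.0268    1757
```

`autoplot()` on the result draws per-category metric bars;
`plot_mse_curve()` the running MSE. A CLI with `simulate`, `recommend`,
`evaluate`, `export` and `kb-report` subcommands is installed at
`system.file("cli", "renalrx.R", package = "renalrx")`.

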