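---
title: "Methods: rule-based prescription decision support for diabetic CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based prescription decision support for diabetic CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `renalrx`, the assumptions baked
into its knowledge base and generators, the default parameters and why they
were chosen, and the known limitations. It makes no empirical claims beyond
what the test suite and `scripts/acceptance.R` compute.

## The clinical model

The package targets one concrete safety problem: auditing the prescription
of a patient who has both type 2 diabetes and chronic kidney disease. Four
rule families operate over a declarative knowledge base
(`inst/extdata/kb.yaml`):

1. **Classification.** eGFR maps to CKD stages G1–G5 on half-open
   intervals: `[90, ∞) → G1`, `[60, 90) → G2`, `[45, 60) → G3a`,
   `[30, 45) → G3b`, `[15, 30) → G4`, `[0, 15) → G5`. The lower bound
   belongs to the better stage, so eGFR 60 is G2 and 59.9 is G3a. HbA1c
   maps to Normal (< 5.7), Prediabetes (`[5.7, 6.4)`) and Diabetes
   (≥ 6.4); a missing HbA1c yields "Unknown", and values outside the
   physiologic window (3, 20) are rejected as data errors.

2. **Renal dose adjustment.** Dosing uses three GFR bands — high
   (GFR > 50), mid (10 ≤ GFR ≤ 50), low (GFR < 10) — with both boundary
   values assigned to the mid band, matching the conventional
   ">50 / 10–50 / <10" presentation. Each drug with dose guidance stores,
   per band, either a fraction of its normal starting/maximum dose
   (ranges such as 25–50% are preserved as ranges, never collapsed to a
   midpoint), an absolute replacement dose, an *avoid* marker that becomes
   a contraindication warning, or *no data*. Adjusted doses are base ×
   fraction / 100, reported to two decimals.

3. **Safety gating.** A dose rule fires only when the profile carries an
   explicit `has_ckd = "Yes"` *and* an explicit `has_dialysis = "No"`.
   A dialysis patient receives a referral warning instead — GFR-band rules
   are not valid on dialysis — and a missing flag fires nothing: absence
   of evidence is never treated as evidence of absence. The same
   explicit-flag gate applies to the diabetes dose rules
   (`has_t2dm = "Yes"`).

4. **Warnings.** The interaction relation is closed and symmetric:
   {ACE inhibitors × angiotensin receptor antagonists} plus
   {beta blockers × {Diltiazem, Verapamil}}, stored as five one-sided
   rules and expanded to 62 unordered pairs at load time. Potassium
   warnings attach to four scopes (three drug classes plus
   Spironolactone), covering 30 drugs. Warning rules are deliberately
   *not* gated on disease flags — a dangerous combination is worth
   flagging regardless of the recorded comorbidity.

### Knowledge-base validation

`load_knowledge_base()` refuses a KB that fails structural validation:
every dose entry must cover all three bands with fractions in (0, 100] and
non-increasing adjustments from high to low band (*avoid* counts as 0);
interaction rules must reference known drugs, cover classes completely
(touching one member of a class without the rest is reported as an
asymmetric closure), and list each other symmetrically; stages and bands
must partition `[0, ∞)` with consistent open/closed sides; potassium and
diabetes rules must reference known scopes. Violations are returned as a
tibble by `validate_knowledge_base()` so defective KBs can be inspected.

Two curation notes on the bundled KB: a handful of printed dose cells in
the underlying formulary guidance are textual rather than numeric (they
are kept as text with missing mg values and surface as *no data* rather
than being guessed), and the insulin entries are stored under their bare
names ("Lispro mix", "Aspart").

## Evaluation harness

The evaluation protocol mirrors a multi-rater audit: each system output
item is judged True/False by an odd panel of raters; ground truth is the
majority vote (or, optionally, a single rater). Items are reconciled
between the system report and the panel before scoring — any mismatch is
an error, not a silent drop. Metrics follow their standard definitions,
accuracy `(TN+TP)/total`, sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)`, precision `TP/(TP+FP)`, and MSE `(1/n) Σ (A−P)²`; over
binary correctness indicators MSE equals `1 − accuracy`, an identity the
tests exploit. A metric with a zero denominator *raises an error* in the
scalar API and is reported as `NA` in the per-category/per-patient tables;
it is never silently 0.

Because the system only asserts positives, specificity needs true
negatives to be defined. `simulate_rater_panel()` therefore adds, per
patient and category, distractor items the system did **not** assert
(a non-recommended drug, an inert drug pair, a non-potassium-raising
drug). Each rater starts from the correct judgment and flips it
independently with probability `flip_rate`; at `flip_rate = 0` every
metric is exactly 1 and MSE exactly 0, which the end-to-end smoke test
asserts.

## Synthetic cohort generator

`generate_cohort()` emulates the *shape* of a diabetic-CKD study cohort,
not its clinical joint distribution. Defaults were fixed once as the study
conditions:

* `n = 249` patients — the cohort size the engine is designed around;
* `stage_mix = (G1 .15, G2 .25, G3a .20, G3b .18, G4 .15, G5 .07)` — a
  plausible spread guaranteeing coverage of every stage and dose band at
  the default size;
* `t2dm_rate = 1` (everyone diabetic), `ckd_rate = 0.9` (a small minority
  without a confirmed CKD flag exercises the gating), `dialysis_rate = 0`
  (end-stage patients excluded by default; raise it to exercise the
  referral path);
* prescriptions of 1–5 drugs sampled uniformly from the KB drug list;
* 27 numeric features drawn uniformly within clinically plausible ranges.

A patient's stage is sampled first and the GFR then drawn uniformly
*inside* that stage's interval (with rounding clamped away from the open
upper bound), so generated GFRs always classify back to their assigned
stage — a property test. HbA1c is drawn consistent with the diabetes
flag. All randomness flows through a single seed via `withr::with_seed`,
so the same configuration is byte-identical across runs. What the
generator does **not** emulate: correlations between labs, realistic
prescription co-occurrence, longitudinal structure, or any site-specific
demographics.

## RDF export

Patient rows export as one `rdf:type` assertion plus one literal triple
per non-missing column; reports export their rule heads using the rule
vocabulary (`recommendedKidneyDrugDosage` pointing at dose individuals
such as `drug:AcarboseDose_50mg_tid`, `recommendedDiabetesDrugDosage`,
symmetric `hasDrugDrugInteractionWarning` pairs,
`hasPotassiumLevelIncreaseWarning`). Serialization to Turtle, N-Triples
and RDF/XML is hand-written (no RDF stack is available to the package at
runtime), with parsers for all three formats; round-trips are exact, and
the test suite additionally cross-checks all three serializations against
an independent Python `rdflib` installation for graph isomorphism.
Namespaces default to a generic base (`http://example.org/renalrx/`) and
are fully configurable.

## Numerical choices

* Dose arithmetic is plain double precision rounded to 2 decimals at the
  reporting boundary only.
* Interval membership uses half-open comparisons exactly as specified
  above; no epsilon fudging. Stage classification rejects non-positive or
  non-finite eGFR rather than clamping.
* Running MSE is a cumulative mean in patient order; metric identities
  (accuracy as the prevalence-weighted mean of sensitivity and
  specificity; MSE = 1 − accuracy) are verified on random inputs rather
  than assumed.

## Limitations

* The knowledge base covers 44 drugs in 7 classes with banded dose
  guidance for 22 of them; it is a demonstration formulary, not a
  complete clinical reference, and none of this is medical advice.
* Dose rules key on GFR bands alone; weight, age, interacting
  pharmacokinetics and indication are out of scope.
* The rater simulator models independent symmetric error only — no rater
  bias, difficulty structure, or inter-rater correlation.
* Headline agreement statistics obtained on simulated panels measure the
  harness, not clinical validity; validation against real expert ratings
  requires real data the package does not ship.
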