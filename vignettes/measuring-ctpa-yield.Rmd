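---
title: "Measuring ED CTPA yield from structured EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ED CTPA yield from structured EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpayield)
```

## The measurement problem

CT pulmonary angiography is the first-line test for suspected pulmonary
embolism in the emergency department, and its *yield* — the fraction of
completed studies that are actually positive for PE — is widely used as a
proxy for how well a department's ordering matches pretest probability. The
traditional way to measure yield is manual review of radiology reports,
which does not scale to continuous monitoring. This package implements a
fully computable alternative: a completed ED CTPA order is counted positive
when it links to an inpatient admission whose discharge diagnoses contain a
PE code. Everything is derived from four structured tables any EHR can
export — imaging orders, ED encounters, inpatient admissions, and coded
discharge diagnoses — so the measure can run monthly with no human in the
loop.

## The algorithm and its assumptions

The pipeline in `ctpa_yield()` proceeds in four steps.

**Selection.** Only orders with `order_type = CTPA` and `status = COMPLETED`
enter the denominator. Cancelled and discontinued orders represent studies
that never happened. The status column is taken at face value: whether
"completed" means order completion or the final radiology read is a property
of the source system, not of this algorithm.

**Exclusion.** A CTPA ordered on the same calendar day as a completed CT
angiography of the abdomen and pelvis for the same patient is excluded: that
pairing is the signature of an aortic-dissection rule-out protocol, so the
CTPA was not ordered to evaluate PE and would dilute the yield. "Same day"
is equality of the calendar-date component of the order timestamps,
interpreted as site-local wall clock (timestamps are held in UTC purely to
avoid daylight-saving arithmetic; no conversion is ever applied). The
pairing is at *patient* level — one same-day CTA excludes all of that
patient's CTPA orders that day — and only `COMPLETED` CTA orders trigger it,
since the exclusion is about a study actually performed under the protocol.

**Linkage.** Each analyzable order must find its inpatient admission. The
primary join is the explicit encounter key: the admission whose
`source_ed_encounter_id` equals the order's ED encounter. Exports that lack
the key fall back to a time rule — the earliest same-patient admission
admitted within `linkage_window_hours` of the order. The default of 48
hours is wide enough to span overnight ED boarding while staying well below
the gap to an unrelated readmission. Ties on identical admit times (never
expected in practice) break deterministically to the smallest
`admission_id`, with a warning. Two admissions claiming the same encounter
key are a data-integrity error, not a tie.

An order that links to nothing is the *ED-discharge case*: the patient was
treated and released directly from the ED, so no inpatient discharge coding
ever happens and the method necessarily classifies the order negative. This
is the algorithm's one structural failure mode, and the synthetic generator
can reproduce it on demand (`n_positive_discharged_from_ed`).

**Classification and yield.** A linked order is positive iff any discharge
diagnosis of its admission — primary or secondary rank — is in the PE code
set for its ICD version. The yield is the positive count over the analyzable
count, overall and per site; an empty denominator gives an explicitly
undefined yield (`NA`), never a division error. The unit of analysis is the
*order*: a patient scanned twice contributes twice to the denominator.

### The PE code set

The frozen default (`pe_codeset()`) is five ICD-9-CM codes (415.0, 415.11,
415.12, 415.13, 415.19) and eight ICD-10-CM codes (I26.0, I26.01, I26.02,
I26.09, I26.9, I26.90, I26.92, I26.99). Matching is exact set membership
after normalization (upper-case, whitespace- and dot-stripped); there is no
hierarchical prefix expansion, because the definition already enumerates
both the non-billable headers (I26.0, I26.9) and their children, and
expansion could silently over-match other I26.x codes. Whether a source
system can emit the header codes as stored values varies; including them
verbatim is harmless under exact matching. Other phenotypes can swap in
their own lists via `pe_codeset()` or a YAML `codesets:` section, but the
PE default is a named, frozen definition.

## Validation statistics

`validate_against_chart()` compares the computed classification with
chart-review gold-standard labels on the 2×2 table with cells *a*
(both positive), *b* (computed only), *c* (chart only), *d* (both negative).

* **Cohen's kappa**, κ = (p_o − p_e)/(1 − p_e), with p_o = (a+d)/n and
  p_e = [(a+b)(a+c) + (c+d)(b+d)]/n². The confidence interval uses the
  large-sample standard error √[p_o(1 − p_o)/(n(1 − p_e)²)] with z = 1.96,
  truncated to [−1, 1]; near-perfect agreement routinely pushes the raw
  upper bound past 1, so truncation is visible in ordinary use.
* **McNemar's test** on the discordant cells. The default is the
  *uncorrected* statistic χ² = (b−c)²/(b+c): with a single discordant pair
  the continuity-corrected statistic is identically 0 (p = 1) and the exact
  binomial test is also degenerate at p = 1, so only the uncorrected form is
  informative at the discordance levels this method is designed to achieve.
  Both alternatives are exposed (`variant =`), and b + c = 0 yields p = 1 by
  convention in all three.
* **Capture accuracy**, a/(a+c) — the fraction of chart-positive scans the
  method finds. Operationally a sensitivity; the reporting label follows
  the convention of imaging-yield validation studies. It is kept strictly
  separate from observed agreement (a+d)/n, which has a different
  denominator, and it errors loudly (rather than returning NaN) when there
  are no chart positives.

Labels and classifications must pair exactly: a label for an unclassified
order, a duplicate label, or a classified order with no label are integrity
errors, never silent drops — a validation run on a partially labelled
cohort would otherwise report biased agreement.

## The synthetic generator

`generate_cohort()` materializes the five tables for a `cohort_spec()` of
per-site counts: completed CTPA orders, cancelled/discontinued orders,
same-day CTA pairs, chart positives, chart positives discharged from the
ED, and chart negatives with no admission. Counts are exact by
construction — the requested roles are assigned by sampling *which* orders
take them, so re-running the pipeline on a generated cohort recovers the
spec's implied accounting identically, and changing the seed changes
identifiers, timestamps, and role assignment but never a count. Each order
gets its own patient and ED encounter: the unit of analysis downstream is
the order, so sharing patients would complicate the bookkeeping without
exercising anything new. Timestamps are uniform within each site's month;
admissions follow the order by 1–12 hours and last 1–7 days; every
admission carries 1–3 filler diagnoses drawn from a small non-PE list that
is asserted disjoint from the PE code set at generation time; linked
positives carry exactly one PE code, placed at secondary rank with
probability `rank_mix` and coded in ICD-10 with probability
`icd_version_mix`.

`two_site_preset()` freezes the package's reference scenario: site NSUH
(April 2016) with 229 completed orders, 26 same-day exclusions, 203
analyzable, 19 chart positives, one of them discharged from the ED; site
LIJMC (November 2016) with 146 analyzable, 9 chart positives, all admitted.
That yields 375 raw orders, 349 analyzable, 28 chart positives, 27 captured
— a confusion table of (27, 0, 1, 321), κ = 0.98 with 95 % CI (0.94, 1.00),
uncorrected McNemar χ² = 1 (p = 0.32), capture accuracy 96.4 %. Several
preset choices are conventions, since no site-level breakdown constrains
them: the exclusions sit entirely at NSUH; cancelled/discontinued counts
(14 and 9) and unlinked-negative counts (110 and 80 — most PE-negative ED
patients go home) are representative values; PE codes are all ICD-10-CM,
the coding system in use for 2016 discharges, with 30 % at secondary rank.
None of these choices moves any reported statistic, which the test suite
verifies by perturbing them.

What the generator does *not* emulate: demographics, comorbidity structure,
free-text reports, coding errors, cross-site patient overlap, or orders
spanning month boundaries. Passing tests on synthetic cohorts therefore
demonstrate the *algorithmic* correctness of the pipeline and statistics —
that the method computes what it claims on well-formed extracts — not the
clinical accuracy of admission-linked classification on any particular
real EHR, which depends on local coding practice and must be established by
a site's own chart-review validation.

## Numerical and degenerate-input choices

* Yield on an empty analyzable set is `NA` with the accounting intact, so a
  site-month with no orders is distinguishable from one with zero positives.
* Kappa is undefined (an error) on an empty table or when degenerate
  marginals force p_e = 1; capture accuracy errors when a + c = 0.
* All counts are integers throughout; fractions are exact ratios computed
  once, and display rounding (one decimal for percentages, two for kappa)
  never feeds back into stored values.
* Validation errors carry classed conditions (`ctpa_schema_error`,
  `ctpa_validation_error`, `ctpa_integrity_error`) naming the row and
  column, so a bad export fails fast and precisely.

## Problem sizes in the test suite

The reference scenario (375 orders across two sites) runs the full pipeline
in well under a second. The property suites use 200 random feasible specs
for accounting-partition conservation, 100 seeds for generator count
fidelity, 1,000 random 2×2 tables against a brute-force expected-table
kappa, exhaustive enumeration of exact McNemar for all discordance splits
with b + c ≤ 12, and brute-force triple enumeration of the whole pipeline
on cohorts of ≤ 20 orders — sizes at which the independent oracles are
trivially auditable while still covering the combinatorics.

## Limitations

The measure inherits the structural blind spot of inpatient linkage: a
PE-positive patient discharged directly from the ED is always missed, and
outpatient management of low-risk PE is becoming more common, so the
capture accuracy of the admission-linked definition should be expected to
drift down over time until ED and outpatient discharge diagnoses are
linked as well. The package does not distinguish acute from chronic or
subsegmental PE, does not parse report text, and takes order status and
coding at face value.
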