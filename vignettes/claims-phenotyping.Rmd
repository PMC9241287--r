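---
title: "Phenotyping incident lung cancer in SHI claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping incident lung cancer in SHI claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungclaims)
```

## The phenotyping problem

German statutory health insurance (SHI) billing data contain everything a
payer needs and nothing a tumour registry would add: ICD-10-GM diagnoses at
quarter resolution with an inpatient/outpatient setting, EBM codes for
outpatient services, OPS codes for inpatient procedures, and ATC-coded drug
dispensings. There is no histology field, so the clinically decisive
distinction between non-small cell (NSCLC) and small cell (SCLC) lung cancer
has to be inferred — if it can be inferred at all — from what was billed.

`lungclaims` implements a rule-based phenotyping pipeline for this setting.
The pipeline is deterministic: given the same claims tables and the same
code table it always produces the same result, and every rule is exposed as
a testable function.

## Cohort selection

A patient becomes a *candidate* when a C33/C34 diagnosis is coded in a
quarter of the index period (2015–2016); the earliest such quarter is the
**index quarter**. Candidates then pass an ordered exclusion cascade; a
patient failing several checks is counted once, under the first failing
check, so exclusion counts are disjoint and sum to the candidate total:

1. **Confirmation** — outpatient C33/C34 coding in at least two different
   quarters of the observation period (M2Q), or one confirmed inpatient
   coding. The `confirmed` flag is honoured only on the inpatient branch;
   outpatient M2Q counting uses all outpatient codings, because the
   source algorithm attaches the confirmation qualifier only to inpatient
   treatment.
2. **Washout** — no C33/C34 coding in quarters index−8 … index−1.
3. **Pre-observation** — continuous enrollment over those eight quarters
   (administrative gaps shorter than one day are merged).
4. **Other primary tumours** — any C00–C75 coding except C33, C34, C44 and
   C61 within ±8 quarters of the index quarter.
5. **Post-observation** — enrollment must reach the quarter after the index
   quarter. The source publication reports this exclusion without defining
   it; we chose the weakest enrollment-based reading (coverage of at least
   the first day of quarter index+1). The data model carries no death
   marker, so mortality cannot rescue a truncated enrollment here.

The M2Q observation period runs to the end of the data horizon
(2018-12-31 by default) rather than the end of the index period, matching
the use of follow-up data through 2018 for treatment ascertainment.

Stage is assigned from index-quarter codings with the precedence
distant (C78/C79) ≻ lymph-node (C77) ≻ none; the cohort definitions are
nested and stage IV dominates clinically, so co-occurring codes resolve
upward. Age is computed as index year minus birth year and split at 60
years (≤60 vs >60); a missing birth year is reported as `unknown`, never
silently dropped.

## Lines of therapy and classification

First-line therapy is the treatment whose start is billed in the index
quarter or the following one: the earliest therapy-relevant event there
opens the episode, and all therapy billings within the collection window
belong to it. "One month" is not defined in the source; we fix it as **30
calendar days** (configurable via `window`). The window is closed at both
ends, so a new code exactly 30 days after the start is still first-line
and the second-line scan begins at day 31.

Treatment groups are assigned hierarchically over the window —
Immunotherapy ≻ Inhibitors ≻ Chemotherapy ≻ Radiotherapy ≻ Study — the
listing order of the published code table, which states that assignment is
hierarchical without printing the order. The *Study* group requires a
study primary code (EBM 13461/13492/13494) together with a companion
service code (EBM 02100/02101/01510/01511/01512); the published conjunction
is not given a pairing window, so we require same-quarter co-occurrence,
and an unpaired primary neither forms a group nor opens a line.

The second line opens at the first therapy code after the first-line
window that did **not** occur inside that window — any ATC, therapy-OPS or
therapy-EBM code, not only dispensings, because all therapeutic cost items
are recorded again after the first month. Patients can re-enter the same
group with a different drug; repeats of first-line codes never trigger.

Cancer type is read off the NSCLC/SCLC tags of the deciding window: a
uniform tag yields the call; mixed tags yield `unclassifiable` with a
`conflicting` marker (the rule demands unambiguous assignment — no majority
vote); a window with only untyped codes (platins, docetaxel, generic
chemotherapy OPS) falls through to the second line; typed drugs outside
any window leave the patient unclassifiable. Generic chemotherapy OPS
markers (8-542 … 8-549) contribute to the Chemotherapy group but never to
the type call.

Patients without a first-line episode fall through the published
"other treatment" cascade in fixed order: inpatient medication-application
marker (OPS 8-541) within a month of the index quarter → no follow-up
documentation at all → therapy only after the line windows (late therapy)
→ lung cancer never re-coded after the index quarter → surgery without
therapy → bronchoscopy only → none of the above.

## Care attribution and diagnostics

The "therapist" of a quarter is the highest-ranking institution coding
C33/C34 there: inpatient hospital ≻ outpatient hospital ≻ office-based
physician. Within office-based physicians the specialty order
(oncologist ≻ pulmonologist ≻ radiologist ≻ internist ≻ primary care ≻
other) follows the listing in the source text; the authoritative
supplementary hierarchy is not published, so this order is a documented
choice. Attribution is independent of within-quarter event order.

Biomarker tests (EBM 19320–19322, OPS 1-991x/1-992x) and bronchoscopies
(OPS 1-690.0/1-690.1/1-620, EBM 09315/13662) are searched in the
first-line context (index quarter plus the first 30 days of first-line
therapy) and the second-line context (day 31 after first-line start to 30
days after second-line start). Where the contexts overlap — a first line
starting early in the index quarter — the first-line context wins, because
the source assigns tests "during this period" to first-line therapy. A
detected test is *inpatient* if a hospital stay overlaps the 14 days
before the test date (discharge exactly 14 days before still counts;
15 days flips to outpatient), since ambulatory care can be billed with
inpatient OPS codes.

The surgery OPS list lives only in unpublished supplementary material; the
bundled entries (OPS 5-32x lung-resection family) are a clearly labelled
synthetic placeholder in the editable code-table CSV and must be replaced
for real analyses.

## Burden (time expenditure)

For relative quarters −4 … +8 around the index quarter the pipeline counts
pharmacy visits (distinct dispensing dates — claims record dispensings,
not footfall), primary-care and specialist visits (distinct date–provider
contacts; oncologists, pulmonologists, radiologists, internists and other
office-based physicians count as specialists), inpatient hospital days
(closed intervals, the discharge day counts, stays spanning quarter
boundaries are split by calendar membership) and outpatient hospital
contacts. Quarters without enrollment overlap are *missing*, not zero —
zeros would bias means downward after death or disenrollment — and
missing quarters leave the aggregation denominator. The burden analysis is
restricted to patients with exactly a first line and outpatient M2Q
confirmation, mirroring the published exclusions.

## The synthetic generator

`generate_population()` emulates the structure of the proprietary source
data, not its marginals: quarter-resolved C33/C34 coding with M2Q-style
outpatient confirmation or confirmed inpatient coding, staging codes,
therapy events timed relative to the index quarter, planned exclusion
contamination, and background utilisation. Defaults are fixed at the
published study conditions where stated: index period 2015–2016, 80:20
NSCLC:SCLC, 60% treated in first line, exclusion contamination at the
published attrition shares (30.9% / 4.0% / 10.5%), 79% urban, an older
two-point age mixture around the published medians. Where the source is
silent we chose once: 70% incident cases among simulated persons, 50% M2Q
confirmation, 25% second lines, 10% off-label contamination, background
contact rates of 1.5 / 1.0 / 1.2 / 0.3 per quarter (GP / specialist /
pharmacy / outpatient hospital). First-line start is uniform over the
index and following quarter with within-window events at days 0/7/21;
true-SCLC patients draw their treatment group from the SCLC-feasible
groups only, since no SCLC-approved immunotherapy or inhibitor exists in
the code table (an all-infeasible mixture is a configuration error).

Two reproducibility properties are built in. Each patient owns a stream
seeded from a master stream, so populations are prefix-stable under the
same seed; deriving the streams from a single `sample.int()` pass (rather
than arithmetic on the seed) keeps them decorrelated. And the uniform that
decides off-label contamination is drawn at a fixed position whether or
not it fires, so populations at different `off_label_rate` are nested and
classification accuracy is monotone non-increasing in the rate by
construction — which is exactly what the recovery tests assert.

What the generator does **not** emulate: real comorbidity structure,
coding noise beyond off-label drugs, costs, regional marginals, or the
source database's true attrition overlap structure. Passing tests
therefore demonstrate that the *rules* are implemented faithfully and
recover planted truth, not that the pipeline would reproduce the published
cohort counts on real data — those depend on proprietary inputs.

## Numerical and interface choices

* Quarters are integer ordinals (`year*4 + q - 1`); all window arithmetic
  is integer, dates are ISO-8601 `Date`s, intervals are closed.
* Codes are canonicalised (uppercase, dots/spaces stripped, en-dashes to
  hyphens, trailing wildcard markers to prefix entries); three-character
  ICD codes match all their children. The code table ships as an editable
  versioned CSV.
* Percentages print with one decimal and half-up rounding, matching the
  publication's style; report rendering uses fixed radix ordering so
  identical inputs give byte-identical reports.
* Problem sizes in the test-suite recovery checks (populations of a few
  hundred to 5,000 patients, three seeds per stochastic claim) were chosen
  as the smallest sizes at which the binomial recovery intervals are
  informative.

## Known limitations

The surgery and therapist code sets are placeholders (above). The
pipeline stops at the second line. Squamous vs non-squamous NSCLC cannot
be distinguished — the coding system itself does not support it. The
"insufficient post-observation" definition is one defensible reading of an
undefined published criterion; sensitivity to it can be probed by editing
a single rule. Study-group pairing uses same-quarter co-occurrence in the
absence of a published pairing window.
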