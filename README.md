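# lungclaims

Phenotyping incident lung cancer in German statutory health insurance (SHI)
claims data.

German SHI billing data record diagnoses (ICD-10-GM), outpatient services
(EBM), inpatient procedures (OPS) and drug dispensings (ATC), but no
histology. `lungclaims` implements, as a tested and reusable R pipeline, a
published claims-phenotyping algorithm for incident lung cancer:

* **Incident-cohort selection** — the *index quarter* is the first calendar
  quarter in 2015–2016 with a C33/C34 coding; the diagnosis must be
  *confirmed* (outpatient coding in ≥ 2 different quarters, the "M2Q"
  criterion, or one confirmed inpatient coding); an eight-quarter washout
  enforces incidence; patients with other primary solid tumours
  (C00–C75 without C33/C34/C44/C61) within ±8 quarters of the index
  quarter, or with insufficient pre-/post-observation enrollment, are
  excluded with a single, ordered exclusion reason.
* **Staging** from secondary-neoplasm codes in the index quarter
  (C78/C79 → distant metastases ≻ C77 → lymph-node metastases ≻ none).
* **Lines of therapy** — first-line therapy starts with the earliest
  therapy-relevant billing (ATC/OPS/EBM) in the index or following quarter;
  all therapy billings in a 30-day window form the episode, assigned
  hierarchically to Immunotherapy ≻ Inhibitors ≻ Chemotherapy ≻
  Radiotherapy ≻ Study. A code absent from the first-line window, billed
  more than 30 days after its start, opens the second line. Untreated
  patients fall through a fixed "other treatment" cascade.
* **NSCLC/SCLC classification** from type-specific drug codes: a uniformly
  tagged line window yields the call; mixed tags or no typed drug in any
  window leave the patient unclassifiable.
* **Care attribution** — the coding institution ("therapist") per quarter by
  hierarchy; biomarker-testing and bronchoscopy detection with
  inpatient/outpatient assignment via a 14-day hospital-stay lookback;
  surgery flags (the bundled surgery OPS set is a labelled synthetic
  placeholder).
* **Time-expenditure (burden) series** — per relative quarter −4 … +8 around
  the index quarter: pharmacy visits, primary-care and specialist visits,
  inpatient hospital days and outpatient hospital treatments, aggregated as
  means per cancer-type stratum.

The real data source behind the published algorithm is a proprietary claims
database, so the package ships a **synthetic claims generator**
(`generate_population()`) that emits the same four delimited event tables
with ground-truth labels, plus a fixed adversarial edge-case panel
(`inject_edge_cases()`). Every pipeline stage is validated by parameter
recovery against that truth and by an independent brute-force oracle.

## Worked example

```r
library(lungclaims)

pop <- generate_population(scenario_config(n_patients = 300, seed = 2024))
fit <- lc_phenotype(pop$claims)
fit
#> Incident lung-cancer phenotyping
#>   patients: 300 | candidates: 197 | included: 112 
#>   excluded (insufficient_pre_observation): 7 (3.6%)
#>   excluded (other_primary_tumor): 66 (33.5%)
#>   excluded (insufficient_post_observation): 12 (6.1%)
#>   cancer-type calls: NSCLC=43, SCLC=8, unclassifiable=61 
```

Of the 300 simulated insured persons, 197 have an index lung-cancer coding
in 2015–2016; the exclusion cascade removes other-primary-tumour patients
and those with too little enrollment before/after the index quarter,
leaving 112 analysable patients. Drug-based classification resolves 51 of
them (43 NSCLC, 8 SCLC); the rest have no type-specific drug in a line
window — the published algorithm's central limitation, reproduced here by
design. `summary(fit)` prints the attrition and crosstab tables,
`plot(fit)` the mean burden series, and `fit$selection`, `fit$lines`,
`fit$types`, `fit$care`, `fit$burden_means` expose the underlying tables.
Claims datasets are read and written as plain CSV via `read_claims()` /
`write_claims()`.

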