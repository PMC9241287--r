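Package: lungclaims
Title: Phenotyping Incident Lung Cancer in German Statutory Health Insurance Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based phenotyping of incident lung cancer in German statutory
    health insurance (SHI) billing data: incident-cohort selection with M2Q
    confirmation and an eight-quarter washout, code-based staging (C77/C78/C79),
    first- and second-line treatment-episode construction from ATC/OPS/EBM
    codes, NSCLC/SCLC classification from type-specific drug codes, therapist
    attribution and diagnostic-procedure detection, and a per-quarter patient
    time-expenditure (burden) metric. Ships a versioned machine-readable code
    table and a synthetic claims generator with ground-truth labels so the full
    pipeline is testable without access to proprietary claims data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
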