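Package: ctpayield
Title: Computerized Measurement of CT Pulmonary Angiography Yield from EHR Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the diagnostic yield of computed tomography pulmonary
    angiography (CTPA) ordered in the emergency department from structured
    electronic health record extracts. Implements an order-filtering,
    exclusion, and ED-to-inpatient linkage algorithm with ICD-9-CM/ICD-10-CM
    pulmonary-embolism code-set matching, validation statistics against
    chart-review gold standards (Cohen's kappa with asymptotic confidence
    interval, McNemar's test, capture accuracy), and a seeded synthetic EHR
    cohort generator, including a frozen two-site emergency-department
    preset, so the whole workflow is reproducible without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
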