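Package: fractrace
Title: Incident Hip Fracture Ascertainment from Hospital Admission Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting incident hip fractures from raw hospital
    admission records, where transfers, readmissions and complication care
    inflate naive counts. Implements care-episode chaining under the
    one-day transfer rule, a logistic readmission classifier with a fixed
    probability cut-off, comparison counters (naive, official-statistics,
    naive excluding adjacent admissions), direct age-standardization with
    bootstrap percentile confidence intervals, Aalen-Johansen cumulative
    incidence of a second fracture with death as a competing event, and
    scenario-based projections of annual fracture counts. A synthetic
    register generator with ground-truth labels makes the whole pipeline
    testable without access to confidential register data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
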