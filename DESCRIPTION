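Package: labharbor
Title: Harmonize EHR Laboratory Exports into REDCap Registry Imports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms messy multi-source electronic health record (EHR)
    laboratory exports into validated, de-identified, REDCap-importable
    registry records conforming to a shared data dictionary. Provides a
    REDCap data-dictionary model with field-level validation, parsers for
    untidy 4-column EHR exports and tabular data-warehouse exports, a
    key-value lookup remapper from source lab subtypes to registry field
    codes, unit enforcement with itemized exclusion accounting,
    MRN-to-record_id de-identification, repeat-instance assignment for
    same-day draws, multi-site aggregation, and LOINC annotation. An
    outcomes stage derives overall survival from registry instruments and
    runs a univariable Cox proportional-hazards screen (Efron ties, Newton
    iteration) over baseline labs. A synthetic-cohort generator with known
    ground truth and a manual-vs-automated agreement report support
    end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
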