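Package: t1dqm
Title: EHR-Derived Quality Measures for Pediatric Type 1 Diabetes Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes automated quality-of-care measures for pediatric type 1
    diabetes from electronic-health-record extracts held in a PCORnet-style
    Common Data Model. Provides terminology code-set handling (ICD-9-CM,
    ICD-10-CM, SNOMED, LOINC), a computable T1D phenotype over a 365-day
    lookback window, five glycemic-control and utilization measures with
    site-level benchmarking (exact binomial confidence intervals), validation
    of CDM-derived measures against chart-review outcomes (positive and
    negative predictive value, percent agreement), and a synthetic multi-site
    CDM generator with planted gold-standard outcomes and configurable
    error mechanisms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
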