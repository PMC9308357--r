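Package: mirrorimage
Title: Mirror-Image Analysis of Psychiatric Hospitalisations Around an
    Intervention Start Date
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective mirror-image (self-controlled) analyses
    of inpatient psychiatric hospitalisation around the start of a community
    intervention such as Independent Supported Housing. Provides cohort
    selection from utilisation and admission records with administrative
    censoring, construction of equal-length pre/post mirror windows
    (variable-length and fixed 90/180/270/365-day variants), censoring-aware
    counting of admissions and hospitalised person-days, pooled incidence
    rate ratios with log-scale confidence intervals, a lookback-exclusion
    sensitivity analysis targeting regression toward the mean, and a
    synthetic-cohort simulator for validating every pipeline stage without
    access to medical-record data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
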