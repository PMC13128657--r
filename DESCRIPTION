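Package: dipburden
Title: Economic Burden of Hospital-Acquired Infections Under Case-Based
    (DIP) Payment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the economic burden of hospital-acquired
    infections (HAIs) on inpatient episodes settled under China's
    Diagnosis-Intervention Packet (DIP) case-based payment model. Provides a
    synthetic inpatient-cohort generator with injectable, known-magnitude
    infection effects; Charlson age-comorbidity index (CACI) scoring from
    ICD-10 codes; three case-control matching designs (exact 1:1,
    propensity-score caliper matching, and risk-set matching at infection
    onset); nonparametric comparison machinery including Hodges-Lehmann
    median-difference estimation with distribution-free confidence
    intervals; and Gaussian identity-link generalized linear models of DIP
    payment differentials with heteroskedasticity-consistent standard
    errors. An orchestration layer reproduces the full analysis - category
    concentration tables, infection-classification strata, matched
    comparisons and the payment-differential regression - on synthetic or
    user-supplied episode tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
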