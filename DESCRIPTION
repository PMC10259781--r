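Package: jaderpv
Title: Pharmacovigilance Signal Analysis for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality and time-to-onset analysis of
    spontaneous adverse event reports in the four-table layout used by the
    Japanese Adverse Drug Event Report (JADER) database. Reads DEMO, DRUG,
    REAC and HIST tables with a configurable column mapping, joins them into
    case records, flags cases against Standardized MedDRA Query (SMQ) term
    lists, applies exclusion rules with an auditable ledger, estimates crude
    and adjusted reporting odds ratios with Wald confidence intervals via
    multivariate logistic regression, and characterizes onset hazard by a
    maximum-likelihood Weibull fit with failure-type classification. A
    seeded simulator emits database dumps with known ground truth so every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
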