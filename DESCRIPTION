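Package: csaki
Title: Detection and Outcome Analysis of Cardiac Surgery-Associated Acute
    Kidney Injury from Fused Electronic Health Records
Version: 0.1.0
Authors@R:
    person("csaki", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and stage acute kidney injury (AKI) after cardiac
    surgery according to the full KDIGO criteria (serum creatinine, urine
    output, and renal replacement therapy) on time-series data fused from two
    electronic health record sources: a hospital information system
    (demographics, surgeries, outcomes) and an intensive-care patient data
    management system (timestamped observations). Includes record linkage with
    surgery-to-ICU-stay mapping, redundancy resolution by source quality,
    computability exclusions with a cohort-flow report, cohort-level incidence
    and staging summaries, stratified rate tables, chi-square and Wilcoxon
    comparisons, Kaplan-Meier/log-rank survival, logistic regression with Wald
    intervals for first and maximum AKI stage, a simulation-based power
    calculation, and a seeded synthetic-cohort generator with a ground-truth
    ledger built by inverting the detector, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
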