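Package: neocds
Title: Newborn Clinical Decision Support, Form Completeness, and
    Diagnostic-Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine for threshold-based classification of small and
    sick newborns (low birth weight, weight loss, fever, hypothermia, fast
    breathing, danger signs, feeding problems), case-management planning
    (referral, counseling, follow-up dates), a schema-driven assessment-form
    engine with skip logic and completeness auditing, diagnostic-accuracy
    statistics for method-comparison studies (2x2 concordance, chi-squared
    tests, crude and cluster-robust odds ratios), and a seeded synthetic
    cohort and assessor-error simulator for end-to-end method-comparison
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
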