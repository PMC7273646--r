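Package: sortmeta
Title: Symptom-Level Meta-Analysis and Symptom-Oriented Therapy Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for symptom-level comparative-effectiveness synthesis of
    randomised trials of antidepressant medication versus psychotherapy for
    depression. Estimates per-study, per-symptom treatment effects from ordinal
    endpoint frequency tables (proportional odds ratios, median-split odds
    ratios, standardised mean differences), pools them with inverse-variance
    random-effects meta-analysis (REML or DerSimonian-Laird) with heterogeneity,
    Egger regression, moderator meta-regression, dropout meta-analysis and
    Benjamini-Hochberg adjustment, and combines pooled symptom weights with
    patient baseline symptom profiles into Symptom-Oriented Therapy (SOrT)
    allocation scores. Includes evaluation of SOrT-guided allocation
    (valence, median and extreme-group splits) and synthetic-data generators
    for multi-study ordinal trial data and patient cohorts with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    metafor,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
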