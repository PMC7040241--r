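Package: thyrostrat
Title: Risk Stratification of Cytologically Indeterminate Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a combined ultrasound and somatic-variant risk
    stratification system for thyroid nodules with indeterminate cytology
    (Bethesda III/IV). Maps American Thyroid Association sonographic patterns
    to an annotated ultrasound score, computes an additive genomic classifier
    score from weighted somatic alterations (SNV/INDEL, gene fusion, CNV
    terms), and combines them into a total risk score with a management
    cutoff. Provides full diagnostic-performance statistics (Wilson score
    confidence intervals, Woolf odds-ratio intervals, balanced accuracy,
    cutoff selection, subgroup exclusion, proportion comparisons), Bayes
    theorem projection of predictive values across disease prevalence,
    exhaustive reconstruction of integer 2x2 confusion tables from published
    rounded metrics, and a reproducible synthetic cohort generator emulating
    a surgical pilot cohort of indeterminate nodules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
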