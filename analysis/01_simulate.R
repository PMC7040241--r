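#!/usr/bin/env Rscript
# Stage 1 — simulate a study-like cohort.
#
# Draws a 47-patient cohort of cytologically indeterminate thyroid nodules
# from the default configuration (malignancy prevalence 28/47, study-like
# histology mix, histology-conditional alteration spectra, malignancy-
# conditional ATA ultrasound patterns) and writes it as the cohort CSV that
# the later stages consume.

suppressPackageStartupMessages(library(thyrostrat))

seed <- as.integer(Sys.getenv("THYROSTRAT_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cfg <- default_study_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv")

cat(sprintf("Simulated %d nodules (seed %d): %d malignant, %d benign\n",
            nrow(cohort), seed,
            sum(cohort$truth == "MALIGNANT"),
            sum(cohort$truth == "BENIGN")))
cat("Histology counts:\n")
print(table(cohort$histology))
pos <- implied_positivity(cfg)
cat(sprintf("Expected alteration positivity: %.1f%% malignant, %.1f%% benign\n",
            100 * pos["malignant"], 100 * pos["benign"]))
cat("Wrote results/cohort.csv\n")
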