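#!/usr/bin/env Rscript
# Stage 4 — Bayes-theorem projection of predictive values.
#
# Surgical cohorts of indeterminate nodules over-represent malignancy, so
# the cohort PPV/NPV do not transfer to other settings. This stage projects
# each score's predictive values across prevalence 1-99% from its exact
# fractional sensitivity/specificity, highlighting the 6-59% band typical
# of populations with indeterminate cytology.

suppressPackageStartupMessages(library(thyrostrat))

report <- run_evaluate("results/scored.csv")

curves <- do.call(rbind, lapply(c("x_us", "x_gc", "trs"), function(nm) {
  p <- report[[nm]]$performance
  cur <- prevalence_curve(p$sensitivity, p$specificity)
  cbind(score = nm, cur)
}))
utils::write.csv(curves, "results/prevalence_curves.csv", row.names = FALSE)

band <- curves[curves$prevalence %in% c(0.06, 0.28, 0.59), ]
cat("Projected predictive values at prevalence 6% / 28% / 59%:\n")
print(transform(band, ppv = round(100 * ppv, 1), npv = round(100 * npv, 1)),
      row.names = FALSE)
cat("Wrote results/prevalence_curves.csv\n")
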