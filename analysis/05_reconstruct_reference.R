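#!/usr/bin/env Rscript
# Stage 5 — reconstruct the reference pilot cohort from its printed values.
#
# Fully self-contained: recovers the integer 2x2 tables of the three scores
# from the bundled printed rounded metrics by exhaustive search, then
# recomputes every downstream statistic (balanced accuracies, Wilson CIs,
# the X_US odds ratio, the medullary-carcinoma exclusion, the Bayes
# projections) from the reconstructed tables.

suppressPackageStartupMessages(library(thyrostrat))

dir.create("results", showWarnings = FALSE)
r <- reproduce_pilot_study(out_path = "results/reference_report.json")

cat("Reconstructed tables (tp,fp,fn,tn):\n")
for (nm in c("x_us", "x_gc", "trs")) {
  cat(sprintf("  %-5s (%s)%s\n", toupper(nm),
              paste(r[[nm]]$matrix, collapse = ","),
              if (isTRUE(r[[nm]]$unique_solution)) " [unique]" else ""))
}
cat(sprintf("Balanced accuracies: X_US %.1f%%, X_GC %.1f%%, TRS %.1f%%\n",
            100 * r$x_us$balanced_accuracy, 100 * r$x_gc$balanced_accuracy,
            100 * r$trs$balanced_accuracy))
print(r$x_us_odds_ratio)
cat(sprintf("TRS sensitivity without medullary carcinomas: %.1f%%\n",
            100 * r$mtc_exclusion$performance$sensitivity))
cat(sprintf("Bayes TRS PPV at prevalence 0.28: %.1f%%\n",
            100 * r$bayes$trs_ppv_at_reference))
cat(sprintf("Bayes TRS PPV/NPV at prevalence 0.06: %.0f%% / %.0f%%\n",
            100 * r$bayes$trs_ppv_band[1], 100 * r$bayes$trs_npv_band[2]))
cat(sprintf("Printed X_GC PPV/NPV jointly consistent with sens/spec: %s\n",
            r$xgc_joint_consistent))
cat("Wrote results/reference_report.json\n")
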