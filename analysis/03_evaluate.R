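#!/usr/bin/env Rscript
# Stage 3 — diagnostic performance against histology.
#
# Dichotomizes each score at its cutoff (X_US >= 0.9, X_GC >= 0.6,
# TRS >= 0.7), tallies the 2x2 tables, and reports sensitivity/specificity/
# PPV/NPV with 95% Wilson intervals, balanced accuracy (the single-threshold
# ROC AUC), diagnostic odds ratios, and the per-candidate cutoff-selection
# table for each score.

suppressPackageStartupMessages(library(thyrostrat))

report <- run_evaluate("results/scored.csv", out_path = "results/report.json")

for (nm in c("x_us", "x_gc", "trs")) {
  blk <- report[[nm]]
  cat(sprintf("\n== %s (cutoff %.1f) ==\n", toupper(nm), blk$cutoff))
  cat(sprintf("matrix (tp,fp,fn,tn) = (%s)\n",
              paste(blk$matrix, collapse = ",")))
  print(blk$performance)
  print(blk$odds_ratio)
  cat(sprintf("selected cutoff by balanced accuracy: %.1f\n",
              blk$selected_cutoff))
  utils::write.csv(blk$cutoff_table,
                   sprintf("results/cutoff_table_%s.csv", nm),
                   row.names = FALSE)
}

# sensitivity comparison X_US vs TRS, unpaired z and paired McNemar
scored <- utils::read.csv("results/scored.csv", comment.char = "#")
mal <- scored$truth == "MALIGNANT"
z <- compare_proportions(
  sum(scored$x_us[mal] >= 0.9), sum(mal),
  sum(scored$trs[mal] >= 0.7 - 1e-9), sum(mal)
)
mc <- mcnemar_paired(scored$x_us[mal] >= 0.9, scored$trs[mal] >= 0.7 - 1e-9)
cat(sprintf("\nSensitivity X_US vs TRS: two-proportion z p = %.3g, McNemar p = %.3g\n",
            z$p_value, mc$p_value))
cat("Wrote results/report.json and per-score cutoff tables\n")
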