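#!/usr/bin/env Rscript
# Stage 2 — score the cohort.
#
# Applies the three-score system to results/cohort.csv: X_US from the ATA
# pattern, X_GC as the weighted sum of alterations (default weight table),
# TRS as their sum, plus the sequential management recommendation
# (surgery for X_US = 0.9 or TRS >= 0.7, surveillance otherwise).

suppressPackageStartupMessages(library(thyrostrat))

scored <- run_score("results/cohort.csv", out_path = "results/scored.csv")

cat(sprintf("Scored %d nodules -> results/scored.csv\n", nrow(scored)))
cat(sprintf("Recommendations: %d surgery, %d surveillance\n",
            sum(scored$recommendation == "SURGERY"),
            sum(scored$recommendation == "SURVEILLANCE")))
cat("Score summaries:\n")
print(summary(scored[c("x_us", "x_gc", "trs")]))
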