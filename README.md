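# thyrostrat

Risk stratification for thyroid nodules with indeterminate cytology
(Bethesda III/IV), combining ultrasound pattern and somatic-variant
evidence into a single management score.

## The problem

10–25% of thyroid fine-needle aspiration biopsies come back cytologically
indeterminate: not clearly benign, not clearly malignant. Many of these
patients undergo diagnostic surgery for what turns out to be benign
disease. Two independent lines of evidence can sharpen the decision — the
ATA sonographic pattern of the nodule and the somatic alterations found by
targeted sequencing — and this package implements a scoring system that
combines them, together with the statistical machinery needed to evaluate
such a system on a small surgical cohort and to project its performance to
populations with different cancer prevalence.

## The model

Each nodule gets three scores:

- **X_US** — the annotated ultrasound score, the upper bound of the ATA
  guideline malignancy risk for the nodule's sonographic pattern:
  benign/very-low 0, low 0.1, intermediate 0.2, high suspicion 0.9.
- **X_GC** — the genomic classifier score, an additive evidence model over
  the nodule's alterations, each weighted by its association with thyroid
  cancer (weights in [0, 1] per alteration; 0 = no association):

  X_GC = Σᵢ X_SNV/INDEL,i + X_GF + X_CNV

  summing over the n detected SNVs/INDELs plus the fusion and CNV terms.
  The score is not capped: multi-hit nodules exceed 1.
- **TRS** — the total risk score, TRS = X_US + X_GC.

Management is sequential: a high-suspicion pattern (X_US = 0.9) goes to
surgery without molecular testing (sequencing adds no specificity in that
stratum); otherwise surgery is considered when TRS ≥ 0.7 and surveillance
below.

Around the scores, the package provides: 2×2 confusion tables with
sensitivity/specificity/PPV/NPV and 95% Wilson intervals, balanced
accuracy (the ROC AUC of a dichotomized test), Woolf odds-ratio intervals,
cutoff selection with a specificity tie-break, subgroup exclusion,
two-proportion and McNemar comparisons, Bayes-theorem projection of
predictive values across prevalence, exhaustive reconstruction of integer
2×2 tables from published rounded percentages, and a reproducible
synthetic-cohort generator for end-to-end testing.

## Worked example

```r
library(thyrostrat)
path <- system.file("extdata", "example_cohort.csv", package = "thyrostrat")
run_score(path)
#>   nodule_id x_us x_gc  trs recommendation     truth
#> 1      N001  0.9 0.00 0.90        SURGERY MALIGNANT
#> 2      N002  0.2 0.95 1.15        SURGERY MALIGNANT
#> 3      N003  0.1 0.00 0.10   SURVEILLANCE    BENIGN
```

N001 has a high-suspicion pattern, so surgery is recommended regardless of
its (negative) molecular result. N002 is sonographically intermediate
(0.2) but carries BRAF p.Val600Glu (weight 0.95), so TRS = 1.15 ≥ 0.7 →
surgery. N003 is low-suspicion with no alterations: TRS = 0.1 →
surveillance.

Reconstructing the reference pilot cohort from its printed metrics alone:

```r
r <- reproduce_pilot_study()
r$trs$matrix                                  # tp fp fn tn = 22 3 4 18
round(100 * r$trs$balanced_accuracy, 1)       # 85.2
print(r$x_us_odds_ratio)                      # OR 5.03, 95% CI 0.95-26.6
round(100 * r$bayes$trs_ppv_at_reference, 1)  # 69.7 (PPV at prevalence 0.28)
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline and write
their tables under `results/`:

1. `01_simulate.R` — draw a 47-patient study-like synthetic cohort
2. `02_score.R` — compute X_US, X_GC, TRS and recommendations
3. `03_evaluate.R` — confusion tables, Wilson CIs, odds ratios, cutoff
   selection, score comparisons
4. `04_project_prevalence.R` — Bayes predictive-value curves over
   prevalence 1–99%
5. `05_reconstruct_reference.R` — recover the reference cohort's integer
   tables from printed values and recompute its statistics

Run them in order with `Rscript analysis/01_simulate.R` etc.
(`THYROSTRAT_SEED` overrides the simulation seed).

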