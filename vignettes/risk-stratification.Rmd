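---
title: "Combined ultrasound and genomic risk stratification of indeterminate thyroid nodules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined ultrasound and genomic risk stratification of indeterminate thyroid nodules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrostrat)
```

## The scoring system

A cytologically indeterminate nodule (Bethesda III/IV) carries a
malignancy risk too high to ignore and too low to justify surgery
outright. The system implemented here stratifies that risk from two
orthogonal measurements.

**Ultrasound score.** The five ATA sonographic patterns map to an
annotated score equal to the upper bound of the guideline malignancy-risk
band for the pattern: benign and very-low-suspicion 0, low 0.1 (≤10%
risk), intermediate 0.2 (≤20%), high suspicion 0.9 (≤90%). The mapping is
total and deterministic; its image is exactly {0, 0.1, 0.2, 0.9}.

**Genomic classifier score.** Each somatic alteration detected in the
nodule — SNV, INDEL, gene fusion, or CNV — carries a weight in [0, 1]
expressing its strength of association with thyroid cancer. The nodule's
score is the plain sum

$$X_{GC} = \sum_{i=1}^{n} X_{SNV/INDEL,i} + X_{GF} + X_{CNV},$$

with $n$ the number of SNVs/INDELs. This is an additive evidence model:
it is deliberately not capped at 1, because co-occurring driver events
(e.g. the NRAS + SLX4 + ATM profile of Hürthle cell carcinoma, or
BRAF V600E plus a TERT promoter mutation) represent more evidence of
malignancy than either event alone, and the downstream cutoff analysis
operates on the raw sum. Additivity also gives the score convenient
formal properties — order independence, and strict monotonicity in every
positive-weight alteration — which the test suite checks as invariants.

**Total risk score and management.** $TRS = X_{US} + X_{GC}$. Management
is sequential: X_US = 0.9 → surgery, molecular result ignored (in the
high-suspicion stratum sonography alone is already as specific as
sequencing, so testing adds cost, not information); otherwise surgery
when TRS ≥ 0.7, surveillance below. The cutoff is inclusive, and
dichotomization for performance evaluation uses the same inclusive rule
(score ≥ cutoff is test-positive) for all three scores at their cutoffs
(X_US ≥ 0.9, X_GC ≥ 0.6, TRS ≥ 0.7).

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| alteration weights | `default_weight_table()` | unitless, in [0, 1] |
| fallback weight | 0 | score for alterations absent from the table |
| X_US cutoff | 0.9 | high-suspicion pattern only |
| X_GC cutoff | 0.6 | excludes single RAS-type hits (weight 0.5) |
| TRS cutoff | 0.7 | inclusive; intermediate pattern + RAS reaches it |
| confidence level | 0.95 | Wilson and Woolf intervals |
| prevalence grid | 0.01–0.99 by 0.01 | Bayes projection |

The shipped weight table is an illustrative default, not fitted ground
truth: the qualitative ordering (BRAF V600E and activating RET point
mutations ≥ 0.9; TERT promoter high; RAS hotspots 0.5; PAX8-PPARG 0.55;
alterations shared with benign nodules — GNAS, ESR1, TET2 — low) follows
the usual prevalence ratios in large somatic-mutation databases, but the
exact values used by any particular laboratory's annotation are not
public, so analyses that depend on specific weights should supply their
own table (`read_weight_table()`, TSV or JSON). Two interactions between
defaults are load-bearing and intentional: a lone RAS-type mutation
(0.5) fails the X_GC cutoff (0.6) but reaches the TRS cutoff when the
nodule is sonographically intermediate (0.2 + 0.5 = 0.7), and the NIFTP
fusion weight (0.55) behaves the same way. That reproduces the clinically
observed pattern that the combined score rescues follicular-patterned,
RAS-driven malignancies that a genomic score alone misses.

Unknown alterations score the fallback weight (default 0) with a
collected warning rather than an error: pan-cancer panels routinely
report variants absent from any thyroid-specific weight table, and a
hard failure on each would make the tool unusable on real panel output.

## Statistical methods

**Wilson intervals.** All proportion CIs invert the score test (Wilson),
implemented in closed form and cross-checked in the tests against
`prop.test(correct = FALSE)`. Wilson endpoints never leave [0, 1] and the
interval never excludes the point estimate, which matters at the tiny
denominators of subgroup analyses (e.g. 11 high-suspicion nodules). Its
exact coverage oscillates with (n, p) and can dip to ~91.5% at n = 15;
pooled over a grid of binomial draws (n ∈ {15, 30, 47, 100, 200},
p ∈ 0.05–0.95) the empirical coverage sits near the nominal 95%, and the
acceptance suite asserts ≥ 93% pooled.

**Balanced accuracy as "diagnostic accuracy".** For a single-threshold
test the trapezoidal ROC AUC equals (sensitivity + specificity)/2; the
package reports this as the accuracy figure and the tests verify the
identity against an independent AUC computation (pROC) on the same data.
Raw accuracy (TP+TN)/n is not used: it would not reproduce the accuracy
figures that dichotomized-score analyses of this kind report, because
those are AUCs.

**Odds ratios.** Cross-product estimate with the log-normal (Woolf)
interval, z = 1.96 at 95%. Zero cells get the Haldane–Anscombe 0.5
correction on all four cells; the result is flagged. The Woolf interval
reproduces the reference X_US odds ratio (5.03, 0.95–26.6) exactly,
which is how the method choice was settled — the reference analysis does
not name its method.

**Cutoff selection.** Candidates are evaluated exhaustively; the highest
balanced accuracy wins. Candidates within `specificity_tiebreak_tol` of
the maximum are treated as statistically indistinguishable and the most
specific one is chosen — in this clinical setting a false positive is an
unnecessary surgery, so specificity breaks ties. Remaining exact ties go
to the first-listed candidate, making selection deterministic.

**Proportion comparisons.** The unpaired pooled two-proportion z-test is
the default; Fisher's exact test and a paired McNemar variant (for two
scores called on the same nodules) are provided. The package treats
p-values as descriptive here — with ~47 subjects none of these tests has
meaningful power beyond large effects.

**Bayes projection.** PPV and NPV are projected across prevalence from
exact fractional sensitivity/specificity:
$PPV(\pi) = se\,\pi / (se\,\pi + (1-sp)(1-\pi))$ and
$NPV(\pi) = sp(1-\pi) / (sp(1-\pi) + (1-se)\pi)$. At the prevalence
implied by the cohort's own margins the projection returns the
cohort-observed predictive values exactly (an identity the tests check),
so projected curves and observed values form one consistent family.
Projections from rounded printed sensitivities instead of exact fractions
shift third decimals; reports state which was used.

## Reconstructing 2×2 tables from printed metrics

Published diagnostic studies print rounded percentages, not tables.
`reconstruct_matrix()` enumerates every integer table (tp, fp, fn, tn)
summing to the cohort size and keeps those whose metrics, rounded to the
printed precision, equal the printed values. Conventions:

- **Rounding** is half-up on the percentage scale at the printed
  decimals — the convention that all verified reconstructions satisfy. A
  `"trunc"` mode (and `"either"`) exists because printed values are
  sometimes truncations: the reference genomic-score sensitivity 80.7% is
  21/26 = 80.769…%, which no integer table prints under half-up.
- **Uniqueness** is the caller's assertion, not the function's: the
  function returns all solutions. For the reference cohort the X_US and
  TRS quadruples each pin a unique table at n = 47 — (9, 2, 17, 19) and
  (22, 3, 4, 18) — which is what makes the whole reconstruction exercise
  well-posed.
- **Inconsistency is reported, not patched.** The reference cohort's
  printed X_GC PPV/NPV (92.3%, 80%) admit no integer table jointly with
  its sensitivity/specificity at any n ≤ 47 (`reproduce_pilot_study()`
  re-verifies this by exhaustive search), and the margins implied by
  sensitivity (26 malignant) and specificity (19 benign) do not even sum
  to 47. The X_GC view is therefore reconstructed margin-wise and is
  valid for sensitivity, specificity and balanced accuracy only. Relatedly,
  the reference histology table counts 28 malignant / 19 benign while
  every printed metric quadruple implies 26 / 21; both views are carried,
  and the reconstruction reports which margins each figure rests on.

## The synthetic cohort generator

`default_study_config()` emulates a 47-patient surgical cohort of
indeterminate nodules: malignancy prevalence 28/47; a malignant histology
mix of 11 classic papillary, 4 micro-papillary, 6 follicular-variant, 1
NIFTP, 2 Hürthle cell, 1 poorly differentiated and 3 medullary
carcinomas (NIFTP is counted malignant, matching reference practice of
listing it under carcinoma); benign nodules split 6 follicular adenomas /
13 adenomatoid nodules. Ultrasound patterns are drawn conditionally on
malignancy (high suspicion 9/26 among cancers vs 2/21 among benign, the
split implied by the reconstructed X_US table), and alterations are drawn
per histology from locus-structured spectra: each locus holds mutually
exclusive options, so joint multi-hit profiles (Hürthle NRAS+SLX4+ATM;
the rare BRAF+TERT papillary carcinoma) are modeled without double-drawing
a gene, while distinct loci stay independent. Event probabilities were
calibrated once, analytically, to the reference marginals — about 78.5%
of malignant and 36.8% of benign nodules alteration-positive
(`implied_positivity()` returns the exact expectations, 78.7% / 36.5%) —
and then frozen.

Draws come from one seeded stream in a documented per-nodule order
(malignancy, histology, pattern, loci in listed order), so cohorts are
bit-reproducible from the seed and extending a spectrum never silently
reorders existing draws.

`implied_performance()` computes the configuration's exact operating
characteristics by enumeration (pattern and genotype are conditionally
independent given histology, and each histology's X_GC distribution is a
small discrete convolution). The parameter-recovery test generates
20,000 nodules and requires empirical sensitivity/specificity of all
three dichotomized scores within ±1.5 percentage points of these exact
values. That is a self-consistency check of generator + scorer + tallies;
it does not validate the generator against real patients. Real cohorts
differ in ways the generator does not model: allele fractions and
sequencing noise, nodule size and growth, correlated sonographic
features within a pattern, site-specific histology mixes, and
per-nodule genotype correlations beyond the modeled joint events.
Passing tests therefore demonstrate the pipeline's correctness, not
clinical performance.

## Numerical conventions and degenerate inputs

- Score comparisons use an absolute tolerance of 1e-9, because the score
  lattice is decimal and 0.2 + 0.5 must count as ≥ 0.7 despite binary
  floating point.
- Metrics with zero denominators (e.g. PPV when nothing is called
  positive) are explicit `NA` markers with `NA` intervals — never
  silently 0 — since small-stratum subgroup analyses hit them routinely.
- Cutoff selection and evaluation refuse single-class truth vectors; the
  confusion tally refuses empty and length-mismatched input; cohort files
  carrying both `us_pattern` and `x_us` must agree row-wise.
- Problem sizes in the shipped tests: exhaustive table enumeration at
  n = 47 (~2·10⁴ tables), Wilson coverage on 95 grid cells × 2000 draws,
  parameter recovery at n = 20,000, property loops at 10–50 replicates —
  sizes chosen so each check is decisive at desk scale.

## Known limitations

- The weight table is a documented stand-in; the system's discrimination
  is as good as the weights a laboratory supplies.
- The reconstruction logic targets printed percentages of the four
  standard metrics; it does not attempt to invert other summaries
  (likelihood ratios, AUCs with CIs).
- Prevalence projection treats sensitivity and specificity as
  prevalence-invariant, the standard Bayes-theorem assumption; spectrum
  effects (case mix changing with prevalence) violate it in practice.
- The management algorithm encodes exactly the five-pattern ATA system;
  TI-RADS-style "not classifiable" categories are out of scope, as are
  extent-of-surgery decisions from high-risk signatures.
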