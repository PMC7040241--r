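#' Published summary statistics of the reference pilot cohort
#'
#' The risk-stratification system was developed on a 47-patient surgical
#' pilot cohort of cytologically indeterminate nodules. Its publication
#' prints the rounded performance metrics of the three scores at their
#' selected cutoffs but not the underlying 2x2 tables; this function bundles
#' those printed values (percentage, printed decimals) so that
#' [reproduce_pilot_study()] can reconstruct the integer tables with
#' [reconstruct_matrix()] and recompute every downstream statistic from
#' scratch.
#'
#' Two quirks of the printed tables, preserved here deliberately: the X_GC
#' sensitivity 80.7% is a truncation of 21/26 (no integer table prints 80.7
#' under half-up rounding), and the printed X_GC PPV/NPV pair is not jointly
#' consistent with its sensitivity/specificity for any integer table, so the
#' X_GC entry carries sensitivity/specificity only.
#'
#' @return a list with elements `n_total`, `cutoffs`, and per-score printed
#'   metric blocks (`x_us`, `x_gc`, `trs`), each a list of
#'   `c(value, decimals)` entries; plus `mtc_exclusion` (the number of
#'   medullary carcinomas, all true positives of TRS, removed in the
#'   subgroup analysis) and `prevalence_band` (the 6-59% projection range).
#' @export
pilot_study_metrics <- function() {
  list(
    n_total = 47L,
    cutoffs = c(x_us = 0.9, x_gc = 0.6, trs = 0.7),
    x_us = list(
      sensitivity = c(34.6, 1),
      specificity = c(90, 0),
      ppv = c(81.8, 1),
      npv = c(52.8, 1)
    ),
    x_gc = list(
      sensitivity = c(80.7, 1),
      specificity = c(94.7, 1)
    ),
    trs = list(
      sensitivity = c(84.6, 1),
      specificity = c(85.7, 1),
      ppv = c(88, 0),
      npv = c(81.8, 1)
    ),
    mtc_exclusion = list(tp = 3L),
    prevalence_band = c(low = 0.06, high = 0.59),
    trs_ppv_reference_prevalence = 0.28
  )
}
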