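#' End-to-end pipeline stages
#'
#' Thin orchestration over the scoring and statistics modules: score a
#' cohort file, evaluate the three dichotomized scores against histology,
#' project predictive values across prevalence, and reproduce the reference
#' pilot cohort's statistics from its printed values alone. Every stage
#' takes and returns plain data frames/lists and optionally writes
#' versioned CSV/JSON, so the numbered analysis scripts and the tests share
#' the exact same code paths.
#'
#' @name pipeline
NULL

#' Score a cohort end to end
#'
#' @param cohort a cohort data frame or a path to a cohort CSV (see
#'   [read_cohort()]).
#' @param weights a [weight_table()] or a path to a weight table TSV/JSON;
#'   default [default_weight_table()].
#' @param out_path optional CSV path for the scored cohort.
#' @param trs_cutoff management cutoff, default 0.7.
#' @return the scored data frame from [score_cohort()], invisibly carrying
#'   an attribute `n_unknown` with the number of fallback-scored
#'   alterations.
#' @export
run_score <- function(cohort, weights = default_weight_table(),
                      out_path = NULL, trs_cutoff = 0.7) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(weights)) weights <- read_weight_table(weights)
  unknown <- character(0)
  scored <- withCallingHandlers(
    score_cohort(cohort, weights, trs_cutoff = trs_cutoff),
    thyrostrat_unknown_alteration = function(w) {
      unknown <<- c(unknown, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (length(unknown)) {
    warning(sprintf("%d alteration(s) scored by fallback weight", length(unknown)),
            call. = FALSE)
  }
  attr(scored, "n_unknown") <- length(unknown)
  if (!is.null(out_path)) {
    con <- file(out_path, open = "wt", encoding = "UTF-8")
    writeLines("# format_version: 1", con)
    utils::write.csv(scored, con, row.names = FALSE)
    close(con)
  }
  scored
}

#' Evaluate the three scores on a scored cohort
#'
#' Dichotomizes X_US, X_GC and TRS at their cutoffs (score >= cutoff is
#' test-positive), computes full performance with Wilson intervals, the
#' diagnostic odds ratio, and the per-candidate cutoff-selection table for
#' each score.
#'
#' @param scored a scored data frame from [run_score()] (or its CSV path);
#'   must have non-missing `truth`.
#' @param cutoffs named numeric `c(x_us =, x_gc =, trs =)`.
#' @param conf_level confidence level, default 0.95.
#' @param candidates named list of candidate cutoff vectors per score for
#'   the selection table; defaults to each score's observed support.
#' @param out_path optional JSON path for the report.
#' @return a list with one block per score: `cutoff`, `matrix` (cell
#'   counts), `performance`, `odds_ratio`, `cutoff_table`, `selected_cutoff`.
#' @export
run_evaluate <- function(scored, cutoffs = c(x_us = 0.9, x_gc = 0.6, trs = 0.7),
                         conf_level = 0.95, candidates = NULL,
                         out_path = NULL) {
  if (is.character(scored)) {
    scored <- utils::read.csv(scored, comment.char = "#",
                              stringsAsFactors = FALSE)
  }
  if (!"truth" %in% names(scored) || anyNA(parse_truth(scored$truth))) {
    stop_input("missing truth labels: evaluation needs reference histology")
  }
  truth <- parse_truth(scored$truth)
  if (length(unique(truth)) < 2L) {
    stop_input("degenerate input: truth has a single class")
  }
  report <- list()
  for (score_name in c("x_us", "x_gc", "trs")) {
    scores <- scored[[score_name]]
    cut <- cutoffs[[score_name]]
    m <- confusion_from_scores(scores, truth, cut)
    cand <- candidates[[score_name]] %||% sort(unique(scores[scores > 0]))
    if (!length(cand)) cand <- cut  # constant score: only the configured cutoff
    sel <- select_cutoff(scores, truth, cand)
    report[[score_name]] <- list(
      cutoff = cut,
      matrix = c(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn),
      performance = performance(m, conf_level),
      odds_ratio = odds_ratio(m, conf_level),
      cutoff_table = sel$table,
      selected_cutoff = sel$cutoff
    )
  }
  if (!is.null(out_path)) write_report_json(report, out_path)
  report
}

#' @keywords internal
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "diagnostic_performance")) {
      x$matrix <- c(tp = x$matrix$tp, fp = x$matrix$fp,
                    fn = x$matrix$fn, tn = x$matrix$tn)
      x <- unclass(x)
    }
    if (inherits(x, "odds_ratio_result")) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) x <- lapply(x, strip)
    x
  }
  payload <- c(list(format_version = 1), strip(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Reproduce the reference pilot cohort's statistics from printed values
#'
#' Self-contained reconstruction run: recovers the integer 2x2 tables of
#' the three scores from the bundled printed rounded metrics
#' ([pilot_study_metrics()]) by exhaustive search, then recomputes forward
#' performance, Wilson intervals, balanced accuracies, the X_US odds ratio,
#' the medullary-carcinoma exclusion sub-analysis and the Bayes
#' predictive-value projections.
#'
#' The X_GC block is reconstructed from its sensitivity and specificity
#' margins separately (its printed PPV/NPV are jointly inconsistent with
#' them for every integer table — `xgc_joint_consistent` records the
#' exhaustive-search verdict — and the two margins they imply do not even
#' sum to the cohort size, recorded in `xgc_margins_consistent`). The
#' assembled X_GC matrix is therefore a per-margin view, valid for
#' sensitivity, specificity and balanced accuracy but not for predictive
#' values.
#'
#' @param out_path optional JSON report path.
#' @return a list with blocks `x_us`, `x_gc`, `trs` (each: reconstructed
#'   `matrix`, uniqueness flag, `performance`, `balanced_accuracy`),
#'   `x_us_odds_ratio`, `mtc_exclusion` (TRS without the medullary
#'   carcinomas), `bayes` (projections at the reference prevalences) and
#'   `xgc_joint_consistent` (FALSE: no integer table matches all four
#'   printed X_GC metrics).
#' @export
reproduce_pilot_study <- function(out_path = NULL) {
  pm <- pilot_study_metrics()
  n <- pm$n_total

  sol_xus <- reconstruct_matrix(pm$x_us, n)
  sol_trs <- reconstruct_matrix(pm$trs, n)
  stopifnot(length(sol_xus) >= 1L, length(sol_trs) >= 1L)
  m_xus <- sol_xus[[1L]]
  m_trs <- sol_trs[[1L]]

  # The X_GC margins are reconstructed separately: its printed sensitivity
  # and specificity imply truth margins (26 malignant, 19 benign) that do
  # not sum to the cohort size, so no whole-table search can satisfy both.
  # Each margin search is bounded by the corresponding margin of the other
  # two scores' shared table.
  sens_sol <- reconstruct_proportion(pm$x_gc$sensitivity[1],
                                     pm$x_gc$sensitivity[2],
                                     max_n = m_trs$tp + m_trs$fn,
                                     rounding = "either")
  spec_sol <- reconstruct_proportion(pm$x_gc$specificity[1],
                                     pm$x_gc$specificity[2],
                                     max_n = m_trs$fp + m_trs$tn,
                                     rounding = "either")
  stopifnot(nrow(sens_sol) >= 1L, nrow(spec_sol) >= 1L)
  s1 <- sens_sol[nrow(sens_sol), ]  # largest consistent margin
  s2 <- spec_sol[nrow(spec_sol), ]
  m_xgc <- confusion_matrix(tp = s1$k, fp = s2$n - s2$k,
                            fn = s1$n - s1$k, tn = s2$k)
  sol_xgc <- list(m_xgc)
  xgc_margins_consistent <-
    nrow(sens_sol) == 1L && nrow(spec_sol) == 1L && s1$n + s2$n == n

  # the printed X_GC PPV/NPV (92.3 / 80) admit no joint integer table with
  # its sensitivity/specificity at any n up to the cohort size
  joint <- lapply(seq_len(n), function(nn) {
    reconstruct_matrix(
      c(pm$x_gc, list(ppv = c(92.3, 1), npv = c(80, 0))), nn,
      rounding = "either"
    )
  })
  xgc_joint_consistent <- any(lengths(joint) > 0)

  perf_trs <- performance(m_trs)
  sens <- perf_trs$sensitivity
  spec <- perf_trs$specificity
  band <- pm$prevalence_band
  # prevalence implied by the reconstructed truth margins; at this value the
  # Bayes projection reproduces the cohort-observed predictive values exactly
  cohort_prev <- (m_trs$tp + m_trs$fn) / n
  bayes <- list(
    trs_ppv_at_reference = bayes_ppv(sens, spec,
                                     pm$trs_ppv_reference_prevalence),
    trs_ppv_band = c(bayes_ppv(sens, spec, band[["low"]]),
                     bayes_ppv(sens, spec, band[["high"]])),
    trs_npv_band = c(bayes_npv(sens, spec, band[["high"]]),
                     bayes_npv(sens, spec, band[["low"]])),
    cohort_prevalence = cohort_prev,
    trs_ppv_at_cohort_prevalence = bayes_ppv(sens, spec, cohort_prev),
    trs_npv_at_cohort_prevalence = bayes_npv(sens, spec, cohort_prev)
  )

  m_mtc <- exclude_subgroup(m_trs, tp = pm$mtc_exclusion$tp)

  block <- function(m, solutions) {
    list(
      matrix = c(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn),
      unique_solution = length(solutions) == 1L,
      performance = performance(m),
      balanced_accuracy = balanced_accuracy(m)
    )
  }
  report <- list(
    x_us = block(m_xus, sol_xus),
    x_gc = block(m_xgc, sol_xgc),
    trs = block(m_trs, sol_trs),
    x_us_odds_ratio = odds_ratio(m_xus),
    mtc_exclusion = list(
      matrix = c(tp = m_mtc$tp, fp = m_mtc$fp, fn = m_mtc$fn, tn = m_mtc$tn),
      performance = performance(m_mtc)
    ),
    bayes = bayes,
    xgc_joint_consistent = xgc_joint_consistent,
    xgc_margins_consistent = xgc_margins_consistent
  )
  if (!is.null(out_path)) write_report_json(report, out_path)
  report
}

#' Record a run manifest
#'
#' Captures every input that determines a run's outputs, so any two runs
#' with identical manifests produce identical payloads.
#'
#' @param inputs named list/character of input paths.
#' @param cutoffs named numeric cutoffs.
#' @param conf_level confidence level.
#' @param prevalence_grid prevalence grid used for projections.
#' @param seed RNG seed.
#' @param output_dir output directory.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = list(), cutoffs = c(x_us = 0.9, x_gc = 0.6,
                                                      trs = 0.7),
                         conf_level = 0.95,
                         prevalence_grid = seq(0.01, 0.99, by = 0.01),
                         seed = 1L, output_dir = ".") {
  structure(
    list(
      inputs = inputs,
      cutoffs = cutoffs,
      conf_level = conf_level,
      prevalence_grid = prevalence_grid,
      seed = as.integer(seed),
      output_dir = output_dir,
      tool_version = as.character(utils::packageVersion("thyrostrat"))
    ),
    class = "run_manifest"
  )
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path config file; format by extension (`.json`, `.yaml`/`.yml`).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
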