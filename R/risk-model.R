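#' Total risk score and management recommendation
#'
#' The total risk score of a nodule is the plain sum of its ultrasound and
#' genomic classifier scores, `TRS = X_US + X_GC`. Management follows a
#' sequential rule: a high-suspicion sonographic pattern (X_US = 0.9) is
#' referred to surgery regardless of the molecular result (molecular testing
#' adds no specificity in that stratum); otherwise surgery is recommended
#' when TRS reaches the cutoff (default 0.7, inclusive) and active
#' surveillance below it.
#'
#' @name risk_model
NULL

#' Compute the total risk score
#'
#' @param x_us ultrasound score, one of 0, 0.1, 0.2, 0.9 (vectorized).
#' @param x_gc genomic classifier score, non-negative (vectorized).
#' @return `x_us + x_gc`.
#' @examples
#' compute_trs(0.2, 0.5)
#' @export
compute_trs <- function(x_us, x_gc) {
  ok <- vapply(x_us, function(u) any(abs(u - XUS_BY_PATTERN) < SCORE_TOL),
               logical(1))
  if (!all(ok)) {
    stop_input("x_us must be one of 0, 0.1, 0.2, 0.9 (got %g)", x_us[!ok][1L])
  }
  if (any(x_gc < 0)) stop_input("x_gc must be non-negative")
  x_us + x_gc
}

#' Management recommendation for a scored nodule
#'
#' @param x_us ultrasound score(s).
#' @param trs total risk score(s); must satisfy `trs >= x_us`.
#' @param trs_cutoff surgery cutoff on TRS, inclusive; default 0.7.
#' @return character vector, `"SURGERY"` or `"SURVEILLANCE"`.
#' @details Comparisons use a small absolute tolerance so that decimal score
#'   sums sitting exactly on the cutoff (e.g. 0.2 + 0.5) classify as at the
#'   cutoff despite floating-point representation.
#' @examples
#' classify_management(0.9, 0.9)   # high-suspicion pattern: surgery
#' classify_management(0.2, 0.7)   # at cutoff: surgery
#' classify_management(0.1, 0.65)  # below cutoff: surveillance
#' @export
classify_management <- function(x_us, trs, trs_cutoff = 0.7) {
  if (any(trs < x_us - SCORE_TOL)) {
    stop_input("trs must be at least x_us (x_gc cannot be negative)")
  }
  high_us <- gte_tol(x_us, 0.9)
  ifelse(high_us | gte_tol(trs, trs_cutoff), "SURGERY", "SURVEILLANCE")
}

#' Score a cohort of nodules
#'
#' Joins the ultrasound and genomic scores of each nodule, computes the
#' total risk score, and attaches the management recommendation.
#'
#' @param cohort a data frame with columns `nodule_id`, an ultrasound
#'   assessment (`us_pattern` names and/or numeric `x_us`; if both are
#'   present they must agree), an `alterations` column (semicolon-joined
#'   alteration identifiers, `""` for none), and optionally `truth`
#'   (`"MALIGNANT"`/`"BENIGN"`).
#' @param wt a [weight_table()]; default [default_weight_table()].
#' @param trs_cutoff management cutoff on TRS; default 0.7.
#' @param warn_unknown warn about alterations missing from the weight table.
#' @return a data frame with columns `nodule_id`, `x_us`, `x_gc`, `trs`,
#'   `recommendation` and `truth` (NA when no histology is available).
#' @export
score_cohort <- function(cohort, wt = default_weight_table(),
                         trs_cutoff = 0.7, warn_unknown = TRUE) {
  stopifnot(is.data.frame(cohort))
  if (!nrow(cohort)) stop_input("empty input: cohort has no rows")
  if (!"nodule_id" %in% names(cohort)) stop_input("cohort lacks 'nodule_id'")

  has_pat <- "us_pattern" %in% names(cohort)
  has_xus <- "x_us" %in% names(cohort)
  if (!has_pat && !has_xus) {
    stop_input("cohort needs 'us_pattern' or 'x_us'")
  }
  if (has_pat) {
    pat <- parse_us_pattern(cohort$us_pattern)
    x_us <- unname(XUS_BY_PATTERN[pat])
    if (has_xus && any(abs(x_us - as.numeric(cohort$x_us)) > SCORE_TOL)) {
      i <- which(abs(x_us - as.numeric(cohort$x_us)) > SCORE_TOL)[1L]
      stop_input("us_pattern and x_us disagree for nodule '%s'",
                 cohort$nodule_id[i])
    }
  } else {
    x_us <- unname(XUS_BY_PATTERN[parse_us_pattern(as.numeric(cohort$x_us))])
  }

  alt_col <- cohort$alterations %||% rep("", nrow(cohort))
  x_gc <- vapply(seq_len(nrow(cohort)), function(i) {
    alts <- parse_alteration_field(alt_col[i])
    compute_xgc(alts, wt, nodule_id = cohort$nodule_id[i],
                warn_unknown = warn_unknown)$x_gc
  }, numeric(1))

  trs <- compute_trs(x_us, x_gc)
  truth <- if ("truth" %in% names(cohort)) {
    parse_truth(cohort$truth)
  } else {
    rep(NA_character_, nrow(cohort))
  }
  data.frame(
    nodule_id = as.character(cohort$nodule_id),
    x_us = x_us,
    x_gc = x_gc,
    trs = trs,
    recommendation = classify_management(x_us, trs, trs_cutoff),
    truth = truth,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
parse_truth <- function(x) {
  out <- toupper(trimws(as.character(x)))
  out[out %in% c("", "NA")] <- NA_character_
  bad <- !is.na(out) & !out %in% c("MALIGNANT", "BENIGN")
  if (any(bad)) stop_input("truth must be MALIGNANT or BENIGN (got '%s')",
                           x[bad][1L])
  out
}
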