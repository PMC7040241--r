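#' Synthetic cohorts of cytologically indeterminate thyroid nodules
#'
#' Generates cohorts with the statistical structure of a surgical pilot
#' cohort of Bethesda III/IV nodules: a malignancy prevalence near 60%
#' (referral and selection bias towards cancer), histology mixes typical of
#' such cohorts, histology-conditional somatic alteration spectra (BRAF
#' p.Val600Glu dominating papillary carcinoma, RAS variants in
#' follicular-patterned tumors, RET alterations in medullary carcinoma,
#' PAX8-PPARG fusion in NIFTP, multi-hit NRAS/SLX4/ATM profiles in Hürthle
#' cell carcinoma, sparse RAS/GNAS/ESR1/ATM/TET2 events in benign nodules)
#' and malignancy-conditional ATA ultrasound patterns.
#'
#' Alteration spectra are expressed as independent "loci" per histology;
#' each locus carries mutually exclusive options (each an alteration set
#' with a probability; the remainder is "no event at this locus"). Joint
#' multi-hit profiles (Hürthle cell NRAS+SLX4+ATM, the rare BRAF+TERT
#' papillary carcinoma) are single options, so co-occurrence is modeled
#' without double-drawing a gene.
#'
#' @name synthetic_cohort
NULL

MALIGNANT_HISTOLOGIES <- c("PTC", "PTCFV", "MICRO_PTC", "NIFTP", "HTC",
                           "PDTC", "MTC")
BENIGN_HISTOLOGIES <- c("FOLLICULAR_ADENOMA", "ADENOMATOID_NODULE")

#' @keywords internal
locus <- function(...) {
  opts <- list(...)
  total <- sum(vapply(opts, function(o) o$prob, numeric(1)))
  if (total > 1 + 1e-9) stop_input("locus option probabilities exceed 1")
  opts
}

#' @keywords internal
option <- function(prob, ...) {
  list(prob = prob, alterations = list(...))
}

alt <- function(gene, class, detail) genomic_alteration(gene, class, detail)

#' Construct a cohort configuration
#'
#' @param n_patients cohort size.
#' @param malignancy_prevalence probability a nodule is malignant, in (0,1).
#' @param histology_mix named numeric: probabilities over histologies,
#'   summing to 1 within the malignant and within the benign class (each
#'   class's block is renormalized conditional on the malignancy draw).
#' @param alteration_spectrum named list: per histology, a list of loci (see
#'   \link{synthetic_cohort}).
#' @param us_pattern_dist list with `malignant` and `benign` named numeric
#'   distributions over the five ATA patterns, each summing to 1.
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, malignancy_prevalence, histology_mix,
                          alteration_spectrum, us_pattern_dist, seed = 1L) {
  if (malignancy_prevalence < 0 || malignancy_prevalence > 1) {
    stop_input("prevalence must lie in [0, 1]")
  }
  bad_hist <- setdiff(names(histology_mix),
                      c(MALIGNANT_HISTOLOGIES, BENIGN_HISTOLOGIES))
  if (length(bad_hist)) stop_input("unknown histology '%s'", bad_hist[1])
  for (class_set in list(MALIGNANT_HISTOLOGIES, BENIGN_HISTOLOGIES)) {
    p <- histology_mix[intersect(names(histology_mix), class_set)]
    if (malignancy_prevalence > 0 && identical(class_set, MALIGNANT_HISTOLOGIES) ||
        malignancy_prevalence < 1 && identical(class_set, BENIGN_HISTOLOGIES)) {
      if (abs(sum(p) - 1) > 1e-9) {
        stop_input("histology_mix must sum to 1 within each malignancy class")
      }
    }
  }
  for (nm in names(us_pattern_dist)) {
    d <- us_pattern_dist[[nm]]
    if (!all(names(d) %in% ATA_PATTERNS) || abs(sum(d) - 1) > 1e-9) {
      stop_input("us_pattern_dist$%s must be a distribution over ATA patterns", nm)
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      malignancy_prevalence = malignancy_prevalence,
      histology_mix = histology_mix,
      alteration_spectrum = alteration_spectrum,
      us_pattern_dist = us_pattern_dist,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default study-like cohort configuration
#'
#' Encodes the structure of a 47-patient surgical pilot cohort: malignancy
#' prevalence 28/47, a malignant histology mix of 11 classic PTC, 4
#' micro-PTC, 6 follicular-variant PTC, 1 NIFTP, 2 Hürthle cell, 1 poorly
#' differentiated and 3 medullary carcinomas (NIFTP counts as malignant; the
#' benign side is 6 follicular adenomas and 13 adenomatoid nodules).
#' Alteration probabilities are calibrated so that, in expectation, about
#' 78.5% of malignant and 36.8% of benign nodules carry at least one
#' detectable alteration, with BRAF p.Val600Glu concentrated in papillary
#' histologies and RAS variants in follicular-patterned tumors. Ultrasound
#' patterns are drawn conditionally on malignancy with the high-suspicion
#' pattern enriched among cancers (9/26 vs 2/21).
#'
#' @param n_patients cohort size, default 47.
#' @param seed RNG seed, default 1.
#' @return a [cohort_config()].
#' @export
default_study_config <- function(n_patients = 47, seed = 1L) {
  spectrum <- list(
    PTC = list(
      locus(option(0.80, alt("BRAF", "SNV", "p.Val600Glu")),
            option(0.05, alt("BRAF", "SNV", "p.Val600Glu"),
                         alt("TERT", "SNV", "c.1-124C>T")))
    ),
    MICRO_PTC = list(
      locus(option(0.63, alt("BRAF", "SNV", "p.Val600Glu")))
    ),
    PTCFV = list(
      locus(option(0.35, alt("BRAF", "SNV", "p.Val600Glu"))),
      locus(option(0.40, alt("NRAS", "SNV", "p.Gln61Arg")))
    ),
    NIFTP = list(
      locus(option(0.95, alt("PAX8", "GENE_FUSION", "PAX8-PPARG")))
    ),
    HTC = list(
      locus(option(0.90, alt("NRAS", "SNV", "p.Gln61Arg"),
                         alt("SLX4", "SNV", "pathogenic"),
                         alt("ATM", "SNV", "pathogenic")))
    ),
    PDTC = list(
      locus(option(0.85, alt("HRAS", "SNV", "p.Gln61Arg")))
    ),
    MTC = list(
      locus(option(0.40, alt("RET", "SNV", "p.Met918Thr")),
            option(0.30, alt("RET", "SNV", "p.Cys634Arg")),
            option(0.27, alt("RET", "CNV", "deletion")))
    ),
    FOLLICULAR_ADENOMA = list(
      locus(option(0.15, alt("NRAS", "SNV", "p.Gln61Lys"))),
      locus(option(0.08, alt("HRAS", "SNV", "p.Gln61Arg"))),
      locus(option(0.06, alt("GNAS", "SNV", "p.Arg201Cys"))),
      locus(option(0.10, alt("ATM", "SNV", "pathogenic"))),
      locus(option(0.06, alt("TET2", "SNV", "pathogenic")))
    ),
    ADENOMATOID_NODULE = list(
      locus(option(0.14, alt("GNAS", "SNV", "p.Arg201Cys"))),
      locus(option(0.11, alt("ESR1", "SNV", "pathogenic"))),
      locus(option(0.09, alt("ATM", "SNV", "pathogenic"))),
      locus(option(0.08, alt("TET2", "SNV", "pathogenic")))
    )
  )
  cohort_config(
    n_patients = n_patients,
    malignancy_prevalence = 28 / 47,
    histology_mix = c(
      PTC = 11 / 28, MICRO_PTC = 4 / 28, PTCFV = 6 / 28, NIFTP = 1 / 28,
      HTC = 2 / 28, PDTC = 1 / 28, MTC = 3 / 28,
      FOLLICULAR_ADENOMA = 6 / 19, ADENOMATOID_NODULE = 13 / 19
    ),
    alteration_spectrum = spectrum,
    us_pattern_dist = list(
      malignant = c(BENIGN = 0, VERY_LOW = 0, LOW = 6 / 26,
                    INTERMEDIATE = 11 / 26, HIGH = 9 / 26),
      benign = c(BENIGN = 0, VERY_LOW = 0, LOW = 11 / 21,
                 INTERMEDIATE = 8 / 21, HIGH = 2 / 21)
    ),
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws are consumed from a single stream in a fixed per-nodule order —
#' malignancy, histology, ultrasound pattern, then one draw per alteration
#' locus in its listed order — so extending a spectrum never silently
#' reorders existing draws. The caller's RNG state is restored on exit.
#'
#' @param config a [cohort_config()].
#' @return a data frame with columns `nodule_id, histology, truth,
#'   us_pattern, alterations` (alterations as semicolon-joined canonical
#'   identifiers).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  mix <- config$histology_mix
  mal_mix <- mix[intersect(names(mix), MALIGNANT_HISTOLOGIES)]
  ben_mix <- mix[intersect(names(mix), BENIGN_HISTOLOGIES)]

  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    malignant <- stats::runif(1) < config$malignancy_prevalence
    class_mix <- if (malignant) mal_mix else ben_mix
    histology <- sample(names(class_mix), 1L, prob = class_mix)
    pdist <- config$us_pattern_dist[[if (malignant) "malignant" else "benign"]]
    pattern <- sample(names(pdist), 1L, prob = pdist)
    alts <- list()
    for (loc in config$alteration_spectrum[[histology]] %||% list()) {
      u <- stats::runif(1)
      edge <- 0
      for (opt in loc) {
        edge <- edge + opt$prob
        if (u < edge) {
          alts <- c(alts, opt$alterations)
          break
        }
      }
    }
    rows[[i]] <- data.frame(
      nodule_id = sprintf("N%03d", i),
      histology = histology,
      truth = if (malignant) "MALIGNANT" else "BENIGN",
      us_pattern = pattern,
      alterations = format_alteration_field(alts),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Exact distribution of X_GC for one histology
#'
#' Convolves the locus options of a histology's spectrum under a weight
#' table, returning the exact discrete distribution of the genomic
#' classifier score.
#'
#' @param spectrum a list of loci for one histology.
#' @param wt a [weight_table()].
#' @return a data frame with columns `x_gc`, `prob` (probabilities sum to 1).
#' @keywords internal
xgc_distribution <- function(spectrum, wt) {
  dist <- c("0" = 1)
  for (loc in spectrum) {
    none_p <- 1 - sum(vapply(loc, function(o) o$prob, numeric(1)))
    shifts <- c(
      list(list(prob = none_p, delta = 0)),
      lapply(loc, function(o) {
        list(prob = o$prob,
             delta = compute_xgc(o$alterations, wt, warn_unknown = FALSE)$x_gc)
      })
    )
    new <- numeric(0)
    for (v in names(dist)) {
      for (s in shifts) {
        if (s$prob <= 0) next
        key <- sprintf("%.10f", as.numeric(v) + s$delta)
        new[key] <- (if (key %in% names(new)) new[key] else 0) +
          dist[[v]] * s$prob
      }
    }
    dist <- new
  }
  data.frame(x_gc = as.numeric(names(dist)), prob = unname(dist))
}

#' Config-implied operating characteristics
#'
#' Computes, by exact enumeration (no simulation), the sensitivity and
#' specificity that a configuration implies for the three dichotomized
#' scores under a weight table: X_US >= its cutoff, X_GC >= its cutoff and
#' TRS >= its cutoff. Ultrasound pattern and genotype are conditionally
#' independent given histology, so the TRS positivity probability is the
#' pattern-weighted tail probability of the X_GC distribution.
#'
#' @param config a [cohort_config()].
#' @param wt a [weight_table()]; default [default_weight_table()].
#' @param cutoffs named numeric: `x_us`, `x_gc`, `trs` cutoffs; defaults
#'   `c(x_us = 0.9, x_gc = 0.6, trs = 0.7)`.
#' @return a data frame with one row per score (`x_us`, `x_gc`, `trs`) and
#'   columns `score`, `sensitivity`, `specificity`.
#' @export
implied_performance <- function(config, wt = default_weight_table(),
                                cutoffs = c(x_us = 0.9, x_gc = 0.6, trs = 0.7)) {
  stopifnot(inherits(config, "cohort_config"))
  mix <- config$histology_mix
  class_rates <- function(histologies, pdist) {
    p_hist <- mix[intersect(names(mix), histologies)]
    p_hist <- p_hist / sum(p_hist)
    xus_vals <- unname(XUS_BY_PATTERN[names(pdist)])
    pos <- c(x_us = 0, x_gc = 0, trs = 0)
    pos["x_us"] <- sum(pdist[gte_tol(xus_vals, cutoffs["x_us"])])
    for (h in names(p_hist)) {
      d <- xgc_distribution(config$alteration_spectrum[[h]] %||% list(), wt)
      tail_p <- function(thresh) sum(d$prob[gte_tol(d$x_gc, thresh)])
      pos["x_gc"] <- pos["x_gc"] + p_hist[[h]] * tail_p(cutoffs["x_gc"])
      trs_h <- sum(vapply(seq_along(pdist), function(j) {
        pdist[[j]] * tail_p(cutoffs["trs"] - xus_vals[j])
      }, numeric(1)))
      pos["trs"] <- pos["trs"] + p_hist[[h]] * trs_h
    }
    pos
  }
  pos_mal <- class_rates(MALIGNANT_HISTOLOGIES, config$us_pattern_dist$malignant)
  pos_ben <- class_rates(BENIGN_HISTOLOGIES, config$us_pattern_dist$benign)
  data.frame(
    score = c("x_us", "x_gc", "trs"),
    sensitivity = unname(pos_mal),
    specificity = unname(1 - pos_ben),
    row.names = NULL
  )
}

#' Expected fraction of alteration-positive nodules by malignancy class
#'
#' Exact expectation under the configuration of the probability that a
#' nodule carries at least one alteration, for each malignancy class.
#'
#' @param config a [cohort_config()].
#' @return named numeric with elements `malignant` and `benign`.
#' @export
implied_positivity <- function(config) {
  mix <- config$histology_mix
  one_class <- function(histologies) {
    p_hist <- mix[intersect(names(mix), histologies)]
    p_hist <- p_hist / sum(p_hist)
    sum(vapply(names(p_hist), function(h) {
      none <- prod(vapply(config$alteration_spectrum[[h]] %||% list(),
                          function(loc) {
                            1 - sum(vapply(loc, function(o) o$prob, numeric(1)))
                          }, numeric(1)))
      p_hist[[h]] * (1 - none)
    }, numeric(1)))
  }
  c(malignant = one_class(MALIGNANT_HISTOLOGIES),
    benign = one_class(BENIGN_HISTOLOGIES))
}
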