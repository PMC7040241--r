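test_that("the default configuration encodes the study-like structure", {
  cfg <- default_study_config()
  expect_equal(cfg$n_patients, 47L)
  expect_equal(cfg$malignancy_prevalence, 28 / 47)
  # histology mix reproduces the reference row fractions within each class
  expect_equal(cfg$histology_mix[["MTC"]], 3 / 28)
  expect_equal(cfg$histology_mix[["PTC"]], 11 / 28)
  expect_equal(cfg$histology_mix[["ADENOMATOID_NODULE"]], 13 / 19)
  expect_equal(sum(cfg$histology_mix[thyrostrat:::MALIGNANT_HISTOLOGIES]), 1)
  # expected alteration positivity close to the reference marginals
  pos <- implied_positivity(cfg)
  expect_equal(unname(pos["malignant"]), 0.785, tolerance = 0.01)
  expect_equal(unname(pos["benign"]), 0.368, tolerance = 0.01)
})

test_that("generation is deterministic, sized, and respects prevalence", {
  cfg <- default_study_config(seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 47L)
  # malignant count within the binomial 99% band around 28/47 * 47
  k <- sum(a$truth == "MALIGNANT")
  band <- qbinom(c(0.005, 0.995), 47, 28 / 47)
  expect_true(k >= band[1] && k <= band[2])
  # truth is a deterministic function of histology
  expect_true(all(
    (a$histology %in% thyrostrat:::MALIGNANT_HISTOLOGIES) ==
      (a$truth == "MALIGNANT")
  ))

  cfg0 <- cfg
  cfg0$malignancy_prevalence <- 0
  all_benign <- generate_cohort(cfg0)
  expect_true(all(all_benign$truth == "BENIGN"))
  expect_true(all(all_benign$histology %in% thyrostrat:::BENIGN_HISTOLOGIES))
})

test_that("cohorts round-trip through the CSV writer bit-identically", {
  cfg <- default_study_config(n_patients = 30, seed = 4)
  co <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(co, back)
  # and a second write of the read-back file is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("alteration classes survive the identifier round trip", {
  cfg <- default_study_config(n_patients = 200, seed = 2)
  co <- generate_cohort(cfg)
  fields <- co$alterations[nzchar(co$alterations)]
  alts <- unlist(lapply(fields, parse_alteration_field), recursive = FALSE)
  ids <- vapply(alts, function(a) a$identifier, character(1))
  cls <- vapply(alts, function(a) a$class, character(1))
  expect_equal(unique(cls[ids == "PAX8:PAX8-PPARG"]), "GENE_FUSION")
  expect_equal(unique(cls[ids == "RET:deletion"]), "CNV")
  expect_true(all(cls[grepl(":p\\.", ids)] == "SNV"))
})

test_that("a large cohort recovers the config-implied operating characteristics", {
  cfg <- default_study_config(n_patients = 20000, seed = 1)
  scored <- run_score(generate_cohort(cfg))
  implied <- implied_performance(cfg)
  cuts <- c(x_us = 0.9, x_gc = 0.6, trs = 0.7)
  for (nm in names(cuts)) {
    m <- confusion_from_scores(scored[[nm]], scored$truth, cuts[[nm]])
    emp_sens <- m$tp / (m$tp + m$fn)
    emp_spec <- m$tn / (m$tn + m$fp)
    row <- implied[implied$score == nm, ]
    expect_lt(abs(emp_sens - row$sensitivity), 0.015)
    expect_lt(abs(emp_spec - row$specificity), 0.015)
  }
})

test_that("raising malignant alteration probabilities raises X_GC sensitivity", {
  cfg <- default_study_config(n_patients = 4000, seed = 6)
  bumped <- cfg
  for (h in thyrostrat:::MALIGNANT_HISTOLOGIES) {
    spec_h <- bumped$alteration_spectrum[[h]]
    for (i in seq_along(spec_h)) {
      tot <- sum(vapply(spec_h[[i]], function(o) o$prob, numeric(1)))
      room <- (1 - tot) / length(spec_h[[i]])
      for (j in seq_along(spec_h[[i]])) {
        spec_h[[i]][[j]]$prob <- spec_h[[i]][[j]]$prob + 0.9 * room
      }
    }
    bumped$alteration_spectrum[[h]] <- spec_h
  }
  sens_of <- function(config) {
    s <- run_score(generate_cohort(config))
    m <- confusion_from_scores(s$x_gc, s$truth, 0.6)
    m$tp / (m$tp + m$fn)
  }
  expect_gte(sens_of(bumped), sens_of(cfg))
  # and the implied (exact) sensitivities agree with the ordering
  expect_gte(implied_performance(bumped)$sensitivity[2],
             implied_performance(cfg)$sensitivity[2])
})

test_that("invalid configurations are rejected", {
  cfg <- default_study_config()
  bad <- cfg$histology_mix
  bad[["MTC"]] <- bad[["MTC"]] + 0.1
  expect_error(
    cohort_config(47, 28 / 47, bad, cfg$alteration_spectrum,
                  cfg$us_pattern_dist),
    "sum to 1"
  )
  expect_error(
    cohort_config(47, 1.5, cfg$histology_mix, cfg$alteration_spectrum,
                  cfg$us_pattern_dist),
    "prevalence"
  )
})
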