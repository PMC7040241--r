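#' Cohort and variant file input/output
#'
#' Cohort CSV: one row per nodule with columns `nodule_id, histology, truth,
#' us_pattern, alterations`, alterations as semicolon-joined canonical
#' identifiers (`GENE:detail`), empty string for none. Variant list TSV: one
#' row per alteration with columns `nodule_id, gene, class, detail`.
#'
#' @name cohort_io
NULL

# Alteration classes are recovered from the identifier when a cohort CSV is
# read back: known fusion/CNV identifiers are registered here, everything
# else is treated as SNV (protein-change details) or INDEL is preserved via
# the registry. The variants TSV carries the class explicitly and needs no
# registry.
KNOWN_ALTERATION_CLASSES <- c(
  "PAX8:PAX8-PPARG" = "GENE_FUSION",
  "RET:deletion"    = "CNV"
)

#' @keywords internal
class_from_identifier <- function(identifier) {
  cls <- KNOWN_ALTERATION_CLASSES[identifier]
  ifelse(is.na(cls), "SNV", cls)
}

#' Parse a semicolon-joined alteration field into alteration objects
#'
#' @param field a single string like `"BRAF:p.Val600Glu;TERT:c.1-124C>T"`,
#'   or `""`/`NA` for no alterations.
#' @return list of [genomic_alteration()].
#' @export
parse_alteration_field <- function(field) {
  if (is.na(field) || !nzchar(trimws(field))) return(list())
  ids <- trimws(strsplit(field, ";", fixed = TRUE)[[1L]])
  ids <- ids[nzchar(ids)]
  lapply(ids, function(id) {
    parts <- regmatches(id, regexpr(":", id, fixed = TRUE), invert = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L])) {
      stop_input("malformed alteration identifier '%s' (expected GENE:detail)", id)
    }
    genomic_alteration(parts[1L], class_from_identifier(id), parts[2L])
  })
}

#' @keywords internal
format_alteration_field <- function(alterations) {
  if (!length(alterations)) return("")
  paste(vapply(alterations, function(a) a$identifier, character(1)),
        collapse = ";")
}

#' Write a cohort to CSV
#'
#' @param cohort a data frame as produced by [generate_cohort()] (columns
#'   `nodule_id, histology, truth, us_pattern, alterations`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# format_version: 1", con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path cohort CSV path (leading `#` comment lines are skipped).
#' @return a data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_input("cohort file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!nrow(df)) stop_input("empty input: %s", path)
  df
}

#' Read a per-nodule variant list (TSV)
#'
#' @param path TSV with header `nodule_id, gene, class, detail`.
#' @return a named list: for each nodule_id, a list of
#'   [genomic_alteration()].
#' @export
read_variant_list <- function(path) {
  if (!file.exists(path)) stop_input("variant list not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("nodule_id", "gene", "class", "detail")
  if (!all(need %in% names(df))) {
    stop_input("variant list must have columns %s", paste(need, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    a <- genomic_alteration(df$gene[i], df$class[i], df$detail[i])
    id <- df$nodule_id[i]
    out[[id]] <- c(out[[id]], list(a))
  }
  out
}

#' Attach a variant list to a cohort table
#'
#' Replaces/creates the cohort's `alterations` column from a variant list
#' read with [read_variant_list()]. Nodules absent from the list get no
#' alterations.
#'
#' @param cohort cohort data frame with `nodule_id`.
#' @param variants named list from [read_variant_list()].
#' @return the cohort with an `alterations` column.
#' @export
attach_variants <- function(cohort, variants) {
  cohort$alterations <- vapply(cohort$nodule_id, function(id) {
    format_alteration_field(variants[[id]] %||% list())
  }, character(1), USE.NAMES = FALSE)
  cohort
}
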