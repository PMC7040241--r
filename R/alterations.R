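#' Genomic alterations and weight tables
#'
#' A genomic alteration is one somatic event detected in a nodule: a
#' single-nucleotide variant, an insertion/deletion, a gene fusion, or a copy
#' number variant. Each alteration is annotated with a weight in \[0, 1\]
#' expressing its strength of association with thyroid cancer (0 = no
#' association, 1 = invariably malignant), looked up by a canonical
#' identifier `GENE:detail`.
#'
#' @name alterations
NULL

ALTERATION_CLASSES <- c("SNV", "INDEL", "GENE_FUSION", "CNV")

#' Construct a genomic alteration
#'
#' @param gene gene symbol (e.g. `"BRAF"`). Uppercased for the identifier.
#' @param class alteration class: one of `"SNV"`, `"INDEL"`, `"GENE_FUSION"`,
#'   `"CNV"` (case-insensitive).
#' @param detail protein change (e.g. `"p.Val600Glu"`), fusion partner
#'   (e.g. `"PAX8-PPARG"`), or CNV descriptor. Kept verbatim after trimming.
#' @return an object of class `genomic_alteration`: a list with fields
#'   `gene`, `class`, `detail` and the canonical `identifier`.
#' @examples
#' genomic_alteration("BRAF", "SNV", "p.Val600Glu")
#' @export
genomic_alteration <- function(gene, class, detail) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(trimws(gene)))
  class <- toupper(trimws(class))
  if (!class %in% ALTERATION_CLASSES) {
    stop_input("unknown alteration class '%s' (expected one of %s)",
               class, paste(ALTERATION_CLASSES, collapse = ", "))
  }
  detail <- trimws(as.character(detail))
  structure(
    list(
      gene = trimws(gene),
      class = class,
      detail = detail,
      identifier = alteration_id(gene, detail)
    ),
    class = "genomic_alteration"
  )
}

#' Canonical alteration identifier
#'
#' Deterministic key `GENE:detail` used to look up weights: the gene symbol is
#' uppercased, the detail is kept verbatim after trimming whitespace.
#'
#' @param gene gene symbol.
#' @param detail protein change / fusion partner / CNV descriptor.
#' @return character identifier.
#' @export
alteration_id <- function(gene, detail) {
  paste0(toupper(trimws(gene)), ":", trimws(as.character(detail)))
}

#' @export
print.genomic_alteration <- function(x, ...) {
  cat(sprintf("<genomic_alteration> %s [%s]\n", x$identifier, x$class))
  invisible(x)
}

#' Construct a weight table
#'
#' Maps alteration identifiers to association weights in \[0, 1\]. Unknown
#' identifiers fall back to `fallback_weight` (pan-cancer panels report
#' variants absent from any thyroid-specific table; an unannotated variant
#' contributes the fallback, it is never an error).
#'
#' @param weights named numeric vector, names are canonical identifiers.
#' @param fallback_weight weight assigned to identifiers absent from the
#'   table; default 0 (no evidence of association).
#' @param provenance optional character vector (same length as `weights`)
#'   with a free-text note per entry.
#' @return an object of class `weight_table`.
#' @export
weight_table <- function(weights, fallback_weight = 0, provenance = NULL) {
  if (length(weights) && is.null(names(weights))) {
    stop_input("weights must be a named vector (names are identifiers)")
  }
  weights <- vapply(weights, as.numeric, numeric(1))
  if (anyNA(weights)) stop_input("non-numeric weight")
  if (length(weights) && (any(weights < 0) || any(weights > 1))) {
    bad <- names(weights)[weights < 0 | weights > 1][1L]
    stop_input("weight out of range [0,1] for '%s'", bad)
  }
  if (anyDuplicated(names(weights))) {
    stop_input("duplicate identifier '%s'",
               names(weights)[duplicated(names(weights))][1L])
  }
  if (!is_scalar_number(fallback_weight) ||
      fallback_weight < 0 || fallback_weight > 1) {
    stop_input("fallback_weight out of range [0,1]")
  }
  if (!is.null(provenance) && length(provenance) != length(weights)) {
    stop_input("provenance must have one note per entry")
  }
  structure(
    list(
      entries = weights,
      fallback_weight = fallback_weight,
      provenance = provenance
    ),
    class = "weight_table"
  )
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d entries, fallback %.3g\n",
              length(x$entries), x$fallback_weight))
  invisible(x)
}

#' Read a weight table from TSV or JSON
#'
#' TSV format: header `identifier<TAB>weight<TAB>provenance` (provenance
#' optional), UTF-8, lines starting with `#` skipped. JSON format: a flat
#' object mapping identifier to weight; an optional `"_fallback"` key sets
#' the fallback weight.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"json"`.
#' @param fallback_weight fallback for identifiers not in the table (TSV
#'   only; JSON may carry its own `"_fallback"`).
#' @return a [weight_table()].
#' @export
read_weight_table <- function(path, format = c("auto", "tsv", "json"),
                              fallback_weight = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("weight table file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(obj) && is.null(names(obj))) {
      stop_input("weight table JSON must be a flat object")
    }
    obj <- unlist(obj)
    if (anyDuplicated(names(obj))) {
      stop_input("duplicate identifier '%s'",
                 names(obj)[duplicated(names(obj))][1L])
    }
    fb <- fallback_weight
    if ("_fallback" %in% names(obj)) {
      fb <- as.numeric(obj[["_fallback"]])
      obj <- obj[names(obj) != "_fallback"]
    }
    w <- suppressWarnings(vapply(obj, as.numeric, numeric(1)))
    if (anyNA(w)) stop_input("non-numeric weight in %s", path)
    return(weight_table(w, fallback_weight = fb))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop_input("empty weight table: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  if (!identical(header[1:2], c("identifier", "weight"))) {
    stop_input("weight table TSV must start with header 'identifier\\tweight'")
  }
  rows <- fields[-1L]
  if (!length(rows)) stop_input("weight table has a header but no rows: %s", path)
  bad <- which(vapply(rows, length, 1L) < 2L)
  if (length(bad)) stop_input("malformed row %d in %s", bad[1L] + 1L, path)
  ids <- vapply(rows, function(r) trimws(r[[1L]]), character(1))
  w <- suppressWarnings(vapply(rows, function(r) as.numeric(r[[2L]]), numeric(1)))
  if (anyNA(w)) stop_input("non-numeric weight for '%s'", ids[which(is.na(w))[1L]])
  prov <- vapply(rows, function(r) if (length(r) >= 3L) trimws(r[[3L]]) else "",
                 character(1))
  names(w) <- ids
  weight_table(w, fallback_weight = fallback_weight, provenance = prov)
}

#' Write a weight table to TSV
#'
#' @param wt a [weight_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(wt, path) {
  stopifnot(inherits(wt, "weight_table"))
  prov <- wt$provenance %||% rep("", length(wt$entries))
  lines <- c(
    "# format_version: 1",
    "identifier\tweight\tprovenance",
    sprintf("%s\t%s\t%s", names(wt$entries),
            format(wt$entries, trim = TRUE), prov)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up the annotated weight of one alteration
#'
#' Returns the table weight when the identifier is known, otherwise the
#' table's fallback weight. Fallback use signals a condition of class
#' `thyrostrat_unknown_alteration` (a warning) so callers can collect or
#' silence unknown-variant reports.
#'
#' @param alteration a [genomic_alteration()].
#' @param wt a [weight_table()].
#' @param warn_unknown signal the unknown-alteration warning? Default `TRUE`.
#' @return numeric weight in \[0, 1\].
#' @export
annotate_alteration <- function(alteration, wt, warn_unknown = TRUE) {
  stopifnot(inherits(alteration, "genomic_alteration"),
            inherits(wt, "weight_table"))
  id <- alteration$identifier
  if (id %in% names(wt$entries)) {
    return(unname(wt$entries[[id]]))
  }
  if (warn_unknown) {
    warning(warningCondition(
      sprintf("alteration '%s' not in weight table; using fallback %.3g",
              id, wt$fallback_weight),
      class = "thyrostrat_unknown_alteration"
    ))
  }
  wt$fallback_weight
}
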