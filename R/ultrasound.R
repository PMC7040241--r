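#' Ultrasound score X_US from ATA sonographic patterns
#'
#' The five ATA sonographic pattern categories map to an annotated
#' ultrasound score equal to the upper bound of the guideline malignancy
#' risk for the pattern: benign and very-low-suspicion patterns score 0,
#' low suspicion 0.1 (10% upper risk), intermediate suspicion 0.2 (20%),
#' and high suspicion 0.9 (90%).
#'
#' @name ultrasound
NULL

ATA_PATTERNS <- c("BENIGN", "VERY_LOW", "LOW", "INTERMEDIATE", "HIGH")

XUS_BY_PATTERN <- c(
  BENIGN = 0, VERY_LOW = 0, LOW = 0.1, INTERMEDIATE = 0.2, HIGH = 0.9
)

#' Map an ATA pattern to its ultrasound score
#'
#' @param pattern character vector of ATA pattern names (`"BENIGN"`,
#'   `"VERY_LOW"`, `"LOW"`, `"INTERMEDIATE"`, `"HIGH"`), case-insensitive.
#' @return numeric vector of scores in \{0, 0.1, 0.2, 0.9\}.
#' @examples
#' xus_from_pattern(c("HIGH", "LOW"))
#' @export
xus_from_pattern <- function(pattern) {
  pattern <- parse_us_pattern(pattern)
  unname(XUS_BY_PATTERN[pattern])
}

#' Parse ATA patterns from names or numeric scores
#'
#' Cohort files encode the sonographic assessment either as the pattern name
#' or as the numeric score; both are accepted, case-insensitively, with
#' hyphen/space variants of the names (`"very low"`, `"very-low"`)
#' normalized. A numeric 0 parses as `"VERY_LOW"` (benign-pattern nodules
#' would not have been biopsied, and both categories score 0).
#'
#' @param x character or numeric vector.
#' @return character vector of canonical pattern names.
#' @export
parse_us_pattern <- function(x) {
  if (is.numeric(x)) {
    out <- rep(NA_character_, length(x))
    for (i in seq_along(x)) {
      hit <- which(abs(XUS_BY_PATTERN - x[i]) < SCORE_TOL &
                     names(XUS_BY_PATTERN) != "BENIGN")
      if (!length(hit)) {
        stop_input("invalid ultrasound score %g (expected 0, 0.1, 0.2 or 0.9)",
                   x[i])
      }
      out[i] <- names(XUS_BY_PATTERN)[hit[1L]]
    }
    return(out)
  }
  norm <- gsub("[ -]+", "_", toupper(trimws(as.character(x))))
  # numeric strings in a character column are accepted too
  num <- suppressWarnings(as.numeric(norm))
  if (all(!is.na(num))) return(parse_us_pattern(num))
  bad <- !norm %in% ATA_PATTERNS
  if (any(bad)) {
    stop_input("unrecognized ATA pattern '%s'", as.character(x)[bad][1L])
  }
  norm
}
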