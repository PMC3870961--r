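#' Canonical strain and line designs
#'
#' The genetic design consists of two parental strains and five
#' autosome-substitution lines of the house fly. ALHF carries the resistant
#' ("R") allele on all five autosomes; aabys carries the susceptible ("S")
#' marker allele on all five. Each substitution line replaces exactly one
#' ALHF autosome with its aabys counterpart, and its name lists the
#' autosomes retained from ALHF (A1234 lacks autosome 5, A2345 lacks
#' autosome 1, and so on).
#'
#' @return A named list of genotypes, one per line, in the order ALHF,
#'   aabys, A2345, A1345, A1245, A1235, A1234. Each genotype is a character
#'   vector of length five with names `"1"`..`"5"` and values `"R"` or
#'   `"S"`.
#' @examples
#' line_designs()[["A1234"]]
#' @export
line_designs <- function() {
  nm <- c("ALHF", "aabys", "A2345", "A1345", "A1245", "A1235", "A1234")
  stats::setNames(lapply(nm, parse_line_name), nm)
}

#' Names of the five substitution lines
#'
#' @return Character vector `c("A2345", "A1345", "A1245", "A1235", "A1234")`,
#'   ordered by the substituted autosome (1 to 5).
#' @export
substitution_lines <- function() {
  c("A2345", "A1345", "A1245", "A1235", "A1234")
}

#' Parse a line name into a genotype
#'
#' `"ALHF"` maps to all-R, `"aabys"` to all-S. A substitution-line name is
#' `"A"` followed by a strictly increasing run of four distinct digits from
#' 1-5: the listed autosomes are R (from ALHF) and the single missing
#' autosome is S (from aabys).
#'
#' @param name Line name (`"ALHF"`, `"aabys"`, or e.g. `"A1234"`).
#' @return Genotype: named character vector over autosomes 1-5 with values
#'   `"R"`/`"S"`.
#' @export
parse_line_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  auto <- as.character(1:5)
  if (name == "ALHF") {
    return(stats::setNames(rep("R", 5L), auto))
  }
  if (name == "aabys") {
    return(stats::setNames(rep("S", 5L), auto))
  }
  if (!grepl("^A[1-5]+$", name)) {
    stop(parse_error(sprintf("malformed line name: '%s'", name)))
  }
  digits <- as.integer(strsplit(substring(name, 2L), "")[[1L]])
  if (anyDuplicated(digits) || is.unsorted(digits, strictly = TRUE)) {
    stop(parse_error(sprintf(
      "line name '%s' must list distinct increasing autosomes", name
    )))
  }
  if (length(digits) != 4L) {
    stop(parse_error(sprintf(
      "line name '%s' must retain exactly four autosomes (one substituted)",
      name
    )))
  }
  g <- stats::setNames(rep("S", 5L), auto)
  g[as.character(digits)] <- "R"
  g
}

#' Autosome substituted in a line
#'
#' The line substituting autosome `a` is the one whose name omits `a`:
#' A2345 -> 1, A1345 -> 2, A1245 -> 3, A1235 -> 4, A1234 -> 5.
#'
#' @param name Substitution-line name (vectorised).
#' @return Integer vector of substituted autosomes.
#' @export
substituted_autosome <- function(name) {
  vapply(name, function(nm) {
    g <- parse_line_name(nm)
    s <- which(g == "S")
    if (length(s) != 1L) {
      stop(parse_error(sprintf(
        "'%s' is not a single-autosome substitution line", nm
      )))
    }
    as.integer(names(g)[s])
  }, integer(1L), USE.NAMES = FALSE)
}

parse_error <- function(message) {
  structure(
    class = c("muscalink_parse_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}

config_error <- function(message) {
  structure(
    class = c("muscalink_config_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}

normalization_error <- function(message) {
  structure(
    class = c("muscalink_normalization_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}
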