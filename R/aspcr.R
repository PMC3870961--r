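#' Read an allele-specific PCR band table
#'
#' @param path TSV with a `gene_id` column and one `present`/`absent`
#'   column per line (the five substitution lines; parental ALHF and aabys
#'   columns optional).
#' @return Wide tibble of band calls.
#' @export
read_bands <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Merge replicated band patterns by majority vote
#'
#' The assay is run on independent mRNA preparations; replicated patterns
#' are merged per gene x line by majority vote. Ties become `NA`, which
#' [infer_location()] reports as ambiguous.
#'
#' @param patterns List of wide band tibbles (same columns).
#' @return A single wide tibble; tied cells are `NA`.
#' @export
merge_band_replicates <- function(patterns) {
  stopifnot(length(patterns) >= 1L)
  template <- patterns[[1L]]
  line_cols <- setdiff(names(template), "gene_id")
  out <- template
  for (col in line_cols) {
    votes <- sapply(patterns, function(p) {
      p[[col]][match(template$gene_id, p$gene_id)]
    })
    votes <- matrix(votes, nrow = nrow(template))
    out[[col]] <- apply(votes, 1L, function(v) {
      n_present <- sum(v == "present", na.rm = TRUE)
      n_absent <- sum(v == "absent", na.rm = TRUE)
      if (n_present > n_absent) "present" else if (n_absent > n_present) "absent" else NA_character_
    })
  }
  out
}

#' Infer a gene's physical autosome from its band pattern
#'
#' ALHF-allele-specific primers amplify only the ALHF allele, so absence of
#' a band in exactly one substitution line places the gene on that line's
#' substituted autosome (absence in A1234 means the gene sits on autosome
#' 5). A band in all five lines leaves the gene unmapped; absence in two or
#' more lines, a tied replicate call, or an inconsistent parental row (ALHF
#' without a band, or aabys with one) is reported as ambiguous. Parental
#' rows are used only as consistency checks, never to map.
#'
#' @param bands Wide band tibble: `gene_id` plus one column per line with
#'   values `"present"`/`"absent"` (`NA` = tied replicates). Must cover the
#'   five substitution lines; `ALHF`/`aabys` columns are optional.
#' @return Tibble with columns `gene_id`, `outcome`
#'   (`"mapped"`/`"unmapped"`/`"ambiguous"`), `autosome` (integer, `NA`
#'   unless mapped), `evidence` (the line(s) lacking the band, or the
#'   reason for ambiguity).
#' @export
infer_location <- function(bands) {
  lines <- substitution_lines()
  missing_cols <- setdiff(lines, names(bands))
  if (length(missing_cols)) {
    stop(parse_error(sprintf(
      "band table lacks line column(s): %s", paste(missing_cols, collapse = ", ")
    )))
  }
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    v <- vapply(lines, function(l) bands[[l]][i], character(1))
    if (("ALHF" %in% names(bands) && !is.na(bands$ALHF[i]) && bands$ALHF[i] != "present") ||
      ("aabys" %in% names(bands) && !is.na(bands$aabys[i]) && bands$aabys[i] != "absent")) {
      return(list(outcome = "ambiguous", autosome = NA_integer_,
                  evidence = "inconsistent parental band"))
    }
    if (anyNA(v)) {
      return(list(outcome = "ambiguous", autosome = NA_integer_,
                  evidence = "tied replicate band calls"))
    }
    lacking <- lines[v == "absent"]
    if (length(lacking) == 0L) {
      list(outcome = "unmapped", autosome = NA_integer_, evidence = "band in all lines")
    } else if (length(lacking) == 1L) {
      list(outcome = "mapped", autosome = substituted_autosome(lacking),
           evidence = lacking)
    } else {
      list(outcome = "ambiguous", autosome = NA_integer_,
           evidence = paste(lacking, collapse = ","))
    }
  })
  tibble::tibble(
    gene_id = bands$gene_id,
    outcome = vapply(rows, `[[`, character(1), "outcome"),
    autosome = vapply(rows, `[[`, integer(1), "autosome"),
    evidence = vapply(rows, `[[`, character(1), "evidence")
  )
}

#' Pivot long band calls to the wide per-line layout
#'
#' @param bands_long [simulate_bands()] output (`gene_id`, `line`, `band`).
#' @return Wide tibble consumable by [infer_location()].
#' @export
bands_to_wide <- function(bands_long) {
  tidyr::pivot_wider(bands_long, names_from = "line", values_from = "band")
}
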