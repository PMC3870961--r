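#' Path to a packaged fixture file
#'
#' @param file File name under `extdata` (default the transcribed qPCR
#'   relative-expression table).
#' @return Absolute path to the installed fixture.
#' @export
muscalink_fixture <- function(file = "table4_fixture.tsv") {
  path <- system.file("extdata", file, package = "muscalink", mustWork = FALSE)
  if (!nzchar(path)) stop(sprintf("fixture '%s' not found", file))
  path
}

table4_cols <- function() {
  lines <- c("ALHF", substitution_lines())
  c(
    "general_function", "detailed_function", "family", "gene_id",
    unlist(lapply(lines, function(l) {
      if (l == "ALHF") paste0(l, c("_mean", "_se")) else paste0(l, c("_mean", "_se", "_sig"))
    }))
  )
}

#' Read the transcribed qPCR relative-expression table
#'
#' Loads the packaged 70-gene relative-expression fixture (mean +/- SE per
#' line, with the printed significance asterisks as 0/1 flags) into the
#' long summary format used by [call_linkage()]. Rows printed without data
#' (withdrawn assays) become `status = "missing"` records. Printed values
#' are preserved verbatim in `mean_printed` / `se_printed` so the table
#' round-trips exactly through [write_table4()].
#'
#' @param path Fixture path; defaults to the packaged file.
#' @param n_reps Replicate count behind each printed mean (three biological
#'   replicates in the assay design).
#' @return Long tibble: `general_function`, `detailed_function`, `family`,
#'   `gene_id`, `line`, `mean`, `se`, `n`, `significant` (logical; `NA` for
#'   the comparator ALHF column), `mean_printed`, `se_printed`, `status`,
#'   `provenance = "printed"`.
#' @export
read_table4 <- function(path = muscalink_fixture(), n_reps = 3L) {
  wide <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  stopifnot(identical(names(wide), table4_cols()))
  lines <- c("ALHF", substitution_lines())
  long <- dplyr::bind_rows(lapply(lines, function(l) {
    tibble::tibble(
      general_function = wide$general_function,
      detailed_function = wide$detailed_function,
      family = wide$family,
      gene_id = wide$gene_id,
      line = l,
      mean_printed = wide[[paste0(l, "_mean")]],
      se_printed = wide[[paste0(l, "_se")]],
      significant = if (l == "ALHF") {
        NA
      } else {
        ifelse(nzchar(wide[[paste0(l, "_sig")]]),
          wide[[paste0(l, "_sig")]] == "1", NA
        )
      }
    )
  }))
  long$mean <- ifelse(nzchar(long$mean_printed), as.numeric(long$mean_printed), NA_real_)
  long$se <- ifelse(nzchar(long$se_printed), as.numeric(long$se_printed), NA_real_)
  long$n <- ifelse(is.na(long$mean), NA_integer_, as.integer(n_reps))
  long$status <- ifelse(is.na(long$mean), "missing", "ok")
  long$provenance <- "printed"
  long[order(match(long$gene_id, wide$gene_id), match(long$line, lines)), c(
    "general_function", "detailed_function", "family", "gene_id", "line",
    "mean", "se", "n", "significant", "mean_printed", "se_printed",
    "status", "provenance"
  )]
}

#' Serialise a loaded relative-expression table back to its TSV form
#'
#' Inverse of [read_table4()]: reconstructs the wide fixture layout from
#' the printed-value columns, byte-identical to the packaged file.
#'
#' @param tbl Long tibble from [read_table4()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table4 <- function(tbl, path) {
  lines <- c("ALHF", substitution_lines())
  genes <- unique(tbl$gene_id)
  wide <- tbl[match(genes, tbl$gene_id), c("general_function", "detailed_function", "family", "gene_id")]
  for (l in lines) {
    sub <- tbl[tbl$line == l, ][match(genes, tbl$gene_id[tbl$line == l]), ]
    wide[[paste0(l, "_mean")]] <- sub$mean_printed
    wide[[paste0(l, "_se")]] <- sub$se_printed
    if (l != "ALHF") {
      wide[[paste0(l, "_sig")]] <- ifelse(is.na(sub$significant), "",
        ifelse(sub$significant, "1", "0")
      )
    }
  }
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}
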