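#' Read a gene function catalog
#'
#' @param path TSV with columns `gene_id`, `general_function`,
#'   `detailed_function`, `family`. Each gene may appear at most once.
#' @return Catalog tibble.
#' @export
read_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("gene_id", "general_function", "detailed_function", "family") %in% names(cat)))
  if (anyDuplicated(cat$gene_id)) {
    stop(config_error("catalog contains duplicated gene ids"))
  }
  cat
}

#' Build a catalog from the packaged relative-expression table
#'
#' @param t4 Long tibble from [read_table4()].
#' @return Catalog tibble (one row per gene).
#' @export
catalog_from_table4 <- function(t4 = read_table4()) {
  first <- t4[match(unique(t4$gene_id), t4$gene_id), ]
  tibble::tibble(
    gene_id = first$gene_id,
    general_function = first$general_function,
    detailed_function = first$detailed_function,
    family = first$family
  )
}

normalize_category <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Tally function-category membership of a gene set
#'
#' Counts every gene of the set exactly once under its (general, detailed)
#' category pair; genes absent from the catalog are counted under the
#' `"NONA"` / `"not annotated"` category, so counts always sum to the set
#' size. Category strings are matched case-insensitively after whitespace
#' normalisation.
#'
#' @param gene_set Character vector of gene ids (duplicates collapsed).
#' @param catalog Catalog tibble from [read_catalog()] or
#'   [catalog_from_table4()].
#' @return Tibble with columns `general_function`, `detailed_function`,
#'   `n`, sorted by decreasing count.
#' @export
tally_categories <- function(gene_set, catalog) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) {
    return(tibble::tibble(
      general_function = character(0), detailed_function = character(0),
      n = integer(0)
    ))
  }
  idx <- match(gene_set, catalog$gene_id)
  general <- ifelse(is.na(idx), "NONA",
    normalize_category(catalog$general_function[idx])
  )
  detailed <- ifelse(is.na(idx), "not annotated",
    normalize_category(catalog$detailed_function[idx])
  )
  counts <- dplyr::count(
    tibble::tibble(general_function = general, detailed_function = detailed),
    .data$general_function, .data$detailed_function,
    name = "n"
  )
  counts[order(-counts$n, counts$general_function, counts$detailed_function), ]
}
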