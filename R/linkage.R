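#' Call each gene's autosome linkage set
#'
#' An autosome belongs to a gene's linkage set iff the line substituting
#' that autosome shows a significant expression change against ALHF
#' (A2345 -> autosome 1, A1345 -> 2, A1245 -> 3, A1235 -> 4, A1234 -> 5).
#' Significance in either direction creates a linkage edge. When the input
#' carries printed significance flags (the transcribed assay table) those
#' flags ARE the calls; otherwise Welch's t-test against ALHF at `alpha`
#' decides. Genes whose five line records are all missing get
#' `status = "no_data"` and are excluded from partitions.
#'
#' @param summary Long summary tibble ([summarize_lines()] or
#'   [read_table4()] output): columns `gene_id`, `line`, `mean`, `se`, `n`,
#'   and either `significant` or enough summary statistics to recompute it.
#' @param alpha Significance level used when flags must be recomputed.
#' @param use_printed_flags Use the `significant` column when present
#'   (default); set `FALSE` to recompute Welch p-values from `mean`/`se`/`n`
#'   (diagnostic only for printed tables, whose values are rounded).
#' @return Tibble with columns `gene_id`, `linked` (list of integer
#'   autosome vectors), `linked_autosomes` (comma-joined digits, `""` for
#'   the empty set), `n_linked`, `status` (`"called"`/`"no_data"`),
#'   `provenance` (`"printed"` or `"welch"`).
#' @export
call_linkage <- function(summary, alpha = 0.05, use_printed_flags = TRUE) {
  lines <- substitution_lines()
  unknown <- setdiff(unique(summary$line), c("ALHF", "aabys", lines))
  if (length(unknown)) {
    stop(parse_error(sprintf(
      "unknown line name(s): %s", paste(unknown, collapse = ", ")
    )))
  }
  has_flags <- use_printed_flags && "significant" %in% names(summary) &&
    any(!is.na(summary$significant))
  sub <- summary[summary$line %in% lines, , drop = FALSE]
  if (!has_flags) {
    ref <- summary[summary$line == "ALHF", c("gene_id", "mean", "se", "n")]
    names(ref) <- c("gene_id", "ref_mean", "ref_se", "ref_n")
    sub <- dplyr::left_join(sub, ref, by = "gene_id")
    ok <- !is.na(sub$mean) & !is.na(sub$ref_mean)
    sig <- rep(NA, nrow(sub))
    if (any(ok)) {
      w <- welch_test(
        sub$mean[ok], sub$se[ok], sub$n[ok],
        sub$ref_mean[ok], sub$ref_se[ok], sub$ref_n[ok]
      )
      sig[ok] <- w$p <= alpha
    }
    sub$significant <- sig
  }
  sub$autosome <- substituted_autosome(sub$line)
  genes <- unique(summary$gene_id)
  calls <- lapply(genes, function(g) {
    rows <- sub[sub$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0L || all(is.na(rows$significant))) {
      return(list(linked = integer(0), status = "no_data"))
    }
    list(
      linked = sort(rows$autosome[!is.na(rows$significant) & rows$significant]),
      status = "called"
    )
  })
  tibble::tibble(
    gene_id = genes,
    linked = lapply(calls, `[[`, "linked"),
    linked_autosomes = vapply(calls, function(x) format_subset(x$linked), character(1)),
    n_linked = vapply(calls, function(x) length(x$linked), integer(1)),
    status = vapply(calls, `[[`, character(1), "status"),
    provenance = if (has_flags) "printed" else "welch"
  )
}

#' Partition called genes by their exact linkage subset
#'
#' Every gene with `status = "called"` falls in exactly one class: the
#' exact subset of autosomes in its linkage set (including the empty set).
#' Class counts therefore sum to the number of called genes.
#'
#' @param calls Output of [call_linkage()].
#' @return Tibble with columns `subset` (comma-joined digits, `""` for the
#'   empty set), `n`, `gene_ids` (list), ordered by decreasing count.
#' @export
venn_partition <- function(calls) {
  if (anyDuplicated(calls$gene_id)) {
    stop(parse_error("duplicate gene_id in linkage calls"))
  }
  called <- calls[calls$status == "called", , drop = FALSE]
  key <- called$linked_autosomes
  classes <- split(called$gene_id, key)
  out <- tibble::tibble(
    subset = names(classes),
    n = unname(lengths(classes)),
    gene_ids = unname(classes)
  )
  out[order(-out$n, out$subset), ]
}

#' Count of one exact subset class
#'
#' @param partition Output of [venn_partition()].
#' @param subset Integer vector of autosomes (subset of 1..5); unrealised
#'   subsets count 0.
#' @return Integer count.
#' @export
subset_count <- function(partition, subset) {
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > 5L) || anyDuplicated(subset)) {
    stop(parse_error("subset must be a set of autosomes within 1..5"))
  }
  key <- format_subset(subset)
  hit <- partition$n[partition$subset == key]
  if (length(hit)) as.integer(unname(hit)) else 0L
}

#' Genes regulated solely by a single autosome
#'
#' @param partition Output of [venn_partition()].
#' @return List with `per_autosome` (named integer vector over autosomes
#'   1-5 counting singleton classes) and `total`.
#' @export
single_autosome_summary <- function(partition) {
  per <- vapply(1:5, function(a) subset_count(partition, a), integer(1))
  names(per) <- as.character(1:5)
  list(per_autosome = per, total = sum(per))
}
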