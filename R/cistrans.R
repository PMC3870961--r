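#' Classify regulation as cis, trans, or cis+trans at autosome level
#'
#' Combines each gene's linkage set with its physical autosome location:
#' `cis_only` when the linkage set is exactly the gene's own autosome,
#' `trans_only` when the (non-empty) set excludes it, `cis_plus_trans` when
#' the set contains it plus others, and `unlinked` when the set is empty.
#' "Cis" is autosome-level coincidence of location and linkage — the
#' design cannot resolve whether the cis edge is a regulatory factor or the
#' gene's own locus, so cis_plus_trans genes carry a `cis_or_locus` flag.
#'
#' @param linkage Output of [call_linkage()].
#' @param mapping Output of [infer_location()] (or a tibble with `gene_id`,
#'   `outcome`, `autosome`). Only `outcome == "mapped"` genes are
#'   classified; others are returned with a skip reason.
#' @return Tibble with columns `gene_id`, `location`, `linked_autosomes`,
#'   `class` (`cis_only`/`trans_only`/`cis_plus_trans`/`unlinked`/`NA`),
#'   `cis_or_locus`, `reason` (`NA` when classified).
#' @export
classify_regulation <- function(linkage, mapping) {
  merged <- dplyr::left_join(
    mapping[, c("gene_id", "outcome", "autosome")],
    linkage[, c("gene_id", "linked", "linked_autosomes", "status")],
    by = "gene_id"
  )
  cls <- character(nrow(merged))
  reason <- rep(NA_character_, nrow(merged))
  for (i in seq_len(nrow(merged))) {
    if (merged$outcome[i] != "mapped") {
      cls[i] <- NA_character_
      reason[i] <- sprintf("mapping outcome '%s'", merged$outcome[i])
    } else if (is.na(merged$status[i]) || merged$status[i] != "called") {
      cls[i] <- NA_character_
      reason[i] <- "no linkage call"
    } else {
      linked <- merged$linked[[i]]
      loc <- merged$autosome[i]
      cls[i] <- if (length(linked) == 0L) {
        "unlinked"
      } else if (identical(as.integer(linked), as.integer(loc))) {
        "cis_only"
      } else if (loc %in% linked) {
        "cis_plus_trans"
      } else {
        "trans_only"
      }
    }
  }
  tibble::tibble(
    gene_id = merged$gene_id,
    location = merged$autosome,
    linked_autosomes = merged$linked_autosomes,
    class = cls,
    cis_or_locus = !is.na(cls) & cls == "cis_plus_trans",
    reason = reason
  )
}

#' Score recovery of simulated regulatory architectures
#'
#' Compares inferred linkage calls against simulator ground truth at the
#' level of gene-autosome edges: sensitivity is the fraction of true factor
#' edges recovered, the false-discovery proportion (FDP) the fraction of
#' called edges that are not true, and the exact-set fraction the share of
#' genes whose inferred set equals the truth exactly. A per-autosome
#' breakdown and a truth-vs-inferred regulation-class confusion table are
#' included.
#'
#' @param calls Output of [call_linkage()] on simulated data.
#' @param truth Gene specification tibble from [sample_architectures()].
#' @return List with `edge_sensitivity`, `edge_fdp`, `exact_fraction`,
#'   `per_autosome` (tibble: `autosome`, `sensitivity`, `fdp`), and
#'   `class_confusion` (table of true vs inferred regulation classes).
#' @export
evaluate_recovery <- function(calls, truth) {
  if (!setequal(calls$gene_id, truth$gene_id)) {
    stop(parse_error("gene ids differ between inferred calls and truth"))
  }
  truth <- truth[match(calls$gene_id, truth$gene_id), ]
  true_sets <- lapply(truth$factor_autosomes, parse_subset)
  inf_sets <- calls$linked
  edge_stats <- function(keep_autosome = NULL) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(true_sets)) {
      tr <- true_sets[[i]]
      inf <- inf_sets[[i]]
      if (!is.null(keep_autosome)) {
        tr <- intersect(tr, keep_autosome)
        inf <- intersect(inf, keep_autosome)
      }
      tp <- tp + length(intersect(tr, inf))
      fp <- fp + length(setdiff(inf, tr))
      fn <- fn + length(setdiff(tr, inf))
    }
    c(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fdp = if (tp + fp > 0) fp / (tp + fp) else 0
    )
  }
  overall <- edge_stats()
  per_auto <- t(vapply(1:5, function(a) edge_stats(a), numeric(2)))
  reg_class <- function(linked, loc) {
    if (length(linked) == 0L) {
      "unlinked"
    } else if (identical(as.integer(linked), as.integer(loc))) {
      "cis_only"
    } else if (loc %in% linked) {
      "cis_plus_trans"
    } else {
      "trans_only"
    }
  }
  lv <- c("cis_only", "trans_only", "cis_plus_trans", "unlinked")
  true_cls <- factor(mapply(reg_class, true_sets, truth$physical_autosome), levels = lv)
  inf_cls <- factor(mapply(reg_class, inf_sets, truth$physical_autosome), levels = lv)
  list(
    edge_sensitivity = unname(overall["sensitivity"]),
    edge_fdp = unname(overall["fdp"]),
    exact_fraction = mean(mapply(function(a, b) setequal(a, b), true_sets, inf_sets)),
    per_autosome = tibble::tibble(
      autosome = 1:5,
      sensitivity = per_auto[, "sensitivity"],
      fdp = per_auto[, "fdp"]
    ),
    class_confusion = table(truth = true_cls, inferred = inf_cls)
  )
}
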