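#' Relative expression by the 2^-ddCt method
#'
#' For each sample (line), `dCt = mean(Ct_target) - mean(Ct_reference)`;
#' `ddCt = dCt - dCt_calibrator`; relative expression is `2^-ddCt`, so the
#' calibrator's own value is exactly 1. Replicate-level values are computed
#' by normalising each target replicate against the sample's mean reference
#' Ct and the calibrator's mean dCt, preserving replicate scatter for the
#' downstream significance test.
#'
#' @param ct Ct table with columns `target_id`, `line`, `replicate`, `ct`
#'   (as produced by [simulate_ct()] or read from TSV).
#' @param target Gene id to quantify.
#' @param reference Reference (endogenous control) `target_id`; default
#'   `"beta_actin"`.
#' @param calibrator Line used as calibrator (relative expression 1).
#' @return A list with `per_sample` (tibble: `line`, `n`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`) and `replicates` (tibble: `line`,
#'   `replicate`, `rel_expr`).
#' @export
ddct <- function(ct, target, reference = "beta_actin", calibrator) {
  stopifnot(all(c("target_id", "line", "replicate", "ct") %in% names(ct)))
  tgt <- ct[ct$target_id == target, , drop = FALSE]
  ref <- ct[ct$target_id == reference, , drop = FALSE]
  if (nrow(tgt) == 0L) {
    stop(normalization_error(sprintf("no Ct records for target '%s'", target)))
  }
  lines <- unique(tgt$line)
  if (!calibrator %in% lines) {
    stop(normalization_error(sprintf(
      "calibrator sample '%s' has no records for target '%s'",
      calibrator, target
    )))
  }
  missing_ref <- setdiff(lines, unique(ref$line))
  if (length(missing_ref)) {
    stop(normalization_error(sprintf(
      "no reference ('%s') Ct records for sample(s): %s",
      reference, paste(missing_ref, collapse = ", ")
    )))
  }
  ref_mean <- tapply(ref$ct, ref$line, mean)
  tgt_mean <- tapply(tgt$ct, tgt$line, mean)
  d_ct <- tgt_mean[lines] - ref_mean[lines]
  dd_ct <- d_ct - d_ct[[calibrator]]
  per_sample <- tibble::tibble(
    line = lines,
    n = as.integer(table(tgt$line)[lines]),
    delta_ct = as.numeric(d_ct),
    delta_delta_ct = as.numeric(dd_ct),
    rel_expr = 2^(-as.numeric(dd_ct))
  )
  reps <- tibble::tibble(
    line = tgt$line,
    replicate = tgt$replicate,
    rel_expr = 2^(-((tgt$ct - as.numeric(ref_mean[tgt$line])) -
      as.numeric(d_ct[[calibrator]])))
  )
  list(per_sample = per_sample, replicates = reps)
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite
#' degrees of freedom
#' `df = (se1^2 + se2^2)^2 / (se1^4/(n1-1) + se2^4/(n2-1))` and a two-sided
#' p-value from the t distribution. Degenerate inputs (both SEs zero) give
#' `t = 0, p = 1` for equal means and `p = 0` (flagged) for unequal means,
#' the limit of vanishing replicate variance.
#'
#' @param mean1,se1,n1 Summary statistics of group 1 (SE of the mean).
#' @param mean2,se2,n2 Summary statistics of group 2.
#' @return Tibble with columns `t`, `df`, `p`, `degenerate` (vectorised).
#' @export
welch_test <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(
    all(se1 >= 0, na.rm = TRUE), all(se2 >= 0, na.rm = TRUE),
    all(n1 >= 2, na.rm = TRUE), all(n2 >= 2, na.rm = TRUE)
  )
  v <- se1^2 + se2^2
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  t_stat <- (mean1 - mean2) / sqrt(v)
  degenerate <- v == 0
  t_stat[degenerate] <- ifelse(mean1[degenerate] == mean2[degenerate], 0, Inf *
    sign(mean1[degenerate] - mean2[degenerate]))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[degenerate] <- ifelse(mean1[degenerate] == mean2[degenerate], 1, 0)
  degenerate <- degenerate & mean1 != mean2
  tibble::tibble(t = t_stat, df = df, p = p, degenerate = degenerate)
}

#' Summarise relative expression per gene and line against ALHF
#'
#' Computes per gene x line the mean, standard error (`sd/sqrt(n)`) and
#' replicate count, then calls significance of each line against the ALHF
#' strain with Welch's t-test at `alpha` (two-sided, per test, no
#' multiple-testing correction). Direction records the sign of
#' `line mean - ALHF mean`.
#'
#' @param replicates Replicate-level table with columns `gene_id`, `line`,
#'   `replicate`, `value` (linear-scale expression; [simulate_replicates()]
#'   output, or `rel_expr` values from [ddct()] renamed to `value`).
#' @param alpha Per-test significance level (default 0.05).
#' @param ref_line Comparator strain (default `"ALHF"`); every gene must
#'   have records for it.
#' @return Tibble with columns `gene_id`, `line`, `mean`, `se`, `n`,
#'   `p_value`, `significant`, `direction` (`"up"`/`"down"`/`"none"`),
#'   `status` (`"ok"`/`"missing"`). Gene x line combinations absent from
#'   the input are kept as `status = "missing"` rows rather than dropped.
#' @export
summarize_lines <- function(replicates, alpha = 0.05, ref_line = "ALHF") {
  stopifnot(all(c("gene_id", "line", "replicate", "value") %in% names(replicates)))
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(replicates, .data$gene_id, .data$line),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  genes <- unique(replicates$gene_id)
  no_ref <- setdiff(genes, stats_tbl$gene_id[stats_tbl$line == ref_line])
  if (length(no_ref)) {
    stop(normalization_error(sprintf(
      "gene(s) without %s records: %s", ref_line,
      paste(utils::head(no_ref, 5L), collapse = ", ")
    )))
  }
  full <- tidyr::complete(
    stats_tbl,
    gene_id = genes,
    line = union(unique(stats_tbl$line), ref_line)
  )
  ref <- full[full$line == ref_line, c("gene_id", "mean", "se", "n")]
  names(ref) <- c("gene_id", "ref_mean", "ref_se", "ref_n")
  out <- dplyr::left_join(full, ref, by = "gene_id")
  is_ref <- out$line == ref_line
  have <- !is.na(out$mean) & !is_ref
  w <- welch_test(
    out$mean[have], out$se[have], out$n[have],
    out$ref_mean[have], out$ref_se[have], out$ref_n[have]
  )
  out$p_value <- NA_real_
  out$p_value[have] <- w$p
  out$significant <- NA
  out$significant[have] <- w$p <= alpha
  out$direction <- "none"
  out$direction[have] <- ifelse(
    !out$significant[have], "none",
    ifelse(out$mean[have] > out$ref_mean[have], "up", "down")
  )
  out$status <- ifelse(is.na(out$mean), "missing", "ok")
  out$direction[out$status == "missing"] <- NA_character_
  out[order(match(out$gene_id, genes), match(out$line, c(ref_line, substitution_lines()))),
    c("gene_id", "line", "mean", "se", "n", "p_value", "significant", "direction", "status")
  ]
}
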