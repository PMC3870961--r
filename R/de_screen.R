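#' Fragments per kilobase per million mapped fragments (FPKM)
#'
#' `fpkm = 1e9 * count / (length_nt * library_size)`.
#'
#' @param count Non-negative fragment count (vectorised).
#' @param length_nt Gene length in nucleotides (> 0).
#' @param library_size Total mapped fragments in the sample (> 0).
#' @return Numeric FPKM values.
#' @export
fpkm <- function(count, length_nt, library_size) {
  if (any(length_nt <= 0)) stop(config_error("length_nt must be > 0"))
  if (any(library_size <= 0)) stop(config_error("library_size must be > 0"))
  1e9 * count / (length_nt * library_size)
}

#' FPKM matrix for a count matrix
#'
#' @param cm A `count_matrix` ([simulate_counts()] or [read_count_matrix()]).
#' @return Matrix of FPKM values, genes x samples.
#' @export
fpkm_matrix <- function(cm) {
  sweep(
    sweep(cm$counts * 1e9, 1L, cm$length_nt, "/"),
    2L, cm$library_size, "/"
  )
}

# Scale each sample's counts to the geometric-mean library size.
equalize_libsizes <- function(counts, library_size) {
  target <- exp(mean(log(library_size)))
  sweep(counts, 2L, target / library_size, "*")
}

#' Method-of-moments common NB dispersion
#'
#' After scaling every sample to the geometric-mean depth, computes for
#' each gene the within-group sample mean `m` and variance `s^2` and the
#' moment statistic `(s^2 - m) / m^2` (averaged over groups with at least
#' two samples); the common dispersion estimate is the median over genes of
#' this statistic truncated at zero. Pure Poisson counts give an estimate
#' near zero; constant counts give exactly zero.
#'
#' @param cm A `count_matrix`.
#' @param groups Factor or character vector of group labels, one per sample
#'   (column). At least one group needs >= 2 samples.
#' @return Non-negative scalar dispersion `phi`.
#' @export
estimate_common_dispersion <- function(cm, groups) {
  stopifnot(length(groups) == ncol(cm$counts))
  groups <- as.factor(groups)
  if (!any(table(groups) >= 2L)) {
    stop(config_error("need at least one group with >= 2 samples"))
  }
  scaled <- equalize_libsizes(cm$counts, cm$library_size)
  per_gene <- apply(scaled, 1L, function(x) {
    vals <- vapply(levels(groups), function(g) {
      xs <- x[groups == g]
      if (length(xs) < 2L) {
        return(NA_real_)
      }
      m <- mean(xs)
      if (m <= 0) {
        return(NA_real_)
      }
      (stats::var(xs) - m) / m^2
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
  stats::median(pmax(0, per_gene), na.rm = TRUE)
}

#' Exact conditional negative-binomial test for one gene
#'
#' Two-sided exact test of equal expression between two groups,
#' conditional on the gene's total count after library-size equalization.
#' Group sums of NB(mu, phi) counts are NB with shape `n_samples / phi`,
#' so under the null the split of the total between groups follows a
#' negative hypergeometric (beta-binomial) law that is free of mu; with
#' `phi = 0` it reduces exactly to the conditional binomial (exact
#' Poisson) test. The p-value sums the probabilities of all splits at most
#' as probable as the observed one (probability ordering; ties included,
#' conservative).
#'
#' @param countsA,countsB Integer count vectors (one entry per sample).
#' @param phi Common NB dispersion (>= 0).
#' @param libA,libB Optional library sizes per sample; when given, counts
#'   are scaled to the common geometric-mean depth and rounded before
#'   conditioning.
#' @return Two-sided p-value in (0, 1]; a zero total gives 1.
#' @export
nb_exact_test <- function(countsA, countsB, phi, libA = NULL, libB = NULL) {
  if (phi < 0) stop(config_error("phi must be >= 0"))
  stopifnot(all(countsA >= 0), all(countsB >= 0))
  if (!is.null(libA) || !is.null(libB)) {
    stopifnot(length(libA) == length(countsA), length(libB) == length(countsB))
    target <- exp(mean(log(c(libA, libB))))
    countsA <- round(countsA * target / libA)
    countsB <- round(countsB * target / libB)
  }
  a <- sum(countsA)
  n <- a + sum(countsB)
  if (n == 0) {
    return(1)
  }
  nA <- length(countsA)
  nB <- length(countsB)
  k <- 0:n
  if (phi == 0) {
    logp <- stats::dbinom(k, n, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    logp <- lgamma(k + rA) - lgamma(rA) - lfactorial(k) +
      lgamma(n - k + rB) - lgamma(rB) - lfactorial(n - k) -
      (lgamma(n + rA + rB) - lgamma(rA + rB) - lfactorial(n))
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[a + 1L] * (1 + 1e-12)]))
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Rejects the hypotheses with the `k` smallest p-values where
#' `k = max(i : p_(i) <= i * alpha / m)`.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` entries are never
#'   rejected and do not count toward `m`).
#' @param alpha Target false discovery rate.
#' @return Logical rejection flags, same length as `p`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop(config_error("p-values must lie in [0, 1]"))
  }
  flags <- rep(FALSE, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) {
    return(flags)
  }
  o <- order(pv)
  passed <- which(pv[o] <= seq_len(m) * alpha / m)
  if (length(passed)) {
    flags[which(ok)[o[seq_len(max(passed))]]] <- TRUE
  }
  flags
}

#' Two-group differential-expression screen
#'
#' For each gene: exact conditional NB test between the two groups using a
#' single common method-of-moments dispersion, BH FDR control at `alpha`,
#' and a log2 fold-change of group A over group B from library-equalized
#' mean counts (pseudocount 0.5). This is the desk-scale analogue of the
#' RNA-Seq screen; library-size normalisation is simple total-count
#' scaling to the geometric-mean depth.
#'
#' @param cm A `count_matrix`.
#' @param samplesA,samplesB Column names of the two groups.
#' @param alpha FDR level (default 0.05).
#' @param min_count Genes with equalized total below this are not tested
#'   (`p = NA`, never flagged; default 0).
#' @param phi Common dispersion; estimated from the data when `NULL`.
#' @return Tibble with columns `gene_id`, `log2fc`, `p`, `fdr_flag`,
#'   `direction` (`"up"`/`"down"`/`"none"`); attribute `"phi"` carries the
#'   dispersion used.
#' @export
de_test <- function(cm, samplesA, samplesB, alpha = 0.05, min_count = 0,
                    phi = NULL) {
  stopifnot(
    all(samplesA %in% colnames(cm$counts)),
    all(samplesB %in% colnames(cm$counts))
  )
  if (is.null(phi)) {
    sub <- new_count_matrix(
      cm$counts[, c(samplesA, samplesB), drop = FALSE],
      cm$length_nt,
      cm$library_size[c(samplesA, samplesB)]
    )
    grp <- rep(c("A", "B"), c(length(samplesA), length(samplesB)))
    phi <- tryCatch(
      estimate_common_dispersion(sub, grp),
      muscalink_config_error = function(e) 0
    )
  }
  lib <- cm$library_size
  scaled <- equalize_libsizes(cm$counts, lib)
  mA <- rowMeans(scaled[, samplesA, drop = FALSE])
  mB <- rowMeans(scaled[, samplesB, drop = FALSE])
  log2fc <- log2((mA + 0.5) / (mB + 0.5))
  p <- vapply(rownames(cm$counts), function(g) {
    a <- cm$counts[g, samplesA]
    b <- cm$counts[g, samplesB]
    tot <- sum(round(scaled[g, c(samplesA, samplesB)]))
    if (tot < min_count) {
      return(NA_real_)
    }
    nb_exact_test(a, b, phi, libA = lib[samplesA], libB = lib[samplesB])
  }, numeric(1))
  flag <- bh_fdr(p, alpha)
  tibble::tibble(
    gene_id = rownames(cm$counts),
    log2fc = unname(log2fc),
    p = unname(p),
    fdr_flag = flag,
    direction = ifelse(!flag, "none", ifelse(log2fc > 0, "up", "down"))
  ) -> out
  attr(out, "phi") <- phi
  out
}

#' Co-regulated gene sets across two comparisons
#'
#' Genes significantly up (down) in both comparisons form the co-up
#' (co-down) set; genes with conflicting directions belong to neither.
#'
#' @param de_a,de_b [de_test()] results over the same gene universe.
#' @return List with character vectors `co_up` and `co_down`.
#' @export
co_regulated_sets <- function(de_a, de_b) {
  if (!setequal(de_a$gene_id, de_b$gene_id)) {
    stop(config_error("gene universes differ between the two comparisons"))
  }
  b <- de_b[match(de_a$gene_id, de_b$gene_id), ]
  list(
    co_up = de_a$gene_id[de_a$direction == "up" & b$direction == "up"],
    co_down = de_a$gene_id[de_a$direction == "down" & b$direction == "down"]
  )
}

#' Replicate concordance of two FPKM profiles
#'
#' Squared Pearson correlation of `log2(FPKM + 1)` across genes.
#'
#' @param fpkm_a,fpkm_b FPKM vectors over the same genes (>= 3 genes).
#' @return Scalar r-squared, or `NA` when either transformed vector is
#'   constant.
#' @export
replicate_concordance <- function(fpkm_a, fpkm_b) {
  stopifnot(length(fpkm_a) == length(fpkm_b))
  if (length(fpkm_a) < 3L) {
    stop(config_error("need at least 3 genes for concordance"))
  }
  x <- log2(fpkm_a + 1)
  y <- log2(fpkm_b + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Read a count matrix and its sidecar from TSV
#'
#' @param counts_path TSV with `gene_id` column then one integer column per
#'   sample.
#' @param sidecar_path TSV with columns `id`, `kind` (`"length_nt"` per
#'   gene / `"library_size"` per sample), `value`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, sidecar_path) {
  tab <- readr::read_tsv(counts_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_integer()
  ))
  side <- readr::read_tsv(sidecar_path, col_types = readr::cols(
    id = readr::col_character(), kind = readr::col_character(),
    value = readr::col_double()
  ))
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  len <- side[side$kind == "length_nt", ]
  lib <- side[side$kind == "library_size", ]
  new_count_matrix(
    counts,
    stats::setNames(len$value, len$id)[rownames(counts)],
    stats::setNames(lib$value, lib$id)[colnames(counts)]
  )
}

#' Write a count matrix and its sidecar to TSV
#'
#' @param cm A `count_matrix`.
#' @param counts_path,sidecar_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, sidecar_path) {
  tab <- tibble::as_tibble(cm$counts)
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(cm$counts)), tab)
  readr::write_tsv(tab, counts_path)
  side <- dplyr::bind_rows(
    tibble::tibble(id = names(cm$length_nt), kind = "length_nt",
                   value = as.numeric(cm$length_nt)),
    tibble::tibble(id = names(cm$library_size), kind = "library_size",
                   value = as.numeric(cm$library_size))
  )
  readr::write_tsv(side, sidecar_path)
  invisible(counts_path)
}
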