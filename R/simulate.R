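#' Default architecture priors
#'
#' Priors over factor-autosome subset classes for the synthetic generator.
#' The default class weights mirror the co-regulation partition observed in
#' the qPCR study (59 called genes): the {2,5} class dominates, followed by
#' {1,2,5}, {2,3,5}, the singletons on autosomes 2, 5 and 3, and the minor
#' classes {1,2}, {1,2,3,5}, {3,4,5}, {2,4,5} and the unregulated class.
#'
#' @param classes Named numeric vector of subset-class weights. Names are
#'   comma-joined autosome digits (`"2,5"`, `"1,2,5"`, ...; `""` is the
#'   unregulated class). Must sum to 1.
#' @param effect_range Range (log2 units) from which per-factor effects
#'   `beta` are drawn uniformly. A degenerate range (e.g. `c(1.5, 1.5)`)
#'   fixes the effect.
#' @param baseline_range Range of baseline log2 expression.
#' @param length_range Range of gene lengths (nt, minimum 300).
#' @return A list with class `"muscalink_priors"`.
#' @export
architecture_priors <- function(classes = stats::setNames(
                                  c(21, 9, 6, 4, 6, 1, 3, 3, 2, 2, 2) / 59,
                                  c(
                                    "2,5", "1,2,5", "2,3,5", "2", "5", "3",
                                    "1,2", "1,2,3,5", "3,4,5", "2,4,5", ""
                                  )
                                ),
                                effect_range = c(0.8, 1.6),
                                baseline_range = c(2, 8),
                                length_range = c(300L, 3000L)) {
  if (is.null(names(classes))) {
    stop(config_error("class weights must be named by autosome subsets"))
  }
  if (abs(sum(classes) - 1) > 1e-8) {
    stop(config_error("subset-class weights must sum to 1"))
  }
  if (any(classes < 0)) {
    stop(config_error("subset-class weights must be non-negative"))
  }
  for (nm in names(classes)) {
    subset <- parse_subset(nm)
    if (any(subset < 1L | subset > 5L) || anyDuplicated(subset)) {
      stop(config_error(sprintf("invalid subset class '%s'", nm)))
    }
  }
  structure(
    list(
      classes = classes, effect_range = effect_range,
      baseline_range = baseline_range, length_range = length_range
    ),
    class = "muscalink_priors"
  )
}

parse_subset <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(integer(0))
  }
  sort(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
}

format_subset <- function(x) paste(sort(unique(as.integer(x))), collapse = ",")

#' Sample gene regulatory architectures
#'
#' Draws `n_genes` ground-truth gene specifications: a physical autosome
#' (uniform over 1-5), a factor-autosome subset drawn from the class priors,
#' per-factor log2 effects, a baseline log2 expression and a gene length.
#'
#' @param n_genes Number of genes (>= 1).
#' @param priors An [architecture_priors()] object.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A tibble with columns `gene_id`, `physical_autosome`,
#'   `factor_autosomes` (comma-joined digits, `""` if none), `effects`
#'   (list column of named numeric log2 effects), `baseline_log2`,
#'   `length_nt`, `general_category`, `detailed_category`.
#' @export
sample_architectures <- function(n_genes, priors = architecture_priors(),
                                 seed = 1L) {
  stopifnot(n_genes >= 1L)
  if (!inherits(priors, "muscalink_priors")) {
    priors <- do.call(architecture_priors, priors)
  }
  with_seed(seed, {
    cls <- sample(names(priors$classes), n_genes,
      replace = TRUE, prob = priors$classes
    )
    phys <- sample.int(5L, n_genes, replace = TRUE)
    base <- stats::runif(n_genes, priors$baseline_range[1], priors$baseline_range[2])
    len <- as.integer(round(stats::runif(
      n_genes, priors$length_range[1], priors$length_range[2]
    )))
    effects <- lapply(cls, function(cl) {
      f <- parse_subset(cl)
      stats::setNames(
        stats::runif(length(f), priors$effect_range[1], priors$effect_range[2]),
        as.character(f)
      )
    })
    tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      physical_autosome = phys,
      factor_autosomes = vapply(effects, function(e) {
        format_subset(as.integer(names(e)))
      }, character(1)),
      effects = effects,
      baseline_log2 = base,
      length_nt = pmax(300L, len),
      general_category = "simulated",
      detailed_category = cls
    )
  })
}

#' Expected log2 expression of genes under a genotype
#'
#' Under the additive model each factor autosome carrying the R allele adds
#' its log2 effect to the baseline (multiplicative on the linear scale).
#' Under the AND model the full summed effect applies only when every
#' factor autosome carries R; otherwise expression stays at baseline.
#'
#' @param specs Gene specification tibble from [sample_architectures()].
#' @param genotype A genotype as returned by [parse_line_name()].
#' @param model `"additive"` (default) or `"and"`.
#' @return Numeric vector of expected log2 expression, one per gene.
#' @export
expected_log2_expression <- function(specs, genotype, model = c("additive", "and")) {
  model <- match.arg(model)
  vapply(seq_len(nrow(specs)), function(i) {
    eff <- specs$effects[[i]]
    base <- specs$baseline_log2[i]
    if (length(eff) == 0L) {
      return(base)
    }
    present <- genotype[names(eff)] == "R"
    if (model == "additive") {
      base + sum(eff[present])
    } else {
      base + if (all(present)) sum(eff) else 0
    }
  }, numeric(1))
}

#' Simulate replicate expression measurements
#'
#' Linear-scale expression per replicate is `2^(mu + e)` with
#' `e ~ Normal(0, noise_sd^2)` and `mu` the expected log2 expression of the
#' gene under the line's genotype, emulating independent biological
#' replicates with lognormal measurement noise.
#'
#' @inheritParams expected_log2_expression
#' @param designs Named list of genotypes (default [line_designs()]).
#' @param n_reps Replicates per gene x line (>= 2).
#' @param noise_sd Replicate noise SD in log2 units (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `line`, `replicate`, `value`
#'   (linear-scale expression, > 0).
#' @export
simulate_replicates <- function(specs, designs = line_designs(), n_reps = 3L,
                                noise_sd = 0.15, seed = 1L,
                                model = "additive") {
  stopifnot(n_reps >= 2L, noise_sd >= 0)
  mu <- vapply(designs, function(g) {
    expected_log2_expression(specs, g, model)
  }, numeric(nrow(specs)))
  if (nrow(specs) == 1L) mu <- matrix(mu, nrow = 1L, dimnames = list(NULL, names(designs)))
  with_seed(seed, {
    grid <- expand.grid(
      gene = seq_len(nrow(specs)), line = names(designs),
      replicate = seq_len(n_reps),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    eps <- stats::rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(
      gene_id = specs$gene_id[grid$gene],
      line = grid$line,
      replicate = grid$replicate,
      value = 2^(mu[cbind(grid$gene, match(grid$line, colnames(mu)))] + eps)
    )
  })
}

#' Simulate a fragment count matrix
#'
#' Counts are negative binomial around a depth-scaled mean proportional to
#' linear expression times gene length: within a sample the expected counts
#' are `library_size * expr * length / sum(expr * length)`. `dispersion = 0`
#' degenerates to Poisson sampling.
#'
#' @inheritParams simulate_replicates
#' @param mean_depth Library size (total expected fragments) per sample.
#' @param dispersion NB dispersion `phi` (>= 0); variance is
#'   `mu + phi * mu^2`.
#' @param n_reps Samples simulated per line.
#' @return An object of class `"count_matrix"`: a list with integer matrix
#'   `counts` (genes x samples), `length_nt` (named), and `library_size`
#'   (named, the normalisation denominator).
#' @export
simulate_counts <- function(specs, designs = line_designs(), mean_depth = 1e5,
                            dispersion = 0.05, n_reps = 1L, seed = 1L,
                            model = "additive") {
  if (dispersion < 0) stop(config_error("dispersion must be >= 0"))
  mu_log2 <- vapply(designs, function(g) {
    expected_log2_expression(specs, g, model)
  }, numeric(nrow(specs)))
  if (nrow(specs) == 1L) mu_log2 <- matrix(mu_log2, nrow = 1L, dimnames = list(NULL, names(designs)))
  samples <- as.vector(t(outer(names(designs), seq_len(n_reps), paste, sep = "_rep")))
  sample_line <- rep(names(designs), each = n_reps)
  with_seed(seed, {
    counts <- vapply(seq_along(samples), function(j) {
      w <- 2^mu_log2[, sample_line[j]] * specs$length_nt
      mu <- mean_depth * w / sum(w)
      if (dispersion == 0) {
        as.integer(stats::rpois(length(mu), mu))
      } else {
        as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
      }
    }, integer(nrow(specs)))
    counts <- matrix(counts, nrow = nrow(specs))
    dimnames(counts) <- list(specs$gene_id, samples)
    new_count_matrix(
      counts,
      stats::setNames(specs$length_nt, specs$gene_id),
      stats::setNames(rep(mean_depth, length(samples)), samples)
    )
  })
}

new_count_matrix <- function(counts, length_nt, library_size) {
  stopifnot(
    is.matrix(counts), all(counts >= 0),
    identical(rownames(counts), names(length_nt)),
    identical(colnames(counts), names(library_size))
  )
  structure(
    list(counts = counts, length_nt = length_nt, library_size = library_size),
    class = "count_matrix"
  )
}

#' Simulate qPCR cycle-threshold (Ct) tables
#'
#' Target Ct is `intercept - log2(linear expression) + e` so that a two-fold
#' increase in expression lowers Ct by exactly one cycle at zero noise. The
#' reference gene (beta-actin endogenous control) is held constant across
#' strains apart from measurement noise.
#'
#' @inheritParams simulate_replicates
#' @param ct_noise_sd Ct measurement noise SD in cycles.
#' @param intercept Per-gene Ct at unit expression (recycled scalar).
#' @param ref_ct Reference-gene Ct.
#' @return Tibble with columns `target_id` (gene ids plus `"beta_actin"`),
#'   `line`, `replicate`, `ct`.
#' @export
simulate_ct <- function(specs, designs = line_designs(), n_reps = 3L,
                        ct_noise_sd = 0.1, seed = 1L, intercept = 30,
                        ref_ct = 18, model = "additive") {
  mu <- vapply(designs, function(g) {
    expected_log2_expression(specs, g, model)
  }, numeric(nrow(specs)))
  if (nrow(specs) == 1L) mu <- matrix(mu, nrow = 1L, dimnames = list(NULL, names(designs)))
  intercept <- rep_len(intercept, nrow(specs))
  with_seed(seed, {
    grid <- expand.grid(
      gene = seq_len(nrow(specs)), line = names(designs),
      replicate = seq_len(n_reps),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    target <- tibble::tibble(
      target_id = specs$gene_id[grid$gene],
      line = grid$line,
      replicate = grid$replicate,
      ct = intercept[grid$gene] - mu[cbind(grid$gene, match(grid$line, colnames(mu)))] +
        stats::rnorm(nrow(grid), 0, ct_noise_sd)
    )
    ref_grid <- expand.grid(
      line = names(designs), replicate = seq_len(n_reps),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    ref <- tibble::tibble(
      target_id = "beta_actin",
      line = ref_grid$line,
      replicate = ref_grid$replicate,
      ct = ref_ct + stats::rnorm(nrow(ref_grid), 0, ct_noise_sd)
    )
    dplyr::bind_rows(target, ref)
  })
}

#' Simulate allele-specific PCR band patterns
#'
#' ALHF-allele-specific primers amplify only when the line carries the R
#' allele at the gene's physical autosome: a band is present in line L iff
#' L's genotype is R there. AS-PCR is treated as deterministic; an optional
#' drop-out rate flips present calls to absent in substitution lines.
#'
#' @inheritParams simulate_replicates
#' @param dropout Probability that a truly present band fails to amplify in
#'   a substitution line (default 0, no error model).
#' @param seed Seed used only when `dropout > 0`.
#' @return Tibble with columns `gene_id`, `line`, `band`
#'   (`"present"`/`"absent"`).
#' @export
simulate_bands <- function(specs, designs = line_designs(), dropout = 0,
                           seed = 1L) {
  grid <- expand.grid(
    gene = seq_len(nrow(specs)), line = names(designs),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  present <- vapply(seq_len(nrow(grid)), function(i) {
    g <- designs[[grid$line[i]]]
    g[as.character(specs$physical_autosome[grid$gene[i]])] == "R"
  }, logical(1))
  if (dropout > 0) {
    present <- with_seed(seed, {
      is_sub <- grid$line %in% substitution_lines()
      flip <- is_sub & present & stats::runif(length(present)) < dropout
      present & !flip
    })
  }
  tibble::tibble(
    gene_id = specs$gene_id[grid$gene],
    line = grid$line,
    band = ifelse(present, "present", "absent")
  )
}

#' Read a flat key-value scenario configuration
#'
#' Parses a `key = value` text file describing a simulation scenario.
#' Recognised keys: `n_genes`, `n_reps`, `noise_sd`, `dispersion`,
#' `mean_depth`, `ct_noise_sd`, `seed`, `model` (`additive`/`and`),
#' `effect_min`, `effect_max`, and `class.<subset>` weights (e.g.
#' `class.2,5 = 0.3`; `class.none` is the unregulated class). Lines
#' starting with `#` are ignored.
#'
#' @param path Config file path.
#' @return A list with `n_genes`, `n_reps`, `noise_sd`, `dispersion`,
#'   `mean_depth`, `ct_noise_sd`, `seed`, `model`, and `priors`
#'   ([architecture_priors()]).
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop(config_error(sprintf("malformed config line: '%s'", lines[bad][1])))
  }
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[keys == key][1]) else default
  }
  class_keys <- startsWith(keys, "class.")
  priors_args <- list()
  if (any(class_keys)) {
    nms <- sub("^class\\.", "", keys[class_keys])
    nms[nms == "none"] <- ""
    priors_args$classes <- stats::setNames(as.numeric(vals[class_keys]), nms)
  }
  priors_args$effect_range <- c(get_num("effect_min", 0.8), get_num("effect_max", 1.6))
  list(
    n_genes = as.integer(get_num("n_genes", 200)),
    n_reps = as.integer(get_num("n_reps", 3)),
    noise_sd = get_num("noise_sd", 0.15),
    dispersion = get_num("dispersion", 0.05),
    mean_depth = get_num("mean_depth", 1e5),
    ct_noise_sd = get_num("ct_noise_sd", 0.1),
    seed = as.integer(get_num("seed", 1)),
    model = if ("model" %in% keys) match.arg(vals[keys == "model"][1], c("additive", "and")) else "additive",
    priors = do.call(architecture_priors, priors_args)
  )
}

# Evaluate code under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
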