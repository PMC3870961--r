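# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary data.

# A tiny deterministic gene set with known architectures.
toy_specs <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    physical_autosome = c(5L, 2L, 3L),
    factor_autosomes = c("2,5", "", "3"),
    effects = list(c("2" = 1, "5" = 1), stats::setNames(numeric(0), character(0)), c("3" = 1.2)),
    baseline_log2 = c(3, 4, 2),
    length_nt = c(1000L, 1500L, 600L),
    general_category = "toy",
    detailed_category = c("2,5", "", "3")
  )
}

# Default-scenario priors with a fixed per-factor effect.
fixed_effect_priors <- function(beta = 1.5) {
  architecture_priors(effect_range = c(beta, beta))
}
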