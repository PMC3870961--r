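#!/usr/bin/env Rscript
# Generate the default synthetic scenario emulating the autosome-substitution
# design: 200 genes with co-regulation architectures weighted like the
# observed partition, triplicate lognormal expression, NB counts, Ct values
# with a constant reference gene, and deterministic AS-PCR band patterns.
# Writes all tables (plus the ground truth) under results/sim/.

suppressMessages(library(muscalink))
suppressMessages(library(readr))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20130803L

specs <- sample_architectures(200, architecture_priors(), seed = seed)
designs <- line_designs()

truth <- specs[, c("gene_id", "physical_autosome", "factor_autosomes",
                   "baseline_log2", "length_nt")]
truth$effects <- vapply(specs$effects, function(e) {
  paste(sprintf("%s:%.3f", names(e), e), collapse = ";")
}, character(1))
write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))

reps <- simulate_replicates(specs, designs, n_reps = 3, noise_sd = 0.15,
                            seed = seed + 1)
write_tsv(reps, file.path(out_dir, "expression_replicates.tsv"))

cm <- simulate_counts(specs, designs, mean_depth = 1e5, dispersion = 0.05,
                      n_reps = 2, seed = seed + 2)
write_count_matrix(cm, file.path(out_dir, "counts.tsv"),
                   file.path(out_dir, "counts_sidecar.tsv"))

ct <- simulate_ct(specs, designs, n_reps = 3, ct_noise_sd = 0.1, seed = seed + 3)
write_tsv(ct, file.path(out_dir, "ct_table.tsv"))

bands <- bands_to_wide(simulate_bands(specs, designs))
write_tsv(bands, file.path(out_dir, "band_patterns.tsv"))

message(sprintf(
  "simulated %d genes x %d lines: %d expression replicates, %d count samples, %d Ct records",
  nrow(specs), length(designs), nrow(reps), ncol(cm$counts), nrow(ct)
))
message("architecture classes:")
print(sort(table(specs$factor_autosomes), decreasing = TRUE))
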