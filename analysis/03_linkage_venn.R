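#!/usr/bin/env Rscript
# The core analysis: derive each gene's autosome linkage set from the
# transcribed 70-gene qPCR expression table and partition the genes into
# exact co-regulation classes. The printed significance asterisks are the
# authoritative calls; Welch p-values recomputed from the rounded printed
# summaries are written as diagnostics only.

suppressMessages(library(muscalink))
suppressMessages(library(readr))

dir.create("results", showWarnings = FALSE)

t4 <- read_table4()
calls <- call_linkage(t4, use_printed_flags = TRUE)
part <- venn_partition(calls)
singles <- single_autosome_summary(part)

write_tsv(
  calls[, c("gene_id", "linked_autosomes", "n_linked", "status", "provenance")],
  "results/linkage_calls.tsv"
)
part_out <- part
part_out$gene_ids <- vapply(part$gene_ids, paste, character(1), collapse = ";")
write_tsv(part_out, "results/venn_partition.tsv")

# diagnostics: Welch recomputed from the rounded printed mean/SE
diag <- call_linkage(t4, use_printed_flags = FALSE)
write_tsv(
  diag[, c("gene_id", "linked_autosomes", "status", "provenance")],
  "results/linkage_welch_diagnostics.tsv"
)

message(sprintf("%d of 70 genes have usable data; %d withdrawn",
                sum(calls$status == "called"), sum(calls$status == "no_data")))
message("co-regulation classes (exact subsets of autosomes):")
print(as.data.frame(part_out[, c("subset", "n")]))
message(sprintf(
  "single-autosome genes: %d total (autosome 2: %d, autosome 5: %d, autosome 3: %d)",
  singles$total, singles$per_autosome[["2"]], singles$per_autosome[["5"]],
  singles$per_autosome[["3"]]
))
message(sprintf("class {2,5}: %d genes; {1,2,5}: %d; {2,3,5}: %d",
                subset_count(part, c(2, 5)), subset_count(part, c(1, 2, 5)),
                subset_count(part, c(2, 3, 5))))

# category bookkeeping for the co-regulated classes
cat4 <- catalog_from_table4(t4)
tally25 <- tally_categories(part$gene_ids[part$subset == "2,5"][[1]], cat4)
message("function categories of the {2,5} class:")
print(as.data.frame(tally25))
write_tsv(tally25, "results/class_2_5_categories.tsv")
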