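#!/usr/bin/env Rscript
# Stage 4 — paired differential expression.
#
# Applies the completeness and unique-peptide filters to the paired
# study, runs per-protein paired t-tests on log2 intensities (volcano
# thresholds |log2FC| >= 1, p < 0.05), and calls detection-based
# enrichment for proteins that never reach the test.

suppressPackageStartupMessages(library(neutrocopy))
out <- "results/diffexpr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()

q <- read_quant_table("results/sim/quant_paired_mouse.tsv")
filt <- completeness_filter(q, min_unique_peptides = cfg$min_unique_peptides)
message(sprintf(
  "completeness: %d of %d proteins quantified in all replicates/conditions with >= %d unique peptides (removed: %d incomplete, %d low-peptide)",
  nrow(filt$table$annotation), nrow(q$annotation), cfg$min_unique_peptides,
  filt$removed[["incomplete"]], filt$removed[["few_peptides"]]))

res <- paired_ttest_table(filt$table, "blood", "brain",
                          alpha = cfg$alpha, lfc_threshold = cfg$lfc_threshold)
write.table(res, file.path(out, "paired_ttest_brain_vs_blood.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
up <- sum(res$direction == "up"); down <- sum(res$direction == "down")
message(sprintf(
  "differential: %d significant (|log2FC| >= %g, p < %g): %d up, %d down in brain",
  up + down, cfg$lfc_threshold, cfg$alpha, up, down))

truth <- read.delim("results/sim/truth_paired_mouse.tsv")
planted <- truth$protein_id[1:40]
recovered <- sum(res$significant[res$protein_id %in% planted])
tested <- sum(res$protein_id %in% planted)
message(sprintf("planted effects: %d/%d tested planted proteins recovered",
                recovered, tested))

det <- detection_enrichment(q, "blood", "brain")
det_hits <- det[det$enriched_in != "none", ]
write.table(det_hits, file.path(out, "detection_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "detection enrichment: %d proteins present in >= half of one condition but < half of the other",
  nrow(det_hits)))

write_manifest(file.path(out, "manifest.json"),
               inputs = list(quant = "results/sim/quant_paired_mouse.tsv"),
               params = cfg[c("alpha", "lfc_threshold", "min_unique_peptides")])
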