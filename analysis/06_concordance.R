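#!/usr/bin/env Rscript
# Stage 6 — cross-species and cross-inventory concordance.
#
# Compares human and mouse mean copy numbers over a synthetic ortholog
# map (log10 Pearson correlation and per-protein fold differences),
# counts ortholog overlap of the detected proteomes, and overlaps the
# detected genes with a synthetic mitochondrial-style inventory.

suppressPackageStartupMessages(library(neutrocopy))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[match("--seed", args) + 1] else 1)
out <- "results/concord"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hu <- read.delim("results/copynum/copies_human.tsv")
mo <- read.delim("results/copynum/copies_mouse.tsv")

# the simulated organisms share protein ids, which stands in for a
# 1:1 ortholog map between symbol spaces
cc <- concordance_stats(hu[!is.na(hu$copies), c("protein_id", "copies")],
                        mo[!is.na(mo$copies), c("protein_id", "copies")])
write.table(cc$pairs, file.path(out, "human_mouse_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "human vs mouse copies over %d shared proteins: r(log10) = %.3f, median fold = %.1f",
  cc$n, cc$r, median(cc$pairs$fold_1dp)))

map <- data.frame(human_symbol = hu$protein_id, mouse_symbol = mo$protein_id)
ov <- ortholog_overlap(hu$protein_id[!is.na(hu$copies)],
                       mo$protein_id[!is.na(mo$copies)], map)
message(sprintf("ortholog overlap: %d shared, %d human-only, %d mouse-only",
                ov$n_shared, ov$n_a_only, ov$n_b_only))
jsonlite::write_json(list(shared = ov$n_shared, human_only = ov$n_a_only,
                          mouse_only = ov$n_b_only),
                     file.path(out, "ortholog_overlap.json"),
                     auto_unbox = TRUE, pretty = TRUE)

# synthetic inventory: a random tenth of the simulated mouse proteome,
# standing in for a curated organelle inventory
set.seed(seed)
inventory <- sample(mo$protein_id, round(nrow(mo) / 10))
inv <- inventory_overlap(mo$protein_id[!is.na(mo$copies)], inventory)
message(sprintf("inventory overlap: %d of %d inventory entries detected (%.1f%%)",
                inv$count, length(inventory), 100 * inv$fraction))

write_manifest(file.path(out, "manifest.json"),
               inputs = list(copies = "results/copynum/copies_*.tsv"),
               params = list(inventory_fraction = 0.1), seed = seed)
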