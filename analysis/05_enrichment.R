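#!/usr/bin/env Rscript
# Stage 5 — over-representation analysis with term curation.
#
# Builds a small synthetic ontology and annotation over the paired
# study's genes, tests the significantly regulated set for
# over-representation (one-sided hypergeometric), BH-adjusts across
# terms, merges enriched direct descendants into their parents with
# pooled gene counts, and ranks the curated terms by gene count.

suppressPackageStartupMessages(library(neutrocopy))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[match("--seed", args) + 1] else 1)
out <- "results/enrich"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()

res <- read.delim("results/diffexpr/paired_ttest_brain_vs_blood.tsv")
universe <- unique(res$gene)
query <- unique(res$gene[res$significant])
message(sprintf("query: %d significant genes of %d in the universe",
                length(query), length(universe)))

# synthetic two-level ontology: 6 parents, 3 direct children each;
# child terms preferentially annotate significant genes so that the
# curation step has parent/child structure to merge
set.seed(seed)
parents <- sprintf("TRM:P%02d", 1:6)
children <- sprintf("TRM:C%02d", 1:18)
parent_of_child <- rep(parents, each = 3)
ont <- ontology(c(parents, children),
                parents = c(rep(list(character()), 6),
                            as.list(parent_of_child)))
child_sets <- setNames(lapply(1:18, function(i) {
  base <- if (i <= 6) query else universe
  sample(base, min(15, length(base)))
}), children)
# a parent term annotates its descendants' genes plus some of its own
parent_sets <- setNames(lapply(parents, function(p) {
  unique(c(unlist(child_sets[parent_of_child == p], use.names = FALSE),
           sample(universe, 10)))
}), parents)
annot <- c(parent_sets, child_sets)

rec <- fisher_enrichment(query, annot, universe, ont = ont)
write_enrichment(rec, file.path(out, "enrichment_raw.tsv"))
merged <- merge_descendants(rec[rec$q_value < cfg$go_alpha, , drop = FALSE], ont)
ranked <- rank_terms(merged, alpha = cfg$go_alpha)
write_enrichment(ranked, file.path(out, "enrichment_curated.tsv"))
message(sprintf(
  "curation: %d terms pass BH q < %g; %d remain after merging direct descendants",
  sum(rec$q_value < cfg$go_alpha), cfg$go_alpha, nrow(ranked)))
if (nrow(ranked) > 0) {
  top <- ranked[1, ]
  message(sprintf("top term %s: %d pooled genes (absorbed: %s)",
                  top$term_id, top$gene_count,
                  if (length(top$merged_children[[1]]) > 0)
                    paste(top$merged_children[[1]], collapse = ", ")
                  else "none"))
}

write_manifest(file.path(out, "manifest.json"),
               inputs = list(differential = "results/diffexpr/paired_ttest_brain_vs_blood.tsv"),
               params = list(go_alpha = cfg$go_alpha), seed = seed)
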