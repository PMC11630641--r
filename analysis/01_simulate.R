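#!/usr/bin/env Rscript
# Stage 1 — simulate the study's inputs.
#
# Generates, for human and mouse: a ground-truth proteome (log-normal
# copies rescaled to the per-cell protein mass), low-input (1000-cell)
# replicate intensity matrices with abundance-dependent dropout, a
# paired two-condition study with planted effects, antibody titrations
# for three surface targets, and a PE-bead standard table. All outputs
# are plain TSV/CSV under results/sim/ and are consumed by the later
# stages.

suppressPackageStartupMessages(library(neutrocopy))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[match("--seed", args) + 1] else 1)
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_proteins = 5000)
truth <- list(human = gen_proteome(cfg, default_species("human"), seed = seed))

# mouse ortholog copies co-vary with human (rho = 0.8 on the log scale),
# then are rescaled to the mouse per-cell protein and DNA masses the
# same way gen_proteome pins its own draws
rho <- 0.8
sp_m <- default_species("mouse")
set.seed(seed + 1)
z_h <- scale(log(truth$human$copies))[, 1]
z_m <- rho * z_h + sqrt(1 - rho^2) * rnorm(length(z_h))
mo <- truth$human
mo$copies <- exp(cfg$copy_lognormal_mu + cfg$copy_lognormal_sigma * z_m)
mass_pg <- function(t, idx) sum(t$copies[idx] * t$mw_da[idx]) / AVOGADRO * 1e12
h <- mo$is_histone
mo$copies[h] <- mo$copies[h] * sp_m$dna_mass_pg / mass_pg(mo, h)
mo$copies[!h] <- mo$copies[!h] *
  (sp_m$total_protein_mass_pg - sp_m$dna_mass_pg) / mass_pg(mo, !h)
truth$mouse <- mo

for (org in c("human", "mouse")) {
  write.table(truth[[org]], file.path(out, sprintf("truth_%s.tsv", org)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  q <- gen_quant_matrix(truth[[org]], cfg, input_cells = 1000, seed = seed + 10)
  write_quant_table(q, file.path(out, sprintf("quant_%s_1000cells.tsv", org)))
  message(sprintf(
    "%s: %d proteins simulated, %.1f%% of intensity cells missing at 1000-cell input",
    org, nrow(truth[[org]]), 100 * mean(is.na(q$intensities))))
}

# paired brain-vs-blood style design (mouse, n = 3 subjects) with 40
# planted effects of +/-2 log2 units
cfg_p <- sim_config(n_proteins = 3000, n_subjects = 3,
                    conditions = c("blood", "brain"),
                    planted_effects = data.frame(protein = 1:40,
                                                 log2fc = rep(c(2, -2), 20)))
truth_p <- gen_proteome(cfg_p, default_species("mouse"), seed = seed + 20)
qp <- gen_paired_study(truth_p, cfg_p, input_cells = 1000,
                       subject_cv = 0.3, seed = seed + 21)
write_quant_table(qp, file.path(out, "quant_paired_mouse.tsv"))
write.table(truth_p, file.path(out, "truth_paired_mouse.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("paired study: %d proteins x %d samples, 40 planted effects",
                nrow(truth_p), ncol(qp$intensities)))

# qFlow inputs: titrations for three targets plus one bead table; the
# per-target true molecule counts are chosen in the mid-1e4..1e6 range
# the surface targets occupy
targets <- data.frame(target = c("CD11b", "CXCR2", "CD82"),
                      true_copies = c(3e5, 2.5e4, 2e4))
slope <- 1.02; intercept <- 0.9; fp <- 0.95; L <- 1.25
write.table(targets, file.path(out, "qflow_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
beads <- gen_beads(c(200, 2000, 20000, 60000), slope, intercept,
                   cv = 0.02, seed = seed + 30)
write.csv(beads, file.path(out, "beads.csv"), row.names = FALSE, quote = FALSE)
for (i in seq_len(nrow(targets))) {
  corrected <- 10^((log10(targets$true_copies[i] / fp) - intercept) / slope)
  y0c <- corrected / L
  comb <- gen_titration(saturation_fit(y0c, -0.92 * y0c, -0.009), cv = 0.05,
                        target = targets$target[i],
                        stain_context = "combined_fixed_perm",
                        seed = seed + 40 + i)
  y0s <- y0c * 0.8
  surf <- gen_titration(saturation_fit(y0s, -0.9 * y0s, -0.011), cv = 0.05,
                        target = targets$target[i], seed = seed + 50 + i)
  write_titration_csv(comb, file.path(out, sprintf("titration_combined_%s.csv",
                                                   targets$target[i])))
  write_titration_csv(surf, file.path(out, sprintf("titration_surface_%s.csv",
                                                   targets$target[i])))
}
message(sprintf("qFlow inputs for %d targets written (L = %.2f, F:P = %.2f)",
                nrow(targets), L, fp))

write_manifest(file.path(out, "manifest.json"),
               inputs = list(),
               params = list(n_proteins = 5000, paired_n = 3000,
                             loss_factor = L, fp_ratio = fp,
                             bead_slope = slope, bead_intercept = intercept),
               seed = seed)
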