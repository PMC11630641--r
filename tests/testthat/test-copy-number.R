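# Copy-number estimation: contaminant filtering, the two normalization
# approaches, abundance classes and composition statistics.

test_that("contaminant filter removes listed genes and anchored patterns", {
  m <- matrix(1:10, nrow = 5,
              dimnames = list(NULL, c("A:S01:R1", "A:S02:R1")))
  q <- tiny_quant(m)
  q$annotation$gene <- c("MPO", "KRT1", "HBA1", "HBEGF", "ELANE")

  res <- filter_contaminants(q, contaminants = c("KRT1", "ALB"))
  expect_equal(nrow(res$table$annotation), 4)
  expect_equal(res$removed$gene, "KRT1")

  res2 <- filter_contaminants(q, contaminants = "KRT1",
                              extra_patterns = "^HB[AB]")
  expect_setequal(res2$removed$gene, c("KRT1", "HBA1"))
  # HBEGF survives the anchored hemoglobin family pattern
  expect_true("HBEGF" %in% res2$table$annotation$gene)

  res3 <- filter_contaminants(q, contaminants = character())
  expect_equal(res3$table$annotation, q$annotation)
  expect_equal(nrow(res3$removed), 0)
})

test_that("total protein approach: single-protein and symmetry cases", {
  m <- matrix(c(1000), 1, dimnames = list(NULL, "A:S01:R1"))
  q1 <- tiny_quant(m, mw = 5e4)
  sp <- species_profile("x", total_protein_mass_pg = 50, dna_mass_pg = 6.5)
  ct <- total_protein_copies(q1, sp, "A:S01:R1")
  # the whole 50 pg is this one protein: 50e-12 * N_A / 5e4
  expect_equal(ct$table$copies, 50e-12 * AVOGADRO / 5e4, tolerance = 1e-12)
  expect_equal(signif(ct$table$copies, 5), 6.0221e8)

  m2 <- matrix(c(700, 700), 2, dimnames = list(NULL, "A:S01:R1"))
  q2 <- tiny_quant(m2, mw = c(5e4, 5e4))
  ct2 <- total_protein_copies(q2, sp, "A:S01:R1")
  expect_equal(ct2$table$copies, rep(ct$table$copies / 2, 2), tolerance = 1e-12)
})

test_that("total protein approach conserves mass and ignores sample scale", {
  cfg <- sim_config(n_proteins = 100)
  sp <- default_species("mouse")
  truth <- gen_proteome(cfg, sp, seed = 11)
  q <- gen_quant_matrix(truth, cfg, seed = 12)
  for (s in colnames(q$intensities)) {
    ct <- total_protein_copies(q, sp, s)
    mass <- sum(ct$table$copies * ct$table$mw_da, na.rm = TRUE) / AVOGADRO * 1e12
    expect_equal(mass, sp$total_protein_mass_pg, tolerance = 1e-9)
  }
  # doubling the sample's intensities changes nothing
  q2 <- q; q2$intensities <- q$intensities * 2
  s1 <- colnames(q$intensities)[1]
  expect_equal(total_protein_copies(q2, sp, s1)$table$copies,
               total_protein_copies(q, sp, s1)$table$copies, tolerance = 1e-12)
})

test_that("noise-free synthetic intensities recover true copies exactly", {
  cfg <- sim_config(n_proteins = 300, intensity_cv = 0, sample_scale_cv = 0)
  sp <- default_species("human")
  truth <- gen_proteome(cfg, sp, seed = 5)
  q <- gen_quant_matrix(truth, cfg, dropout = FALSE, seed = 6)
  ct <- total_protein_copies(q, sp, colnames(q$intensities)[1])
  expect_equal(ct$table$copies, truth$copies, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("proteomic ruler: self-referential histone case and scale invariance", {
  m <- matrix(c(2000, 500), 2, dimnames = list(NULL, "A:S01:R1"))
  q <- tiny_quant(m, mw = c(14000, 5e4))
  q$annotation$gene <- c("H4C1", "MPO")
  sp <- species_profile("x", total_protein_mass_pg = 50, dna_mass_pg = 6.5,
                        histone_ids = "H4C1")
  ct <- proteomic_ruler_copies(q, sp, "A:S01:R1")
  # the single histone carries the whole DNA-equivalent mass
  expect_equal(ct$table$copies[1], 6.5e-12 * AVOGADRO / 1.4e4, tolerance = 1e-12)
  expect_equal(signif(ct$table$copies[1], 4), 2.796e8)

  q2 <- q; q2$intensities <- q$intensities * 7
  expect_equal(proteomic_ruler_copies(q2, sp, "A:S01:R1")$table$copies,
               ct$table$copies, tolerance = 1e-12)

  sp0 <- species_profile("x", 50, 6.5, histone_ids = "H3C1")
  expect_error(proteomic_ruler_copies(q, sp0, "A:S01:R1"),
               class = "ncp_ruler_unavailable_error")
})

test_that("ruler estimates track truth on noisy synthetic data", {
  cfg <- sim_config(n_proteins = 400, intensity_cv = 0.05)
  sp <- default_species("human")
  truth <- gen_proteome(cfg, sp, seed = 21)
  q <- gen_quant_matrix(truth, cfg, dropout = FALSE, seed = 22)
  ct <- proteomic_ruler_copies(q, sp, colnames(q$intensities)[1])
  r <- cor(log10(ct$table$copies), log10(truth$copies))
  expect_gt(r, 0.99)
})

test_that("the two approaches agree when consistently parameterized", {
  cfg <- sim_config(n_proteins = 500, intensity_cv = 0.05)
  sp <- default_species("human")
  truth <- gen_proteome(cfg, sp, seed = 31)
  q <- gen_quant_matrix(truth, cfg, dropout = FALSE, seed = 32)
  s <- colnames(q$intensities)[1]
  cmp <- compare_methods(total_protein_copies(q, sp, s),
                         proteomic_ruler_copies(q, sp, s))
  expect_gt(cmp$r, 0.999)
  expect_gt(cmp$median_ratio, 0.8)
  expect_lt(cmp$median_ratio, 1.25)

  # identity and pure-scale comparisons
  a <- total_protein_copies(q, sp, s)
  cmp_id <- compare_methods(a, a)
  expect_equal(cmp_id$r, 1, tolerance = 1e-12)
  expect_equal(unique(cmp_id$pairs$ratio), 1)
  b <- a; b$table$copies <- a$table$copies * 2
  cmp_sc <- compare_methods(a, b)
  expect_equal(cmp_sc$r, 1, tolerance = 1e-12)
  expect_equal(unique(round(cmp_sc$pairs$ratio, 12)), 2)
})

test_that("abundance classes use strict outer bounds and a closed middle", {
  ct <- neutrocopy:::new_copy_table(
    data.frame(protein_id = sprintf("P%d", 1:6), gene = sprintf("G%d", 1:6),
               mw_da = rep(5e4, 6)),
    c(6e5, 5e5 + 1e-6, 5e5, 1e4, 9999, NA), "total_protein", NULL, "s")
  cc <- classify_abundance(ct)
  expect_equal(cc$table$abundance_class,
               c("high", "high", "medium", "medium", "low", NA))
  # partition: every quantified protein gets exactly one class
  expect_false(anyNA(cc$table$abundance_class[!is.na(cc$table$copies)]))
})

test_that("topk_share computes exact fractions with deterministic ties", {
  ct <- neutrocopy:::new_copy_table(
    data.frame(protein_id = c("P1", "P2"), gene = c("a", "b"),
               mw_da = c(1, 1)),
    c(80, 20), "total_protein", NULL, "s")
  expect_equal(topk_share(ct, 1), 0.8)
  expect_equal(topk_share(ct, 2), 1.0)
  expect_error(topk_share(ct, 0), class = "ncp_argument_error")
  expect_error(topk_share(ct, 3), class = "ncp_argument_error")

  # tie at rank k broken by protein id: P1 and P2 tie, k = 1 picks P1
  tie <- neutrocopy:::new_copy_table(
    data.frame(protein_id = c("P2", "P1", "P3"), gene = letters[1:3],
               mw_da = rep(1, 3)),
    c(50, 50, 10), "total_protein", NULL, "s")
  expect_equal(topk_share(tie, 1), 50 / 110)
})
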