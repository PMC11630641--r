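# Paired differential expression: filters, the t-test against
# independent oracles, BH adjustment and detection-based enrichment.

test_that("completeness filter applies both rules and counts removals", {
  m <- matrix(c(10, 20, 30, 40, 50,
                11, NA, 31, 41, 51,
                12, 22, 32, 42, 52,
                13, 23, 33, 43, 53), nrow = 5,
              dimnames = list(NULL, c("A:S01:R1", "A:S02:R1",
                                      "B:S01:R1", "B:S02:R1")))
  q <- tiny_quant(m, upep = c(3L, 3L, 1L, 3L, 3L))
  res <- completeness_filter(q)
  # one protein misses a replicate, one has a single unique peptide
  expect_equal(nrow(res$table$annotation), 3)
  expect_equal(unname(res$removed), c(1, 1))
  expect_false("P002" %in% res$table$annotation$protein_id)
  expect_false("P003" %in% res$table$annotation$protein_id)
})

test_that("relaxed completeness keeps proteins above the fraction", {
  m <- matrix(c(10, NA, NA, NA,
                11, 21, 31, 41), byrow = TRUE, nrow = 2,
              dimnames = list(NULL, c("A:S01:R1", "A:S02:R1",
                                      "B:S01:R1", "B:S02:R1")))
  q <- tiny_quant(m)
  strict <- completeness_filter(q)
  expect_equal(nrow(strict$table$annotation), 1)
  relaxed <- completeness_filter(q, require_all = FALSE, min_fraction = 0.5)
  # detected in half the replicates of each condition: kept
  expect_equal(nrow(relaxed$table$annotation), 1)
  m2 <- m; m2[1, c(1, 3)] <- c(10, 30)
  relaxed2 <- completeness_filter(tiny_quant(m2), require_all = FALSE,
                                  min_fraction = 0.5)
  expect_equal(nrow(relaxed2$table$annotation), 2)
})

test_that("empty tables pass through the filter unchanged", {
  m <- matrix(numeric(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("A:S01:R1", "B:S01:R1")))
  q <- quant_table(
    data.frame(protein_id = character(), gene = character(),
               mw_da = numeric(), unique_peptides = integer()),
    m, neutrocopy:::parse_sample_names(colnames(m)))
  expect_equal(nrow(completeness_filter(q)$table$annotation), 0)
})

test_that("paired t-test matches the closed-form worked example", {
  # per-subject log2 differences 1, 2, 3
  A <- c(100, 100, 100)
  m <- matrix(c(A, A * 2^c(1, 2, 3)), nrow = 1)
  colnames(m) <- c("A:S01:R1", "A:S02:R1", "A:S03:R1",
                   "B:S01:R1", "B:S02:R1", "B:S03:R1")
  q <- tiny_quant(m, conditions = c("A", "B"), n_subjects = 3)
  res <- paired_ttest_table(q, "A", "B")
  expect_equal(res$log2fc, 2, tolerance = 1e-12)
  expect_equal(res$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(round(res$t_stat, 4), 3.4641)
  expect_equal(res$p_value, 2 * pt(sqrt(12), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0742)
  # p = 0.074 misses the 0.05 cut despite the 2-unit fold change
  expect_false(res$significant)
  expect_equal(res$direction, "ns")
})

test_that("paired t-test agrees with t.test per protein on random data", {
  set.seed(99)
  n_prot <- 40; n_subj <- 5
  m <- matrix(2^rnorm(n_prot * 2 * n_subj, 10, 1), nrow = n_prot)
  colnames(m) <- c(sprintf("A:S%02d:R1", 1:n_subj),
                   sprintf("B:S%02d:R1", 1:n_subj))
  q <- tiny_quant(m, conditions = c("A", "B"), n_subjects = n_subj)
  res <- paired_ttest_table(q, "A", "B")
  for (i in seq_len(n_prot)) {
    or <- t.test(log2(m[i, n_subj + 1:n_subj]), log2(m[i, 1:n_subj]),
                 paired = TRUE)
    expect_equal(res$log2fc[i], unname(or$estimate), tolerance = 1e-12)
    expect_equal(res$t_stat[i], unname(or$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], or$p.value, tolerance = 1e-12)
  }
  # up + down counts partition the significant calls
  expect_equal(sum(res$direction %in% c("up", "down")), sum(res$significant))
})

test_that("zero-variance proteins are flagged, not called significant", {
  m <- matrix(c(100, 100, 100, 400, 400, 400), nrow = 1)
  colnames(m) <- c("A:S01:R1", "A:S02:R1", "A:S03:R1",
                   "B:S01:R1", "B:S02:R1", "B:S03:R1")
  q <- tiny_quant(m, conditions = c("A", "B"), n_subjects = 3)
  res <- paired_ttest_table(q, "A", "B")
  expect_true(res$zero_variance)
  expect_true(is.na(res$p_value))
  expect_false(res$significant)
  expect_equal(res$log2fc, 2)
})

test_that("unpaired designs are rejected", {
  m <- matrix(1:4, nrow = 1)
  colnames(m) <- c("A:S01:R1", "A:S02:R1", "B:S01:R1", "B:S03:R1")
  ann <- data.frame(protein_id = "P1", gene = "G1", mw_da = 5e4,
                    unique_peptides = 3L)
  q <- quant_table(ann, m, neutrocopy:::parse_sample_names(colnames(m)))
  expect_error(paired_ttest_table(q, "A", "B"), class = "ncp_design_error")
})

test_that("null simulations match a sign-flip permutation oracle", {
  cfg <- sim_config(n_proteins = 2000, n_subjects = 3, intensity_cv = 0.3,
                    planted_effects = NULL)
  truth <- gen_proteome(cfg, default_species("mouse"), seed = 51)
  q <- gen_paired_study(truth, cfg, dropout = FALSE, subject_cv = 0.1,
                        seed = 52)
  res <- paired_ttest_table(q, "A", "B")
  obs <- sum(res$significant)

  # oracle: expected joint-threshold null rate from all 2^3 sign flips
  sm <- q$sample_meta
  a_cols <- sm$sample[sm$condition == "A"]; b_cols <- sm$sample[sm$condition == "B"]
  d <- log2(q$intensities[, b_cols]) - log2(q$intensities[, a_cols])
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  hits <- 0
  for (r in seq_len(nrow(signs))) {
    ds <- sweep(d, 2, signs[r, ], `*`)
    mu <- rowMeans(ds); sdd <- apply(ds, 1, sd)
    tt <- mu / (sdd / sqrt(3))
    p <- 2 * pt(abs(tt), 2, lower.tail = FALSE)
    hits <- hits + sum(p < 0.05 & abs(mu) >= 1, na.rm = TRUE)
  }
  rate <- hits / (nrow(signs) * nrow(d))
  bounds <- qbinom(c(0.005, 0.995), nrow(d), max(rate, 1e-12))
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])
})

test_that("planted effects are recovered with high power, lost if unpaired", {
  n_eff <- 25
  cfg <- sim_config(n_proteins = 200, n_subjects = 3, intensity_cv = 0.1,
                    planted_effects = data.frame(protein = 1:n_eff,
                                                 log2fc = 2))
  sp <- default_species("mouse")
  power <- vapply(1:100, function(s) {
    truth <- gen_proteome(cfg, sp, seed = 60)
    q <- gen_paired_study(truth, cfg, dropout = FALSE, subject_cv = 0.5,
                          seed = 600 + s)
    res <- paired_ttest_table(q, "A", "B")
    mean(res$significant[1:n_eff])
  }, 0)
  expect_gt(mean(power), 0.8)

  # destroying the pairing by shuffling subject labels within conditions
  # costs power when subject effects are strong
  unpaired_power <- vapply(1:30, function(s) {
    truth <- gen_proteome(cfg, sp, seed = 60)
    q <- gen_paired_study(truth, cfg, dropout = FALSE, subject_cv = 0.5,
                          seed = 600 + s)
    sm <- q$sample_meta
    b <- sm$condition == "B"
    set.seed(s)
    sm$subject[b] <- sample(sm$subject[b])
    q$sample_meta <- sm
    res <- paired_ttest_table(q, "A", "B")
    mean(res$significant[1:n_eff])
  }, 0)
  expect_lt(mean(unpaired_power), mean(power))
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  # permutation invariance up to reordering
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ncp_domain_error")
})

test_that("detection enrichment implements the less-than-half rule", {
  mk <- function(det_a, det_b, n = 7) {
    row <- c(ifelse(seq_len(n) <= det_a, 100, NA),
             ifelse(seq_len(n) <= det_b, 100, NA))
    m <- matrix(row, nrow = 1)
    colnames(m) <- c(sprintf("A:S%02d:R1", 1:n), sprintf("B:S%02d:R1", 1:n))
    tiny_quant(m, conditions = c("A", "B"), n_subjects = n)
  }
  # 7/7 in lavage (B), 3/7 in blood (A): 3 < 3.5, enriched in B
  expect_equal(detection_enrichment(mk(3, 7), "A", "B")$enriched_in, "B")
  # 4/7 in blood: 4 >= 3.5, not enriched
  expect_equal(detection_enrichment(mk(4, 7), "A", "B")$enriched_in, "none")
  # absent everywhere
  expect_equal(detection_enrichment(mk(0, 0), "A", "B")$enriched_in, "none")
  # symmetric call for condition A
  expect_equal(detection_enrichment(mk(7, 2), "A", "B")$enriched_in, "A")
})
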