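# Paired differential-expression analysis on log2 intensities with the
# completeness and unique-peptide filters applied upstream, plus the
# detection-based enrichment rule for presence/absence patterns.

#' Completeness and unique-peptide filter
#'
#' Keeps proteins quantified consistently across the design: non-missing
#' intensity in every sample of every condition (or, with
#' `require_all = FALSE`, in at least `min_fraction` of the samples of
#' each condition) and at least `min_unique_peptides` unique peptides.
#'
#' @param q [quant_table].
#' @param min_unique_peptides unique-peptide threshold (default 2).
#' @param require_all require detection in every sample (default).
#' @param min_fraction minimum detected fraction per condition when
#'   `require_all = FALSE`.
#' @return list with `table` (filtered quant_table) and `removed`
#'   (named counts: `incomplete`, `few_peptides`).
#' @export
completeness_filter <- function(q, min_unique_peptides = 2,
                                require_all = TRUE, min_fraction = 0.5) {
  if (ncol(q$intensities) == 0)
    ncp_stop("quant table has no samples", "ncp_empty_design_error")
  conds <- unique(q$sample_meta$condition)
  det <- !is.na(q$intensities)
  complete <- rep(TRUE, nrow(det))
  for (cn in conds) {
    cols <- q$sample_meta$condition == cn
    frac <- rowMeans(det[, cols, drop = FALSE])
    complete <- complete & (if (require_all) frac == 1 else frac >= min_fraction)
  }
  enough_pep <- q$annotation$unique_peptides >= min_unique_peptides
  keep <- complete & enough_pep
  removed <- c(incomplete = sum(!complete),
               few_peptides = sum(complete & !enough_pep))
  tab <- if (all(keep)) q else if (!any(keep)) {
    quant_table(q$annotation[0, , drop = FALSE],
                q$intensities[0, , drop = FALSE], q$sample_meta)
  } else qt_subset(q, keep)
  list(table = tab, removed = removed)
}

#' Paired t-tests per protein
#'
#' For each protein, computes the per-subject log2 difference
#' `d_s = log2(I_B,s) - log2(I_A,s)`, then `log2fc = mean(d)`,
#' `t = mean(d) / (sd(d) / sqrt(n))` and a two-sided p-value from the t
#' distribution with `n - 1` degrees of freedom. A protein is called
#' significant when `|log2fc| >= lfc_threshold` and `p < alpha` (raw p,
#' as in volcano-style reporting); BH-adjusted q-values are reported
#' alongside. Zero-variance difference vectors get a missing p-value and
#' a `zero_variance` flag instead of a significance call.
#'
#' @param q [quant_table]; normally the output of
#'   [completeness_filter()], so every protein is complete in both
#'   conditions.
#' @param condA,condB condition labels; the fold change is
#'   `condB / condA`.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @return data.frame `protein_id`, `gene`, `log2fc`, `t_stat`,
#'   `p_value`, `q_value`, `significant`, `direction` (up/down/ns),
#'   `zero_variance`.
#' @export
paired_ttest_table <- function(q, condA, condB, alpha = 0.05,
                               lfc_threshold = 1) {
  sm <- q$sample_meta
  a_cols <- sm$sample[sm$condition == condA]
  b_cols <- sm$sample[sm$condition == condB]
  if (length(a_cols) == 0 || length(b_cols) == 0)
    ncp_stop("both conditions must be present in the design",
             "ncp_design_error")
  a_subj <- sm$subject[match(a_cols, sm$sample)]
  b_subj <- sm$subject[match(b_cols, sm$sample)]
  subjects <- intersect(a_subj, b_subj)
  if (!setequal(a_subj, b_subj) || anyDuplicated(a_subj) || anyDuplicated(b_subj))
    ncp_stop("design is not paired: each subject needs exactly one sample per condition",
             "ncp_design_error")
  n <- length(subjects)
  if (n < 2)
    ncp_stop("need at least 2 paired subjects", "ncp_design_error")
  A <- q$intensities[, a_cols[match(subjects, a_subj)], drop = FALSE]
  B <- q$intensities[, b_cols[match(subjects, b_subj)], drop = FALSE]
  d <- log2(B) - log2(A)
  log2fc <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  zero_var <- is.finite(log2fc) & sd_d == 0
  t_stat <- log2fc / (sd_d / sqrt(n))
  t_stat[zero_var] <- NA_real_
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  q_val <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q_val[ok] <- bh_adjust(p[ok])
  significant <- !is.na(p) & p < alpha & abs(log2fc) >= lfc_threshold
  direction <- ifelse(!significant, "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(protein_id = q$annotation$protein_id,
             gene = q$annotation$gene,
             log2fc = log2fc, t_stat = t_stat,
             p_value = p, q_value = q_val,
             significant = significant, direction = direction,
             zero_variance = zero_var,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (wraps
#' `stats::p.adjust(method = "BH")` after validating the domain).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    ncp_stop("p-values must lie in [0, 1]", "ncp_domain_error")
  stats::p.adjust(p, method = "BH")
}

#' Detection-based enrichment calls
#'
#' Flags proteins whose presence/absence pattern separates the two
#' conditions: enriched in B when detected in at least half
#' (`ceiling(n_B / 2)`) of the B replicates but in strictly fewer than
#' half (`< n_A / 2`) of the A replicates; the symmetric rule gives
#' enrichment in A. This captures proteins that never reach the paired
#' test because they fail the completeness filter.
#'
#' @param q [quant_table] (unfiltered; detection = non-missing
#'   intensity).
#' @param condA,condB condition labels.
#' @return data.frame `protein_id`, `gene`, `detected_a`, `detected_b`,
#'   `n_a`, `n_b`, `enriched_in` ("A", "B" or "none").
#' @export
detection_enrichment <- function(q, condA, condB) {
  sm <- q$sample_meta
  a_cols <- sm$sample[sm$condition == condA]
  b_cols <- sm$sample[sm$condition == condB]
  n_a <- length(a_cols); n_b <- length(b_cols)
  det_a <- rowSums(!is.na(q$intensities[, a_cols, drop = FALSE]))
  det_b <- rowSums(!is.na(q$intensities[, b_cols, drop = FALSE]))
  in_b <- det_b >= ceiling(n_b / 2) & det_a < n_a / 2
  in_a <- det_a >= ceiling(n_a / 2) & det_b < n_b / 2
  enriched <- ifelse(in_b, "B", ifelse(in_a, "A", "none"))
  data.frame(protein_id = q$annotation$protein_id,
             gene = q$annotation$gene,
             detected_a = det_a, detected_b = det_b,
             n_a = n_a, n_b = n_b,
             enriched_in = enriched,
             stringsAsFactors = FALSE, row.names = NULL)
}
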