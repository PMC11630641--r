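# Absolute copy-number estimation: the total protein approach (each
# protein's share of total MS signal times the cell's protein mass) and
# the histone-based proteomic ruler (histone signal as a proxy for the
# fixed DNA mass per cell), plus abundance classification and
# composition statistics.

#' Remove contaminant proteins
#'
#' Drops rows whose gene symbol or protein id is in the contaminant set
#' or matches one of the regex patterns (e.g. anchored immunoglobulin or
#' hemoglobin family patterns). Matching is case-insensitive on
#' upper-cased identifiers.
#'
#' @param q [quant_table].
#' @param contaminants character vector of identifiers
#'   (see [read_gene_list()]).
#' @param extra_patterns optional character vector of regular expressions
#'   applied to the gene symbol.
#' @return list with `table` (filtered quant_table) and `removed`
#'   (data.frame `protein_id`, `gene`, `reason`).
#' @export
filter_contaminants <- function(q, contaminants = character(),
                                extra_patterns = NULL) {
  gene_up <- toupper(q$annotation$gene)
  id_up <- toupper(q$annotation$protein_id)
  set <- toupper(contaminants)
  in_list <- gene_up %in% set | id_up %in% set
  reason <- ifelse(in_list, "contaminant_list", NA_character_)
  if (!is.null(extra_patterns)) {
    for (pat in extra_patterns) {
      hit <- grepl(pat, gene_up) & is.na(reason)
      reason[hit] <- paste0("pattern:", pat)
    }
  }
  drop <- !is.na(reason)
  removed <- data.frame(protein_id = q$annotation$protein_id[drop],
                        gene = q$annotation$gene[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  list(table = if (any(drop)) qt_subset(q, !drop) else q, removed = removed)
}

new_copy_table <- function(ann, copies, method, species, sample) {
  structure(
    list(table = data.frame(protein_id = ann$protein_id, gene = ann$gene,
                            mw_da = ann$mw_da, copies = copies,
                            stringsAsFactors = FALSE),
         method = method, species = species, sample = sample),
    class = "copy_number_table"
  )
}

#' @export
print.copy_number_table <- function(x, ...) {
  det <- !is.na(x$table$copies)
  cat(sprintf("copy_number_table (%s, sample %s): %d proteins, %d with copies\n",
              x$method, x$sample %||% "?", nrow(x$table), sum(det)))
  if (any(det))
    cat(sprintf("  copies/cell range: %.3g - %.3g\n",
                min(x$table$copies[det]), max(x$table$copies[det])))
  invisible(x)
}

#' Total protein approach to copies per cell
#'
#' `copies_i = I_i / sum_j(I_j) * M_total * N_A / mw_i`, with the total
#' protein mass per cell `M_total` taken from the species profile.
#' Missing intensities contribute nothing to the total signal and yield
#' missing copies. By construction the estimated copies of the detected
#' proteins conserve the configured protein mass exactly.
#'
#' @param q [quant_table] (contaminants should be removed first — the
#'   total signal is computed over the rows present).
#' @param sp [species_profile].
#' @param sample sample id (column of the intensity matrix).
#' @return A `copy_number_table`.
#' @export
total_protein_copies <- function(q, sp, sample) {
  I <- intensity_column(q, sample)
  if (all(is.na(I)))
    ncp_stop(sprintf("sample '%s' has no detected proteins", sample),
             "ncp_empty_sample_error")
  total <- sum(I, na.rm = TRUE)
  mass_g <- sp$total_protein_mass_pg * 1e-12
  copies <- (I / total) * mass_g * AVOGADRO / q$annotation$mw_da
  new_copy_table(q$annotation, copies, "total_protein", sp, sample)
}

#' Proteomic ruler copies per cell
#'
#' Uses the summed histone MS signal as a stand-in for the fixed DNA
#' mass per cell:
#' `copies_i = I_i * N_A * m_DNA / (mw_i * sum_h(I_h))` with the sum over
#' the histone set of the species profile. Scale-invariant in the
#' intensities; histones themselves are kept in the output.
#'
#' @param q [quant_table].
#' @param sp [species_profile]; `histone_ids` must be non-empty.
#' @param sample sample id.
#' @return A `copy_number_table`.
#' @export
proteomic_ruler_copies <- function(q, sp, sample) {
  if (length(sp$histone_ids) == 0)
    ncp_stop("species profile has no histone ids", "ncp_ruler_unavailable_error")
  I <- intensity_column(q, sample)
  is_hist <- toupper(q$annotation$gene) %in% toupper(sp$histone_ids)
  hist_sig <- sum(I[is_hist], na.rm = TRUE)
  if (!any(is_hist & !is.na(I)) || hist_sig <= 0)
    ncp_stop(sprintf("no histone detected in sample '%s'; ruler unavailable",
                     sample), "ncp_ruler_unavailable_error")
  dna_g <- sp$dna_mass_pg * 1e-12
  copies <- I * AVOGADRO * dna_g / (q$annotation$mw_da * hist_sig)
  new_copy_table(q$annotation, copies, "proteomic_ruler", sp, sample)
}

intensity_column <- function(q, sample) {
  if (!sample %in% colnames(q$intensities))
    ncp_stop(sprintf("unknown sample '%s'", sample), "ncp_argument_error")
  q$intensities[, sample]
}

#' Average copy-number tables over samples
#'
#' Arithmetic mean of per-sample copies (missing values dropped per
#' protein); used to report per-condition averages over replicates.
#'
#' @param tables list of `copy_number_table`s over the same proteins.
#' @return A `copy_number_table` with the mean copies and sample label
#'   "mean".
#' @export
mean_copy_table <- function(tables) {
  stopifnot(length(tables) >= 1)
  mat <- vapply(tables, function(t) t$table$copies,
                numeric(nrow(tables[[1]]$table)))
  mat <- matrix(mat, nrow = nrow(tables[[1]]$table))
  m <- rowMeans(mat, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  out <- tables[[1]]
  out$table$copies <- m
  out$sample <- "mean"
  out
}

#' Compare two copy-number tables
#'
#' Per-protein ratio (b / a) over shared proteins with copies in both,
#' plus the Pearson correlation of log10 copies.
#'
#' @param a,b `copy_number_table`s.
#' @return list with `pairs` (data.frame `protein_id`, `copies_a`,
#'   `copies_b`, `ratio`), `r` (log10-scale Pearson) and `median_ratio`.
#' @export
compare_methods <- function(a, b) {
  m <- merge(a$table[c("protein_id", "copies")],
             b$table[c("protein_id", "copies")],
             by = "protein_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$copies_a) & !is.na(m$copies_b) &
           m$copies_a > 0 & m$copies_b > 0, ]
  if (nrow(m) < 3)
    ncp_stop("fewer than 3 shared quantified proteins",
             "ncp_insufficient_overlap_error")
  m$ratio <- m$copies_b / m$copies_a
  list(pairs = m,
       r = stats::cor(log10(m$copies_a), log10(m$copies_b)),
       median_ratio = stats::median(m$ratio))
}

#' Classify proteins by abundance
#'
#' High-abundance proteins have more than 5e5 copies/cell, low-abundance
#' fewer than 1e4; medium is the closed interval between the two (so the
#' printed strict bounds of the outer classes are preserved).
#'
#' @param ct `copy_number_table`.
#' @param high_min exclusive lower bound of the high class.
#' @param low_max exclusive upper bound of the low class.
#' @return `ct` with an added `abundance_class` column
#'   (high/medium/low, NA for missing copies).
#' @export
classify_abundance <- function(ct, high_min = 5e5, low_max = 1e4) {
  cp <- ct$table$copies
  cls <- ifelse(is.na(cp), NA_character_,
         ifelse(cp > high_min, "high",
         ifelse(cp < low_max, "low", "medium")))
  ct$table$abundance_class <- cls
  ct
}

#' Share of total copies held by the top-k proteins
#'
#' Fraction of all copies contributed by the `k` most abundant proteins.
#' Ties at rank k are broken by protein id so the result is
#' deterministic.
#'
#' @param ct `copy_number_table`.
#' @param k number of top proteins (e.g. 150).
#' @return fraction in `[0, 1]`.
#' @export
topk_share <- function(ct, k) {
  tab <- ct$table[!is.na(ct$table$copies), ]
  n <- nrow(tab)
  if (k <= 0 || k > n)
    ncp_stop(sprintf("k must be in [1, %d]", n), "ncp_argument_error")
  ord <- order(-tab$copies, tab$protein_id)
  sum(tab$copies[ord[seq_len(k)]]) / sum(tab$copies)
}

#' Write a copy-number table to TSV
#' @param ct `copy_number_table` (optionally classified).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_copy_table <- function(ct, path) {
  out <- ct$table
  out$method <- ct$method
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
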