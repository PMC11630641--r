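# Over-representation testing and ontology curation: one-sided
# hypergeometric enrichment per term, BH adjustment across terms,
# merging of enriched direct descendants into their parent terms with
# pooled gene counts, and ranking of the curated list by gene count.

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the query gene set overlaps the term's
#' annotated genes more than expected by chance: with `N = |universe|`,
#' `K = |term|`, `n = |query|` and `k = |overlap|`, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Term gene sets are
#' clipped to the universe.
#'
#' @param query_genes character vector of query genes (must lie in the
#'   universe).
#' @param term_genes named list mapping term id to its annotated gene
#'   set.
#' @param universe character vector of background genes.
#' @param ont optional [ontology] supplying term names.
#' @return data.frame of class `enrichment_result`: `term_id`, `name`,
#'   `gene_count` (overlap size), `p_value`, `q_value` (BH over the
#'   tested terms), `genes` (list column of overlap genes),
#'   `merged_children` (empty; filled by [merge_descendants()]).
#' @export
fisher_enrichment <- function(query_genes, term_genes, universe, ont = NULL) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query_genes))
  if (!all(query %in% universe))
    ncp_stop("query genes must be a subset of the universe",
             "ncp_validation_error")
  N <- length(universe); n <- length(query)
  ids <- names(term_genes)
  rows <- lapply(ids, function(id) {
    genes <- intersect(unique(toupper(term_genes[[id]])), universe)
    K <- length(genes)
    overlap <- intersect(genes, query)
    k <- length(overlap)
    # P(X >= k); k = 0 gives 1 by construction
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(term_id = id, gene_count = k, p_value = min(p, 1), genes = overlap)
  })
  nm <- if (!is.null(ont)) {
    vapply(ids, function(i)
      if (i %in% names(ont$terms)) ont$terms[[i]]$name else i, "")
  } else ids
  out <- data.frame(term_id = ids, name = nm,
                    gene_count = vapply(rows, `[[`, 0L, "gene_count"),
                    p_value = vapply(rows, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_value <- bh_adjust(out$p_value)
  out$genes <- lapply(rows, `[[`, "genes")
  out$merged_children <- rep(list(character()), nrow(out))
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Merge enriched direct descendants into their parents
#'
#' Curation rule: a descendant term that stands in a direct `is_a`
#' relationship with an enriched parent term is treated as part of the
#' parent — its overlap genes are pooled into the parent's gene set and
#' counted together, and the child row is removed (recorded in the
#' parent's `merged_children`). Only direct edges are honoured: a
#' grandchild whose intermediate parent is not among the records is left
#' untouched, and a child that is itself absorbed does not pass its own
#' children upward. Each term's statistics (p, q) are unchanged;
#' merging affects gene sets and counts only, so the operation is
#' idempotent.
#'
#' @param records `enrichment_result` (typically pre-filtered or
#'   carrying q-values computed on the full, un-merged term list).
#' @param ont [ontology] providing the direct `is_a` edges.
#' @return curated `enrichment_result`.
#' @export
merge_descendants <- function(records, ont) {
  unknown <- setdiff(records$term_id, names(ont$terms))
  if (length(unknown) > 0)
    ncp_stop(sprintf("record references unknown term(s): %s",
                     paste(unknown, collapse = ", ")), "ncp_validation_error")
  present <- records$term_id
  parent_of <- lapply(stats::setNames(ont$terms[present], present),
                      function(t) intersect(t$parents, present))
  # A term is absorbed iff it has a present parent that survives the
  # merge itself (a child of an absorbed parent keeps its own record, so
  # genes never travel more than one direct edge). Resolve by fixpoint
  # iteration over the DAG.
  absorbed <- stats::setNames(rep(FALSE, length(present)), present)
  repeat {
    new_abs <- vapply(present, function(id) {
      any(!absorbed[parent_of[[id]]])
    }, TRUE)
    if (identical(unname(new_abs), unname(absorbed))) break
    absorbed <- stats::setNames(new_abs, present)
  }
  pre_genes <- stats::setNames(records$genes, present)
  out <- records
  for (i in seq_len(nrow(out))) {
    id <- out$term_id[i]
    if (absorbed[id]) next
    kids <- present[vapply(present, function(ch)
      absorbed[ch] && id %in% parent_of[[ch]], TRUE)]
    if (length(kids) == 0) next
    pooled <- unique(c(pre_genes[[id]], unlist(pre_genes[kids], use.names = FALSE)))
    out$genes[[i]] <- pooled
    out$gene_count[i] <- length(pooled)
    out$merged_children[[i]] <- sort(unique(c(out$merged_children[[i]], kids)))
  }
  out <- out[!absorbed[out$term_id], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter and rank curated terms
#'
#' Keeps terms with BH-adjusted q below `alpha` and orders them by
#' descending pooled gene count; ties broken by ascending q, then by
#' term id.
#'
#' @param records `enrichment_result` (after [merge_descendants()]).
#' @param alpha q-value cutoff (default 0.05).
#' @return ranked `enrichment_result`.
#' @export
rank_terms <- function(records, alpha = 0.05) {
  keep <- records[!is.na(records$q_value) & records$q_value < alpha, , drop = FALSE]
  ord <- order(-keep$gene_count, keep$q_value, keep$term_id)
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment result to TSV
#' @param records `enrichment_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  flat <- data.frame(
    term_id = records$term_id, name = records$name,
    gene_count = records$gene_count,
    p_value = records$p_value, q_value = records$q_value,
    genes = vapply(records$genes, paste, "", collapse = ","),
    merged_children = vapply(records$merged_children, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
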