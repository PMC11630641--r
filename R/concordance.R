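# Cross-method (qFlow vs MS) and cross-species comparison statistics:
# the one-decimal fold-difference convention, log-scale correlation of
# copy-number tables, ortholog overlap counting and inventory overlap.

#' Directionless fold difference, one-decimal convention
#'
#' `ratio = max(a, b) / min(a, b)`, reported truncated (floored) to one
#' decimal place — e.g. a raw ratio of 1.47 is reported as 1.4. The raw
#' ratio is first rounded to 6 decimals so that binary floating-point
#' representation cannot flip the truncation at an exact decimal
#' boundary. Vectorised over `a` and `b`.
#'
#' @param a,b positive copy numbers.
#' @return data.frame `ratio_full` (full precision) and `fold_1dp`
#'   (truncated to one decimal).
#' @export
fold_difference <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    ncp_stop("fold difference needs positive inputs", "ncp_domain_error")
  ratio <- pmax(a, b) / pmin(a, b)
  fold <- floor(round(ratio, 6) * 10) / 10
  data.frame(ratio_full = ratio, fold_1dp = fold)
}

#' Concordance between two copy-number tables
#'
#' Pearson correlation of log10 copies over the entries shared by both
#' tables, with the per-entry fold differences. Accepts
#' `copy_number_table`s or plain data.frames with `protein_id` and
#' `copies`.
#'
#' @param x,y copy tables (e.g. MS-based vs qFlow-based, or two
#'   species over orthologs).
#' @return list with `pairs` (`protein_id`, `copies_x`, `copies_y`,
#'   `ratio_full`, `fold_1dp`), `r` (log10 Pearson), `n`.
#' @export
concordance_stats <- function(x, y) {
  as_tab <- function(t) if (inherits(t, "copy_number_table")) t$table else t
  xt <- as_tab(x); yt <- as_tab(y)
  m <- merge(xt[c("protein_id", "copies")], yt[c("protein_id", "copies")],
             by = "protein_id", suffixes = c("_x", "_y"))
  m <- m[!is.na(m$copies_x) & !is.na(m$copies_y) &
           m$copies_x > 0 & m$copies_y > 0, ]
  if (nrow(m) < 3)
    ncp_stop("fewer than 3 shared positive entries",
             "ncp_insufficient_overlap_error")
  fd <- fold_difference(m$copies_x, m$copies_y)
  pairs <- cbind(m, fd)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       r = stats::cor(log10(m$copies_x), log10(m$copies_y)),
       n = nrow(m))
}

#' Ortholog overlap between two detected proteomes
#'
#' Counts ortholog pairs detected on both sides, plus the A-only and
#' B-only remainders. One-to-many mappings are collapsed to unique gene
#' pairs, keeping the lexicographically first partner; the collapsed
#' pairs are reported.
#'
#' @param set_a detected genes in species A (matching `map`'s first
#'   column).
#' @param set_b detected genes in species B (second column).
#' @param map data.frame of ortholog pairs (two columns, A-symbols then
#'   B-symbols; see [read_ortholog_map()]).
#' @return list with `shared` (data.frame of detected pairs),
#'   `n_shared`, `n_a_only`, `n_b_only`, `collapsed` (pairs dropped in
#'   one-to-many resolution).
#' @export
ortholog_overlap <- function(set_a, set_b, map) {
  set_a <- unique(toupper(set_a)); set_b <- unique(toupper(set_b))
  map <- data.frame(a = toupper(map[[1]]), b = toupper(map[[2]]),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  map <- map[order(map$a, map$b), ]
  dup <- duplicated(map$a) | duplicated(map$b)
  collapsed <- map[dup, , drop = FALSE]
  if (nrow(collapsed) > 0)
    ncp_warn(sprintf("collapsed %d one-to-many ortholog pairs", nrow(collapsed)),
             "ncp_ortholog_duplicate_warning")
  map <- map[!dup, , drop = FALSE]
  in_a <- map$a %in% set_a
  in_b <- map$b %in% set_b
  shared <- map[in_a & in_b, , drop = FALSE]
  rownames(shared) <- NULL
  # detected genes without a detected ortholog partner on the other side
  n_a_only <- length(set_a) - sum(shared$a %in% set_a)
  n_b_only <- length(set_b) - sum(shared$b %in% set_b)
  list(shared = shared, n_shared = nrow(shared),
       n_a_only = n_a_only, n_b_only = n_b_only, collapsed = collapsed)
}

#' Overlap of a detected proteome with a reference inventory
#'
#' E.g. how much of a mitochondrial protein inventory is detected.
#'
#' @param detected character vector of detected identifiers.
#' @param inventory character vector of inventory identifiers
#'   (non-empty).
#' @param case_normalize upper-case both sets before comparing.
#' @return list with `count` (size of the intersection) and `fraction`
#'   (of the inventory that was detected).
#' @export
inventory_overlap <- function(detected, inventory, case_normalize = TRUE) {
  if (length(inventory) == 0)
    ncp_stop("inventory must not be empty", "ncp_argument_error")
  if (case_normalize) {
    detected <- toupper(detected); inventory <- toupper(inventory)
  }
  detected <- unique(detected); inventory <- unique(inventory)
  n <- length(intersect(detected, inventory))
  list(count = n, fraction = n / length(inventory))
}
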