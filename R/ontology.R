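# Minimal ontology support: parse the id/name/is_a subset of OBO (or an
# equivalent child->parent edge TSV) into a flat term table with direct
# parent links. Only is_a edges are represented; that is the relation the
# term-merging step honours.

#' Ontology term set
#'
#' @param ids term identifiers.
#' @param names term names (defaults to the ids).
#' @param parents list of character vectors of direct `is_a` parents,
#'   parallel to `ids`.
#' @return An object of class `ontology`, a list with a named `terms`
#'   element: each term holds `id`, `name`, `parents`.
#' @export
ontology <- function(ids, names = ids, parents = vector("list", length(ids))) {
  if (anyDuplicated(ids))
    ncp_stop("duplicate term ids", "ncp_validation_error")
  known <- as.character(ids)
  parents <- lapply(parents, function(p) {
    p <- as.character(p %||% character())
    drop <- setdiff(p, known)
    if (length(drop) > 0)
      ncp_warn(sprintf("dropping dangling parent id(s): %s",
                       paste(drop, collapse = ", ")),
               "ncp_dangling_parent_warning")
    intersect(p, known)
  })
  terms <- Map(function(i, n, p) list(id = i, name = n, parents = p),
               known, as.character(names), parents)
  names(terms) <- known
  obj <- structure(list(terms = terms), class = "ontology")
  cyc <- find_cycle(obj)
  if (!is.null(cyc))
    ncp_stop(sprintf("ontology contains a cycle: %s",
                     paste(cyc, collapse = " -> ")), "ncp_cycle_error")
  obj
}

# Kahn-style peeling; returns one offending cycle (as an id path) or NULL.
find_cycle <- function(ont) {
  parents <- lapply(ont$terms, `[[`, "parents")
  remaining <- names(parents)
  repeat {
    deg <- vapply(parents[remaining],
                  function(p) length(intersect(p, remaining)), 0L)
    leaves <- remaining[deg == 0L]
    if (length(leaves) == 0L) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining) == 0L) return(NULL)
  # walk parent links inside the residual set until a repeat closes the loop
  path <- remaining[1]
  repeat {
    nxt <- intersect(parents[[path[length(path)]]], remaining)[1]
    if (nxt %in% path)
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    path <- c(path, nxt)
  }
}

#' @export
print.ontology <- function(x, ...) {
  n_edges <- sum(lengths(lapply(x$terms, `[[`, "parents")))
  cat(sprintf("ontology: %d terms, %d is_a edges\n", length(x$terms), n_edges))
  invisible(x)
}

#' Direct children of each term
#' @param ont ontology.
#' @return named list mapping term id to character vector of direct children.
#' @export
ontology_children <- function(ont) {
  out <- stats::setNames(vector("list", length(ont$terms)), names(ont$terms))
  for (tm in ont$terms)
    for (p in tm$parents) out[[p]] <- c(out[[p]], tm$id)
  out
}

#' Read an ontology file
#'
#' Supports two formats: an OBO file restricted to the `id`, `name` and
#' `is_a` tags of `[Term]` stanzas, or a two-column child/parent edge TSV
#' (no header). Cycles are rejected; links to unknown parents are dropped
#' with a warning.
#'
#' @param path file path.
#' @param format `"obo"` or `"edge_tsv"`; the default guesses from the
#'   file extension.
#' @return An [ontology].
#' @export
read_ontology <- function(path, format = c("auto", "obo", "edge_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  if (format == "auto")
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "edge_tsv"
  if (format == "obo") read_obo(path) else read_edge_tsv(path)
}

read_obo <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- character(); nms <- character(); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      ids <<- c(ids, cur$id)
      nms <<- c(nms, cur$name %||% cur$id)
      parents[[length(parents) + 1L]] <<- cur$parents
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- identical(ln, "[Term]")
      cur <- list(parents = character())
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    }
  }
  if (in_term) flush()
  ontology(ids, nms, parents)
}

read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("child", "parent"))
  ids <- unique(c(df$child, df$parent))
  parents <- lapply(ids, function(i) unique(df$parent[df$child == i]))
  ontology(ids, ids, parents)
}
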