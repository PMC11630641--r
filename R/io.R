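# Readers for the flow-cytometry and annotation side files: antibody
# titration exports, bead standards, plain gene lists, ontology graphs
# and ortholog maps.

#' Antibody titration series
#'
#' A set of (antibody amount in ng/test, median fluorescence intensity)
#' points from a serial antibody dilution on a fixed cell number.
#'
#' @param target stained target protein, e.g. "CD11b".
#' @param amount_ng antibody amounts in ng per test.
#' @param mdnfi median fluorescence intensities (arbitrary units).
#' @param stain_context one of `"surface_unfixed"`, `"surface_fixed_perm"`,
#'   `"combined_fixed_perm"`.
#' @return An object of class `titration_series`, points sorted by
#'   descending antibody amount.
#' @export
titration_series <- function(target, amount_ng, mdnfi,
                             stain_context = c("surface_unfixed",
                                               "surface_fixed_perm",
                                               "combined_fixed_perm")) {
  stain_context <- match.arg(stain_context)
  if (length(amount_ng) != length(mdnfi))
    ncp_stop("amount_ng and mdnfi lengths differ", "ncp_validation_error")
  if (length(amount_ng) < 4)
    ncp_stop("a titration series needs at least 4 points",
             "ncp_insufficient_data_error")
  if (any(!is.finite(amount_ng)) || any(amount_ng <= 0))
    ncp_stop("antibody amounts must be positive", "ncp_validation_error")
  if (any(!is.finite(mdnfi)) || any(mdnfi <= 0))
    ncp_stop("MdnFI values must be positive", "ncp_validation_error")
  ord <- order(amount_ng, decreasing = TRUE)
  amount_ng <- amount_ng[ord]
  mdnfi <- mdnfi[ord]
  if (anyDuplicated(amount_ng))
    ncp_stop("antibody amounts must be strictly decreasing", "ncp_validation_error")
  structure(
    list(target = target, stain_context = stain_context,
         amount_ng = amount_ng, mdnfi = mdnfi),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series '%s' (%s): %d points, %.4g-%.4g ng\n",
              x$target, x$stain_context, length(x$amount_ng),
              max(x$amount_ng), min(x$amount_ng)))
  invisible(x)
}

#' Read an antibody titration CSV
#'
#' Expects columns `antibody_ng` and `mdnfi`; optional `target` and
#' `stain_context` columns (constant per file) are picked up as metadata.
#'
#' @param path CSV path.
#' @param target override for the target name.
#' @return A [titration_series].
#' @export
read_titration_csv <- function(path, target = NULL) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("antibody_ng", "mdnfi"), names(df))
  if (length(miss) > 0)
    ncp_stop(sprintf("titration CSV is missing column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  tgt <- target %||% (if ("target" %in% names(df)) df$target[1] else "unknown")
  ctx <- if ("stain_context" %in% names(df)) df$stain_context[1] else "surface_unfixed"
  titration_series(tgt, df$antibody_ng, df$mdnfi, ctx)
}

#' Write an antibody titration CSV
#' @param t titration_series.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(t, path) {
  utils::write.csv(
    data.frame(target = t$target, stain_context = t$stain_context,
               antibody_ng = t$amount_ng, mdnfi = t$mdnfi),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bead-standard CSV
#'
#' Calibration beads carry known numbers of PE molecules per bead; the
#' file has columns `pe_per_bead` and `mdnfi`.
#'
#' @param path CSV path.
#' @return data.frame with columns `pe_per_bead`, `mdnfi`.
#' @export
read_beads_csv <- function(path) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("pe_per_bead", "mdnfi"), names(df))
  if (length(miss) > 0)
    ncp_stop(sprintf("bead CSV is missing column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  if (nrow(df) < 2)
    ncp_stop("bead table needs at least 2 levels", "ncp_insufficient_data_error")
  if (any(df$pe_per_bead <= 0) || any(df$mdnfi <= 0))
    ncp_stop("bead values must be positive", "ncp_validation_error")
  df[c("pe_per_bead", "mdnfi")]
}

#' Read a plain gene list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#' Used for contaminant catalogues, mitochondrial inventories and
#' histone ruler sets.
#'
#' @param path text file path.
#' @param case_normalize upper-case identifiers so that human (upper-case)
#'   and mouse (title-case) symbols match. Default `TRUE`.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path, case_normalize = TRUE) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (case_normalize) lines <- toupper(lines)
  out <- unique(lines)
  if (length(out) == 0)
    ncp_warn(sprintf("gene list '%s' is empty", path), "ncp_empty_list_warning")
  out
}

#' Read a two-column ortholog map
#'
#' TSV with columns `human_symbol` and `mouse_symbol` (header required).
#' Duplicate identical pairs are dropped silently; conflicting duplicate
#' rows for the same symbol are kept but reported via a warning.
#'
#' @param path TSV path.
#' @param case_normalize upper-case both columns. Default `TRUE`.
#' @return data.frame with columns `human_symbol`, `mouse_symbol`.
#' @export
read_ortholog_map <- function(path, case_normalize = TRUE) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("human_symbol", "mouse_symbol"), names(df))
  if (length(miss) > 0)
    ncp_stop(sprintf("ortholog map is missing column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  if (case_normalize) {
    df$human_symbol <- toupper(df$human_symbol)
    df$mouse_symbol <- toupper(df$mouse_symbol)
  }
  df <- unique(df[c("human_symbol", "mouse_symbol")])
  dup <- duplicated(df$human_symbol) | duplicated(df$mouse_symbol)
  if (any(dup))
    ncp_warn(sprintf("%d one-to-many ortholog pairs retained", sum(dup)),
             "ncp_ortholog_duplicate_warning")
  df
}
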