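#' Protein-level quantification table
#'
#' `quant_table` is the package's container for protein-level DIA output:
#' a protein annotation frame (identifier, gene symbol, molecular weight in
#' Da, unique-peptide count), an intensity matrix (one column per sample,
#' `NA` meaning "not detected" as opposed to a low signal), and per-sample
#' metadata (condition, subject, replicate, input-cells setting).
#'
#' @param annotation data.frame with columns `protein_id`, `gene`, `mw_da`,
#'   `unique_peptides`.
#' @param intensities numeric matrix, rows matching `annotation` rows,
#'   columns named by sample id; values non-negative or `NA`.
#' @param sample_meta data.frame with columns `sample`, `condition`,
#'   `subject`, `replicate` and optionally `input_cells`.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(annotation, intensities, sample_meta) {
  req <- c("protein_id", "gene", "mw_da", "unique_peptides")
  miss <- setdiff(req, names(annotation))
  if (length(miss) > 0)
    ncp_stop(sprintf("annotation is missing column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(annotation))
    ncp_stop("intensity rows do not match annotation rows", "ncp_validation_error")
  if (anyDuplicated(annotation$protein_id))
    ncp_stop(sprintf("duplicate protein_id: %s",
                     annotation$protein_id[duplicated(annotation$protein_id)][1]),
             "ncp_validation_error")
  if (any(!is.finite(annotation$mw_da) | annotation$mw_da <= 0))
    ncp_stop("mw_da must be positive for every protein", "ncp_validation_error")
  if (any(annotation$unique_peptides < 0, na.rm = TRUE))
    ncp_stop("unique_peptides must be non-negative", "ncp_validation_error")
  if (any(intensities < 0, na.rm = TRUE))
    ncp_stop("intensities must be >= 0 or missing", "ncp_validation_error")
  smreq <- c("sample", "condition", "subject", "replicate")
  miss <- setdiff(smreq, names(sample_meta))
  if (length(miss) > 0)
    ncp_stop(sprintf("sample_meta is missing column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  if (is.null(sample_meta$input_cells)) sample_meta$input_cells <- NA_integer_
  if (ncol(intensities) != nrow(sample_meta))
    ncp_stop("sample_meta rows do not match intensity columns", "ncp_validation_error")
  if (is.null(colnames(intensities))) colnames(intensities) <- sample_meta$sample
  if (!identical(colnames(intensities), as.character(sample_meta$sample)))
    ncp_stop("intensity column names do not match sample_meta$sample",
             "ncp_validation_error")
  rownames(intensities) <- annotation$protein_id
  structure(
    list(annotation = as.data.frame(annotation, stringsAsFactors = FALSE),
         intensities = intensities,
         sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE)),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d samples\n",
              nrow(x$annotation), ncol(x$intensities)))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$sample_meta$condition), collapse = ", ")))
  cat(sprintf("  missing intensities: %d (%.1f%%)\n",
              sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)

#' Subset a quant table by protein row index
#' @param q quant_table
#' @param i logical or integer row index
#' @return quant_table with the selected proteins.
#' @export
qt_subset <- function(q, i) {
  quant_table(q$annotation[i, , drop = FALSE],
              q$intensities[i, , drop = FALSE],
              q$sample_meta)
}

# Sample ids encode the design as "<condition>:<subject>:<replicate>".
parse_sample_names <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    ncp_stop(sprintf(
      "sample column '%s' does not follow <condition>:<subject>:<replicate>",
      ids[bad][1]), "ncp_format_error")
  data.frame(sample = ids,
             condition = vapply(parts, `[[`, "", 1L),
             subject = vapply(parts, `[[`, "", 2L),
             replicate = vapply(parts, `[[`, "", 3L),
             input_cells = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Read a protein quantification table
#'
#' Reads the package's wide TSV dialect: reserved columns `protein_id`,
#' `gene`, `mw_da`, `unique_peptides` followed by one column per sample.
#' Sample columns are named `<condition>:<subject>:<replicate>` so the
#' paired design travels with the matrix; alternatively a separate
#' metadata TSV (columns `sample`, `condition`, `subject`, `replicate`,
#' optional `input_cells`) may be supplied. Empty cells are missing
#' values (protein not detected), distinct from 0.
#'
#' @param path path to the TSV file.
#' @param meta optional path to a sample-metadata TSV.
#' @return A [quant_table].
#' @export
read_quant_table <- function(path, meta = NULL) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  req <- c("protein_id", "gene", "mw_da", "unique_peptides")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    ncp_stop(sprintf("quant table is missing mandatory column(s): %s",
                     paste(miss, collapse = ", ")), "ncp_format_error")
  sample_cols <- setdiff(names(df), req)
  if (length(sample_cols) == 0)
    ncp_stop("quant table has no sample columns", "ncp_format_error")
  ann <- data.frame(protein_id = df$protein_id,
                    gene = df$gene,
                    mw_da = as.numeric(df$mw_da),
                    unique_peptides = as.integer(df$unique_peptides),
                    stringsAsFactors = FALSE)
  num <- function(col) {
    x <- df[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0)
      ncp_stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                       x[bad[1]], bad[1], col), "ncp_parse_error")
    v
  }
  mat <- vapply(sample_cols, num, numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, sample_cols))
  sm <- if (is.null(meta)) {
    parse_sample_names(sample_cols)
  } else {
    m <- utils::read.delim(meta, stringsAsFactors = FALSE)
    m <- m[match(sample_cols, m$sample), , drop = FALSE]
    if (anyNA(m$sample))
      ncp_stop("metadata file does not cover every sample column", "ncp_format_error")
    m
  }
  quant_table(ann, mat, sm)
}

#' Write a protein quantification table
#'
#' Inverse of [read_quant_table()]: missing intensities become empty
#' cells so that a read/write cycle is lossless.
#'
#' @param q quant_table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(q, path) {
  out <- cbind(q$annotation, as.data.frame(q$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
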