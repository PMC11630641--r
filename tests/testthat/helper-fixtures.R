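# Fixture builders shared by the test files. Everything is constructed
# in code; no binary data.

# A tiny quant table with an explicit intensity matrix.
tiny_quant <- function(intensities = NULL, conditions = c("A", "B"),
                       n_subjects = 2, mw = NULL, upep = NULL) {
  if (is.null(intensities)) {
    intensities <- matrix(c(100, 200, 300, 110, 210, 310,
                            120, 220, 320, 130, 230, 330),
                          nrow = 3)
  }
  n <- nrow(intensities)
  ids <- as.vector(outer(sprintf("S%02d", seq_len(n_subjects)), conditions,
                         function(s, cn) sprintf("%s:%s:R1", cn, s)))
  ids <- ids[seq_len(ncol(intensities))]
  colnames(intensities) <- ids
  ann <- data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                    gene = sprintf("G%03d", seq_len(n)),
                    mw_da = mw %||% rep(5e4, n),
                    unique_peptides = upep %||% rep(3L, n),
                    stringsAsFactors = FALSE)
  sm <- neutrocopy:::parse_sample_names(ids)
  quant_table(ann, intensities, sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a quant-table TSV by hand (independent of write_quant_table).
write_fixture_tsv <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
}

# A small ontology: root R <- P <- C <- G, plus sibling Q under R.
fixture_ontology <- function() {
  ontology(ids = c("R", "P", "C", "G", "Q"),
           names = c("root", "parent", "child", "grandchild", "other"),
           parents = list(character(), "R", "P", "C", "R"))
}
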