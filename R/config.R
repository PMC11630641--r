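# Flat key-value configuration carrying every analysis threshold, plus
# the JSON run manifest written next to pipeline outputs.

#' Default analysis configuration
#'
#' All tunable thresholds in one flat list: significance level and
#' log2 fold-change cutoff for the paired test, the abundance-class
#' boundaries, the saturation target fraction, the unique-peptide
#' filter, and the F:P coupling default.
#'
#' @return named list of class `ncp_config`.
#' @export
default_config <- function() {
  structure(list(
    alpha = 0.05,               # raw-p significance level, paired test
    lfc_threshold = 1,          # |log2 fold change| cutoff
    go_alpha = 0.05,            # BH q cutoff for term curation
    min_unique_peptides = 2,    # quantification-confidence filter
    abundance_high_min = 5e5,   # copies/cell, exclusive lower bound of "high"
    abundance_low_max = 1e4,    # copies/cell, exclusive upper bound of "low"
    saturation_target = 0.9995, # fraction of plateau for antibody amount
    fp_ratio = 1                # PE molecules per antibody, lot-specific
  ), class = "ncp_config")
}

#' Read a configuration file
#'
#' YAML with flat scalar keys; unknown keys are rejected so typos fail
#' loudly. Missing keys fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return `ncp_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    ncp_stop(sprintf("file not found: %s", path), "ncp_io_error")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0)
    ncp_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
             "ncp_config_error")
  for (k in names(user)) {
    if (!is.numeric(user[[k]]) || length(user[[k]]) != 1)
      ncp_stop(sprintf("config key '%s' must be a single number", k),
               "ncp_config_error")
    cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and package version next to a
#' pipeline output so any table can be traced back to the run that made
#' it.
#'
#' @param path output JSON path.
#' @param inputs named list/vector of input descriptions.
#' @param params named list of parameters (e.g. the config).
#' @param seed RNG seed used, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), params = list(), seed = NULL) {
  manifest <- list(
    package = "neutrocopy",
    version = as.character(utils::packageVersion("neutrocopy")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
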