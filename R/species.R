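#' Species profile for absolute quantification
#'
#' Bundles the per-cell constants that turn relative MS signal into
#' absolute copies: the total cellular protein mass (total protein
#' approach) and the DNA mass per diploid cell together with the histone
#' identifier set (proteomic ruler). The built-in values are working
#' assumptions of this package, not measured constants: the human total
#' protein mass is anchored to a ~300 um^3 neutrophil volume, and the
#' mouse value to human cells carrying ~1.8-fold more protein per cell
#' than mouse cells.
#'
#' @param name species label, e.g. "human" or "mouse".
#' @param total_protein_mass_pg total protein mass per cell in picograms.
#' @param dna_mass_pg DNA mass per diploid cell in picograms.
#' @param histone_ids character vector of gene symbols making up the
#'   ruler set (matched case-insensitively).
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name,
                            total_protein_mass_pg,
                            dna_mass_pg,
                            histone_ids = character()) {
  if (!is.numeric(total_protein_mass_pg) || total_protein_mass_pg <= 0)
    ncp_stop("total_protein_mass_pg must be > 0", "ncp_validation_error")
  if (!is.numeric(dna_mass_pg) || dna_mass_pg <= 0)
    ncp_stop("dna_mass_pg must be > 0", "ncp_validation_error")
  structure(
    list(name = name,
         total_protein_mass_pg = total_protein_mass_pg,
         dna_mass_pg = dna_mass_pg,
         histone_ids = toupper(histone_ids)),
    class = "species_profile"
  )
}

DEFAULT_HISTONES <- c(
  "H1-2", "H1-3", "H1-4", "H2AC4", "H2AC11", "H2AZ1",
  "H2BC11", "H2BC12", "H3C1", "H3-3A", "H4C1"
)

#' Built-in species profiles
#'
#' @param name "human" or "mouse".
#' @return A [species_profile] with the package's default per-cell masses
#'   (human 20 pg protein / 6.5 pg DNA; mouse 11.1 pg protein / 6.0 pg
#'   DNA, preserving the 1.8-fold human:mouse protein ratio).
#' @export
default_species <- function(name = c("human", "mouse")) {
  name <- match.arg(name)
  switch(name,
    human = species_profile("human", 20,   6.5, DEFAULT_HISTONES),
    mouse = species_profile("mouse", 20 / 1.8, 6.0, DEFAULT_HISTONES)
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("species_profile '%s': %.3g pg protein, %.3g pg DNA, %d histone ids\n",
              x$name, x$total_protein_mass_pg, x$dna_mass_pg,
              length(x$histone_ids)))
  invisible(x)
}
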