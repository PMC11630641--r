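# Synthetic-data generators. These produce every input the pipeline
# consumes, with the statistical structure the analysis assumes:
# log-normal copy numbers over ~10^2-10^8 copies/cell with a heavy top
# tail, intensities proportional to copies x molecular weight with
# multiplicative log-normal noise, logistic abundance-dependent dropout
# whose midpoint shifts with the cell-input setting, paired designs with
# planted log2 effects, exponential-saturation antibody titrations and
# exactly log-linear bead standards. All generators are pure functions
# of (configuration, seed).

#' Simulation configuration
#'
#' @param n_proteins number of proteins to simulate.
#' @param copy_lognormal_mu,copy_lognormal_sigma natural-log location and
#'   scale of the copy-number distribution before mass rescaling. The
#'   default sigma 2.5 gives the heavy-tailed abundance profile in which
#'   the ~150 most abundant of 5000 proteins carry the majority of all
#'   copies.
#' @param mw_range_da molecular-weight range in Da; weights are drawn
#'   log-uniformly within it.
#' @param n_subjects subjects per condition (paired designs reuse them).
#' @param conditions condition labels, first is the reference.
#' @param planted_effects data.frame with columns `protein` (index) and
#'   `log2fc` giving planted condition-B effects; `NULL` for none.
#' @param dropout_midpoint_log10copies named numeric vector mapping an
#'   input-cells setting (as character) to the log10 copy number at which
#'   detection probability is 50%. Defaults: 3.7 at 1000 cells, 3.4 at
#'   4000, 2.8 at 100000 — low-input runs lose low-abundance proteins
#'   first.
#' @param dropout_steepness logistic slope per log10 copies decade.
#' @param intensity_cv multiplicative coefficient of variation of protein
#'   intensities.
#' @param sample_scale_cv coefficient of variation of the per-sample
#'   global scale factor (0 emulates perfectly normalised runs).
#' @param n_histones how many simulated proteins form the histone ruler
#'   set; their summed mass is pinned to the species DNA mass (the
#'   nucleosome assumption underlying the proteomic ruler).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 5000,
                       copy_lognormal_mu = log(1e4),
                       copy_lognormal_sigma = 2.5,
                       mw_range_da = c(1e4, 3e5),
                       n_subjects = 5,
                       conditions = c("A", "B"),
                       planted_effects = NULL,
                       dropout_midpoint_log10copies = c(
                         "1000" = 3.7, "4000" = 3.4, "100000" = 2.8),
                       dropout_steepness = 2,
                       intensity_cv = 0.1,
                       sample_scale_cv = 0,
                       n_histones = 6) {
  if (n_proteins < 1) ncp_stop("n_proteins must be >= 1", "ncp_config_error")
  if (dropout_steepness <= 0)
    ncp_stop("dropout_steepness must be > 0", "ncp_config_error")
  if (intensity_cv < 0) ncp_stop("intensity_cv must be >= 0", "ncp_config_error")
  if (!is.null(planted_effects)) {
    if (!all(c("protein", "log2fc") %in% names(planted_effects)))
      ncp_stop("planted_effects needs columns protein, log2fc", "ncp_config_error")
    if (any(planted_effects$protein < 1 | planted_effects$protein > n_proteins))
      ncp_stop("planted effect on nonexistent protein index", "ncp_config_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth proteome
#'
#' Draws per-protein copy numbers log-normally, then rescales so the
#' total protein mass per cell exactly matches the species profile:
#' `sum(copies * mw) / N_A == total_protein_mass`. The first
#' `cfg$n_histones` proteins are labelled with the species histone
#' symbols and their summed mass is pinned to the DNA mass per cell, so
#' the proteomic ruler and the total protein approach are mutually
#' consistent on simulated data.
#'
#' @param cfg [sim_config].
#' @param species [species_profile].
#' @param seed integer seed.
#' @return data.frame `protein_id`, `gene`, `mw_da`, `is_histone`,
#'   `copies` (true copies per cell).
#' @export
gen_proteome <- function(cfg, species = default_species("human"), seed = 1) {
  with_seed(seed, {
    n <- cfg$n_proteins
    mw <- exp(stats::runif(n, log(cfg$mw_range_da[1]), log(cfg$mw_range_da[2])))
    copies <- stats::rlnorm(n, cfg$copy_lognormal_mu, cfg$copy_lognormal_sigma)
    if (all(copies == 0))
      ncp_stop("all simulated copies are zero; cannot rescale",
               "ncp_generation_error")
    nh <- min(cfg$n_histones, n)
    is_histone <- c(rep(TRUE, nh), rep(FALSE, n - nh))
    mass_pg <- function(idx) sum(copies[idx] * mw[idx]) / AVOGADRO * 1e12
    if (nh > 0 && species$dna_mass_pg < species$total_protein_mass_pg) {
      copies[is_histone] <- copies[is_histone] *
        species$dna_mass_pg / mass_pg(is_histone)
      copies[!is_histone] <- copies[!is_histone] *
        (species$total_protein_mass_pg - species$dna_mass_pg) / mass_pg(!is_histone)
    } else {
      copies <- copies * species$total_protein_mass_pg / mass_pg(TRUE)
    }
    gene <- sprintf("GENE%04d", seq_len(n))
    if (nh > 0)
      gene[seq_len(nh)] <- rep_len(species$histone_ids %||% DEFAULT_HISTONES, nh)
    data.frame(protein_id = sprintf("P%05d", seq_len(n)),
               gene = gene, mw_da = mw, is_histone = is_histone,
               copies = copies, stringsAsFactors = FALSE)
  })
}

# Logistic detection probability in log10 copies.
detection_prob <- function(copies, midpoint, steepness) {
  stats::plogis(steepness * (log10(pmax(copies, .Machine$double.xmin)) - midpoint))
}

dropout_midpoint <- function(cfg, input_cells) {
  key <- formatC(input_cells, format = "d")
  mids <- cfg$dropout_midpoint_log10copies
  if (!key %in% names(mids))
    ncp_stop(sprintf("no dropout midpoint configured for input_cells=%s", key),
             "ncp_config_error")
  mids[[key]]
}

#' Simulate an intensity matrix from a ground-truth proteome
#'
#' Per sample: intensity = copies x mw x sample scale x log-normal
#' noise; each protein is detected with a logistic probability in log10
#' copies whose midpoint depends on the cell-input setting; undetected
#' proteins get `NA`.
#'
#' @param truth output of [gen_proteome()].
#' @param cfg [sim_config].
#' @param input_cells cell-input setting; must be a name of
#'   `cfg$dropout_midpoint_log10copies`.
#' @param n_samples number of replicate samples (default
#'   `cfg$n_subjects`), one subject each, condition = first of
#'   `cfg$conditions`.
#' @param dropout set `FALSE` to disable dropout entirely.
#' @param seed integer seed.
#' @return A [quant_table]; `unique_peptides` is simulated as 1 + a
#'   Poisson draw increasing with log10 copies.
#' @export
gen_quant_matrix <- function(truth, cfg, input_cells = 1000,
                             n_samples = cfg$n_subjects,
                             dropout = TRUE, seed = 1) {
  mid <- if (dropout) dropout_midpoint(cfg, input_cells) else -Inf
  with_seed(seed, {
    n <- nrow(truth)
    cond <- cfg$conditions[1]
    ids <- sprintf("%s:S%02d:R1", cond, seq_len(n_samples))
    scales <- lognorm_noise(n_samples, cfg$sample_scale_cv)
    mat <- matrix(NA_real_, n, n_samples, dimnames = list(truth$protein_id, ids))
    for (s in seq_len(n_samples)) {
      noise <- lognorm_noise(n, cfg$intensity_cv)
      intensity <- truth$copies * truth$mw_da * scales[s] * noise
      p_det <- if (dropout) detection_prob(truth$copies, mid, cfg$dropout_steepness)
               else rep(1, n)
      detected <- stats::runif(n) < p_det
      mat[detected, s] <- intensity[detected]
    }
    upep <- 1L + stats::rpois(n, pmax(log10(pmax(truth$copies, 1)), 0))
    ann <- data.frame(protein_id = truth$protein_id, gene = truth$gene,
                      mw_da = truth$mw_da, unique_peptides = upep,
                      stringsAsFactors = FALSE)
    sm <- data.frame(sample = ids, condition = cond,
                     subject = sprintf("S%02d", seq_len(n_samples)),
                     replicate = "R1", input_cells = input_cells,
                     stringsAsFactors = FALSE)
    quant_table(ann, mat, sm)
  })
}

#' Simulate a paired two-condition study
#'
#' Each subject contributes one sample per condition. Subject-level
#' biology is shared across the pair: a per-subject random scale offset
#' multiplies both of the subject's samples, which is what gives the
#' paired test its power advantage over an unpaired analysis. Planted
#' effects multiply condition-B copies by `2^log2fc`.
#'
#' @param truth output of [gen_proteome()].
#' @param cfg [sim_config]; uses the first two `conditions`.
#' @param input_cells cell-input setting for the dropout midpoint.
#' @param subject_cv coefficient of variation of the shared per-subject
#'   offset.
#' @param dropout set `FALSE` to disable dropout.
#' @param seed integer seed.
#' @return A [quant_table] with `2 * cfg$n_subjects` samples.
#' @export
gen_paired_study <- function(truth, cfg, input_cells = 1000,
                             subject_cv = 0.1, dropout = TRUE, seed = 1) {
  if (length(cfg$conditions) < 2)
    ncp_stop("paired study needs two conditions", "ncp_config_error")
  mid <- if (dropout) dropout_midpoint(cfg, input_cells) else -Inf
  with_seed(seed, {
    n <- nrow(truth)
    condA <- cfg$conditions[1]; condB <- cfg$conditions[2]
    effect <- rep(0, n)
    if (!is.null(cfg$planted_effects))
      effect[cfg$planted_effects$protein] <- cfg$planted_effects$log2fc
    copiesB <- truth$copies * 2^effect
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
    subj_offset <- lognorm_noise(cfg$n_subjects, subject_cv)
    ids <- c(sprintf("%s:%s:R1", condA, subjects),
             sprintf("%s:%s:R1", condB, subjects))
    mat <- matrix(NA_real_, n, length(ids),
                  dimnames = list(truth$protein_id, ids))
    scales <- lognorm_noise(length(ids), cfg$sample_scale_cv)
    for (k in seq_along(ids)) {
      s <- ((k - 1L) %% cfg$n_subjects) + 1L
      cp <- if (k <= cfg$n_subjects) truth$copies else copiesB
      noise <- lognorm_noise(n, cfg$intensity_cv)
      intensity <- cp * truth$mw_da * subj_offset[s] * scales[k] * noise
      p_det <- if (dropout) detection_prob(cp, mid, cfg$dropout_steepness)
               else rep(1, n)
      detected <- stats::runif(n) < p_det
      mat[detected, k] <- intensity[detected]
    }
    upep <- 1L + stats::rpois(n, pmax(log10(pmax(truth$copies, 1)), 0))
    ann <- data.frame(protein_id = truth$protein_id, gene = truth$gene,
                      mw_da = truth$mw_da, unique_peptides = upep,
                      stringsAsFactors = FALSE)
    sm <- data.frame(sample = ids,
                     condition = rep(c(condA, condB), each = cfg$n_subjects),
                     subject = rep(subjects, 2L),
                     replicate = "R1", input_cells = input_cells,
                     stringsAsFactors = FALSE)
    quant_table(ann, mat, sm)
  })
}

#' Simulate an antibody titration series
#'
#' Evaluates the exponential saturation model `y0 + A * exp(R0 * x)` on
#' the given antibody amounts and applies multiplicative log-normal
#' noise. The default dilution ladder is a 7-point two-fold series from
#' 1000 ng down to 15.63 ng per test.
#'
#' @param true_fit a [saturation_fit] (or list with `y0`, `A`, `R0`).
#' @param amounts_ng antibody amounts; the default is the conventional
#'   7-point two-fold ladder 1000, 500, 250, 125, 62.5, 31.25, 15.63 ng.
#' @param cv multiplicative noise CV.
#' @param target,stain_context metadata for the series.
#' @param seed integer seed.
#' @return A [titration_series].
#' @export
gen_titration <- function(true_fit,
                          amounts_ng = c(1000, 500, 250, 125, 62.5,
                                         31.25, 15.63),
                          cv = 0, target = "SIM",
                          stain_context = "surface_unfixed", seed = 1) {
  check_saturation_params(true_fit$y0, true_fit$A, true_fit$R0)
  mu <- saturation_value(amounts_ng, true_fit$y0, true_fit$A, true_fit$R0)
  if (any(mu <= 0))
    ncp_stop("saturation model is non-positive at a titration point",
             "ncp_generation_error")
  with_seed(seed, {
    mdnfi <- mu * lognorm_noise(length(mu), cv)
    titration_series(target, amounts_ng, mdnfi, stain_context)
  })
}

#' Simulate a bead-standard table
#'
#' Generates MdnFI values such that `log10(pe) = slope * log10(mdnfi) +
#' intercept` holds exactly at `cv = 0`.
#'
#' @param levels_pe PE molecules per bead for each bead population.
#' @param slope,intercept calibration line on the log10-log10 scale.
#' @param cv multiplicative noise CV on MdnFI.
#' @param seed integer seed.
#' @return data.frame `pe_per_bead`, `mdnfi`.
#' @export
gen_beads <- function(levels_pe, slope = 1, intercept = 1, cv = 0, seed = 1) {
  if (length(levels_pe) < 2)
    ncp_stop("need at least 2 bead levels", "ncp_generation_error")
  if (any(levels_pe <= 0))
    ncp_stop("bead PE levels must be positive", "ncp_generation_error")
  mdnfi <- 10^((log10(levels_pe) - intercept) / slope)
  with_seed(seed, {
    data.frame(pe_per_bead = levels_pe,
               mdnfi = mdnfi * lognorm_noise(length(mdnfi), cv))
  })
}
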