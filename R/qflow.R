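# Quantitative flow cytometry (qFlow): fit exponential saturation
# curves to antibody titrations, solve for the saturating antibody
# amount, correct for permeabilization loss, calibrate MdnFI against
# PE-bead standards and convert plateau fluorescence to absolute
# molecules per cell.

saturation_value <- function(x, y0, A, R0) y0 + A * exp(R0 * x)

check_saturation_params <- function(y0, A, R0) {
  if (!is.finite(y0) || y0 <= 0) ncp_stop("y0 must be > 0", "ncp_validation_error")
  if (!is.finite(A) || A >= 0) ncp_stop("A must be < 0", "ncp_validation_error")
  if (!is.finite(R0) || R0 >= 0) ncp_stop("R0 must be < 0", "ncp_validation_error")
  invisible(TRUE)
}

new_saturation_fit <- function(y0, A, R0, rss, n_points) {
  check_saturation_params(y0, A, R0)
  structure(list(y0 = y0, A = A, R0 = R0, rss = rss, n_points = n_points),
            class = "saturation_fit")
}

#' Saturation-curve fit object
#'
#' Constructor for a fitted `y = y0 + A * exp(R0 * x)` antibody
#' saturation model with plateau `y0 > 0`, amplitude `A < 0` and rate
#' constant `R0 < 0` (the curve rises monotonically towards `y0`).
#'
#' @param y0 plateau MdnFI.
#' @param A amplitude (negative).
#' @param R0 rate constant per ng (negative).
#' @param rss residual sum of squares of the fit.
#' @param n_points number of titration points used.
#' @return object of class `saturation_fit`.
#' @export
saturation_fit <- function(y0, A, R0, rss = NA_real_, n_points = NA_integer_) {
  new_saturation_fit(y0, A, R0, rss, n_points)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation_fit: y0=%.6g, A=%.6g, R0=%.6g (rss=%.3g, n=%d)\n",
              x$y0, x$A, x$R0, x$rss, x$n_points))
  invisible(x)
}

#' Predict MdnFI from a saturation fit
#' @param object saturation_fit.
#' @param x antibody amounts (ng).
#' @param ... unused.
#' @return predicted MdnFI values.
#' @export
predict.saturation_fit <- function(object, x, ...) {
  saturation_value(x, object$y0, object$A, object$R0)
}

#' Fit the antibody saturation model
#'
#' Bounded nonlinear least squares of `y = y0 + A * exp(R0 * x)` to a
#' titration series, constraining `A` and `R0` to be negative.
#' Two starting points are tried — the conventional initialisation
#' (`y0 = max(y)`, `A = -1`, `R0 = -1`), which is poorly scaled for
#' ng-range amounts, and a data-scaled start (`A = -(max(y) - min(y))`,
#' `R0 = -3 / max(x)`) — and the lowest-RSS converged fit is returned.
#'
#' @param t [titration_series].
#' @param init optional list with `y0`, `A`, `R0` used as an additional
#'   starting point.
#' @return A `saturation_fit`.
#' @export
fit_saturation <- function(t, init = NULL) {
  x <- t$amount_ng; y <- t$mdnfi
  if (length(x) < 4)
    ncp_stop("need at least 4 titration points", "ncp_insufficient_data_error")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho) || rho <= 0)
    ncp_stop("MdnFI does not increase with antibody amount; no saturation signal",
             "ncp_no_signal_error")
  eps <- 1e-12
  starts <- list(
    list(y0 = max(y), A = -1, R0 = -1),
    list(y0 = max(y), A = -(max(y) - min(y)), R0 = -3 / max(x))
  )
  if (!is.null(init)) starts <- c(list(init), starts)
  fits <- list()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(R0 * x),
        start = list(y0 = st$y0, A = st$A, R0 = st$R0),
        lower = c(y0 = eps, A = -Inf, R0 = -Inf),
        upper = c(y0 = Inf, A = -eps, R0 = -eps),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0)
    ncp_stop("saturation fit failed to converge from every start", "ncp_fit_error")
  rss <- vapply(fits, stats::deviance, 0)
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  new_saturation_fit(cf[["y0"]], cf[["A"]], cf[["R0"]], min(rss), length(x))
}

#' Antibody amount that saturates the target
#'
#' Solves `target_fraction * y0 = y0 + A * exp(R0 * x)` for `x` in
#' closed form: `x* = log((1 - target_fraction) * y0 / (-A)) / R0`.
#' The default target fraction 0.9995 asks for the amount at which the
#' signal reaches 99.95% of the plateau. If the curve already starts at
#' or above the target (`(1 - f) * y0 >= -A`), 0 is returned with a
#' warning; if `x*` exceeds `max_titrated_ng`, an extrapolation warning
#' is attached.
#'
#' @param f `saturation_fit`.
#' @param target_fraction fraction of the plateau to reach.
#' @param max_titrated_ng largest titrated amount (for the extrapolation
#'   warning); `NULL` to skip the check.
#' @return amount in ng, with attribute `warnings` (character vector).
#' @export
optimal_antibody_amount <- function(f, target_fraction = 0.9995,
                                    max_titrated_ng = NULL) {
  check_saturation_params(f$y0, f$A, f$R0)
  if (target_fraction <= 0 || target_fraction >= 1)
    ncp_stop("target_fraction must be in (0, 1)", "ncp_argument_error")
  warnings <- character()
  gap <- (1 - target_fraction) * f$y0
  if (gap >= -f$A) {
    ncp_warn("curve already meets the target at x = 0; no titration needed",
             "ncp_already_saturated_warning")
    x <- 0
  } else {
    x <- log(gap / (-f$A)) / f$R0
    if (!is.null(max_titrated_ng) && x > max_titrated_ng) {
      warnings <- c(warnings, sprintf(
        "optimal amount %.4g ng extrapolates beyond the titrated maximum %.4g ng",
        x, max_titrated_ng))
    }
  }
  structure(x, warnings = warnings)
}

#' Permeabilization loss factor
#'
#' Ratio of the surface-stain MdnFI on unfixed cells to the surface
#' MdnFI after fixation/permeabilization; multiplying the combined-stain
#' plateau by this factor compensates for antigen lost to the
#' permeabilization procedure. Either argument may be a
#' `saturation_fit` (its plateau `y0` is used) or a single MdnFI value.
#'
#' @param surface_unfixed fit or MdnFI of the unfixed surface stain.
#' @param surface_fixed_perm fit or MdnFI of the fixed/permeabilized
#'   surface stain.
#' @param target optional target labels; if both are given they must
#'   match.
#' @return loss factor L (> 0).
#' @export
loss_factor <- function(surface_unfixed, surface_fixed_perm, target = NULL) {
  val <- function(x) if (inherits(x, "saturation_fit")) x$y0 else as.numeric(x)
  if (!is.null(target) && length(target) == 2 && target[1] != target[2])
    ncp_stop(sprintf("loss factor across different targets: %s vs %s",
                     target[1], target[2]), "ncp_argument_error")
  a <- val(surface_unfixed); b <- val(surface_fixed_perm)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    ncp_stop("both MdnFI signals must be positive", "ncp_validation_error")
  a / b
}

#' Fit the PE-bead calibration line
#'
#' Ordinary least squares of `log10(PE molecules per bead)` on
#' `log10(MdnFI)` over the bead populations, stored together with the
#' antibody lot's F:P coupling ratio (PE molecules per antibody).
#'
#' @param beads data.frame with columns `pe_per_bead`, `mdnfi`
#'   (see [read_beads_csv()] / [gen_beads()]).
#' @param fp_ratio F:P coupling ratio of the antibody lot; default 1.
#' @return object of class `bead_calibration` with `slope`, `intercept`,
#'   `fp_ratio`, `n_levels`, `r_squared`.
#' @export
fit_bead_calibration <- function(beads, fp_ratio = 1) {
  if (nrow(beads) < 2)
    ncp_stop("need at least 2 bead levels", "ncp_insufficient_data_error")
  if (any(beads$pe_per_bead <= 0) || any(beads$mdnfi <= 0))
    ncp_stop("bead values must be positive", "ncp_validation_error")
  if (length(unique(beads$mdnfi)) < 2)
    ncp_stop("identical MdnFI across bead levels; calibration is singular",
             "ncp_singular_fit_error")
  lx <- log10(beads$mdnfi); ly <- log10(beads$pe_per_bead)
  fit <- stats::lm(ly ~ lx)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fp_ratio = fp_ratio,
                 n_levels = nrow(beads),
                 r_squared = r2),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat(sprintf(
    "bead_calibration: log10(PE) = %.6g * log10(MdnFI) + %.6g (n=%d, R2=%.4f), F:P=%.3g\n",
    x$slope, x$intercept, x$n_levels, x$r_squared, x$fp_ratio))
  invisible(x)
}

#' Convert MdnFI to molecules per cell
#'
#' `copies = 10^(slope * log10(mdnfi) + intercept) * fp_ratio`: the
#' calibration line maps log10 fluorescence to log10 PE molecules, the
#' log is reversed, and the antibody lot's F:P coupling ratio is applied
#' multiplicatively.
#'
#' @param mdnfi MdnFI value(s), positive.
#' @param cal `bead_calibration`.
#' @return molecules per cell.
#' @export
mdnfi_to_copies <- function(mdnfi, cal) {
  if (any(!is.finite(mdnfi)) || any(mdnfi <= 0))
    ncp_stop("MdnFI must be positive", "ncp_domain_error")
  10^(cal$slope * log10(mdnfi) + cal$intercept) * cal$fp_ratio
}

#' End-to-end qFlow quantification of one target
#'
#' Runs the full pipeline: fit the combined surface+intracellular
#' titration and take its plateau `y0`; compute the permeabilization
#' loss factor from the unfixed vs fixed/permeabilized surface signals;
#' upscale the combined plateau by the loss factor; convert the
#' corrected MdnFI to absolute molecules per cell through the bead
#' calibration and F:P ratio. Every intermediate is returned in the
#' report.
#'
#' @param surface_unfixed [titration_series] (or single MdnFI) of the
#'   surface stain on unfixed cells.
#' @param surface_fixed_perm single MdnFI (or [titration_series]) of the
#'   surface stain after fixation/permeabilization.
#' @param combined [titration_series] of the combined
#'   surface+intracellular stain on fixed/permeabilized cells.
#' @param beads bead-standard data.frame.
#' @param fp_ratio antibody lot F:P coupling ratio.
#' @param target_fraction saturation target for the reported optimal
#'   amounts.
#' @return list of class `qflow_report`: `target`, `copies`,
#'   `y0_surface`, `y0_combined`, `loss_factor`, `corrected_mdnfi`,
#'   `x_optimal_ng`, `calibration`, `fits`, `warnings`.
#' @export
quantify_target <- function(surface_unfixed, surface_fixed_perm, combined,
                            beads, fp_ratio = 1, target_fraction = 0.9995) {
  stage <- function(label, expr) {
    tryCatch(expr, ncp_error = function(e) {
      ncp_stop(sprintf("[%s] %s", label, conditionMessage(e)), class(e)[1])
    })
  }
  warnings <- character()
  fit_or_value <- function(x, label) {
    if (inherits(x, "titration_series")) stage(label, fit_saturation(x)) else x
  }
  surf <- fit_or_value(surface_unfixed, "surface stain")
  comb <- stage("combined stain",
                if (inherits(combined, "titration_series")) fit_saturation(combined)
                else ncp_stop("combined stain must be a titration series",
                              "ncp_argument_error"))
  y0_surface <- if (inherits(surf, "saturation_fit")) surf$y0 else as.numeric(surf)
  L <- stage("loss factor", loss_factor(surf, surface_fixed_perm))
  corrected <- comb$y0 * L
  cal <- stage("bead calibration", fit_bead_calibration(beads, fp_ratio))
  copies <- stage("bead conversion", mdnfi_to_copies(corrected, cal))
  x_opt <- if (inherits(combined, "titration_series")) {
    xo <- stage("optimal amount",
                optimal_antibody_amount(comb, target_fraction,
                                        max_titrated_ng = max(combined$amount_ng)))
    warnings <- c(warnings, attr(xo, "warnings"))
    as.numeric(xo)
  } else NA_real_
  structure(
    list(target = if (inherits(combined, "titration_series")) combined$target else NA,
         copies = copies,
         y0_surface = y0_surface,
         y0_combined = comb$y0,
         loss_factor = L,
         corrected_mdnfi = corrected,
         x_optimal_ng = x_opt,
         target_fraction = target_fraction,
         calibration = cal,
         fits = list(surface = if (inherits(surf, "saturation_fit")) surf else NULL,
                     combined = comb),
         warnings = warnings),
    class = "qflow_report"
  )
}

#' @export
print.qflow_report <- function(x, ...) {
  cat(sprintf("qflow_report '%s': %.6g molecules/cell\n", x$target, x$copies))
  cat(sprintf("  y0 combined = %.6g, loss factor = %.4g, corrected MdnFI = %.6g\n",
              x$y0_combined, x$loss_factor, x$corrected_mdnfi))
  cat(sprintf("  saturating amount = %.4g ng (%.2f%% of plateau)\n",
              x$x_optimal_ng, 100 * x$target_fraction))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
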