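# qFlow pipeline: saturation fitting, saturating-amount solution, loss
# factor, bead calibration and end-to-end molecules-per-cell.

test_that("noise-free titrations recover the generating parameters", {
  true <- saturation_fit(10000, -9500, -0.01)
  t <- gen_titration(true, cv = 0)
  fit <- fit_saturation(t)
  expect_equal(fit$y0, true$y0, tolerance = 1e-6)
  expect_equal(fit$A, true$A, tolerance = 1e-6)
  expect_equal(fit$R0, true$R0, tolerance = 1e-6)
  # fitted curve is increasing in the antibody amount
  xs <- seq(1, 1000, length.out = 50)
  expect_true(all(diff(predict(fit, xs)) > 0))
})

test_that("degenerate or trendless series raise a no-signal error", {
  flat <- titration_series("X", c(1000, 500, 250, 125), rep(500, 4))
  expect_error(fit_saturation(flat), class = "ncp_no_signal_error")
  falling <- titration_series("X", c(1000, 500, 250, 125),
                              c(100, 200, 400, 800))
  expect_error(fit_saturation(falling), class = "ncp_no_signal_error")
})

test_that("plateau recovery stays accurate under multiplicative noise", {
  true <- saturation_fit(8000, -7600, -0.008)
  errs <- vapply(1:100, function(s) {
    t <- gen_titration(true, cv = 0.05, seed = s)
    abs(fit_saturation(t)$y0 / true$y0 - 1)
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("closed-form saturating amount matches worked value and boundary", {
  f <- saturation_fit(10000, -9500, -0.01)
  x <- optimal_antibody_amount(f)
  expect_equal(as.numeric(x), log(5 / 9500) / (-0.01), tolerance = 1e-12)
  expect_equal(round(as.numeric(x), 2), 754.96)

  # curve already at target when -A equals the allowed gap
  f0 <- saturation_fit(10000, -(1 - 0.9995) * 10000, -0.01)
  expect_warning(x0 <- optimal_antibody_amount(f0),
                 class = "ncp_already_saturated_warning")
  expect_equal(as.numeric(x0), 0)

  # beyond-titration extrapolation is flagged, not an error
  xw <- optimal_antibody_amount(f, max_titrated_ng = 500)
  expect_match(attr(xw, "warnings"), "extrapolates")
})

test_that("closed form agrees with a bisection oracle on random fits", {
  set.seed(42)
  n <- 1000
  y0 <- runif(n, 500, 50000)
  A <- -y0 * runif(n, 0.05, 0.99)
  R0 <- -exp(runif(n, log(1e-4), log(0.5)))
  frac <- 0.9995
  for (i in seq_len(n)) {
    f <- saturation_fit(y0[i], A[i], R0[i])
    if ((1 - frac) * y0[i] >= -A[i]) next
    x_closed <- as.numeric(optimal_antibody_amount(f, frac))
    g <- function(x) y0[i] + A[i] * exp(R0[i] * x) - frac * y0[i]
    hi <- 1
    while (g(hi) < 0) hi <- hi * 2
    x_bisect <- uniroot(g, c(0, hi), tol = 1e-12)$root
    expect_equal(x_closed, x_bisect, tolerance = 1e-8)
  }
})

test_that("loss factor is the plain signal ratio and checks its inputs", {
  expect_equal(loss_factor(5000, 4000), 1.25)
  expect_equal(loss_factor(4000, 4000), 1)
  # applied to a combined plateau: 3000 * 1.25 = 3750
  expect_equal(3000 * loss_factor(5000, 4000), 3750)
  expect_equal(loss_factor(saturation_fit(5000, -4000, -0.01), 4000), 1.25)
  expect_error(loss_factor(5000, 4000, target = c("CD11b", "CXCR2")),
               class = "ncp_argument_error")
  expect_error(loss_factor(-1, 4000), class = "ncp_validation_error")
})

test_that("bead calibration is exact on log-linear beads and robust to noise", {
  cal <- fit_bead_calibration(gen_beads(c(500, 5000, 50000), 1, 1))
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 1, tolerance = 1e-12)

  # 2-level set: exact interpolation through both points
  b2 <- gen_beads(c(300, 30000), slope = 0.9, intercept = 1.4)
  cal2 <- fit_bead_calibration(b2)
  expect_equal(10^(cal2$slope * log10(b2$mdnfi) + cal2$intercept),
               b2$pe_per_bead, tolerance = 1e-9)

  expect_error(fit_bead_calibration(data.frame(pe_per_bead = c(1, 2),
                                               mdnfi = c(5, 5))),
               class = "ncp_singular_fit_error")

  slopes <- vapply(1:100, function(s) {
    fit_bead_calibration(gen_beads(c(500, 5000, 2e4, 5e4), 1.05, 0.8,
                                   cv = 0.02, seed = s))$slope
  }, 0)
  expect_lt(median(abs(slopes / 1.05 - 1)), 0.05)
})

test_that("MdnFI conversion inverts the bead line and scales with F:P", {
  cal <- fit_bead_calibration(gen_beads(c(500, 5000, 50000), 1, 1))
  expect_equal(mdnfi_to_copies(2000, cal), 20000, tolerance = 1e-9)
  cal95 <- fit_bead_calibration(gen_beads(c(500, 5000, 50000), 1, 1),
                                fp_ratio = 0.95)
  expect_equal(mdnfi_to_copies(2000, cal95), 19000, tolerance = 1e-9)
  # round trip on the bead points themselves
  b <- gen_beads(c(500, 5000, 50000), 1.1, 0.7)
  calb <- fit_bead_calibration(b)
  expect_equal(mdnfi_to_copies(b$mdnfi, calb), b$pe_per_bead, tolerance = 1e-9)
  expect_error(mdnfi_to_copies(0, cal), class = "ncp_domain_error")
  # monotone: more fluorescence, more molecules
  expect_true(all(diff(mdnfi_to_copies(c(10, 100, 1000), cal)) > 0))
})

test_that("end-to-end qFlow identity holds in the noise-free limit", {
  slope <- 1.02; intercept <- 0.9; fp <- 0.95
  true_copies <- 150000
  L <- 1.25
  # invert the pipeline to build consistent inputs
  corrected <- 10^((log10(true_copies / fp) - intercept) / slope)
  y0_comb <- corrected / L
  y0_surf <- 5000
  comb <- gen_titration(saturation_fit(y0_comb, -0.9 * y0_comb, -0.01),
                        cv = 0, target = "CD11b",
                        stain_context = "combined_fixed_perm")
  surf <- gen_titration(saturation_fit(y0_surf, -0.9 * y0_surf, -0.012),
                        cv = 0, target = "CD11b")
  beads <- gen_beads(c(500, 5000, 50000), slope, intercept)
  rep <- quantify_target(surf, y0_surf / L, comb, beads, fp_ratio = fp)
  expect_equal(rep$copies, true_copies, tolerance = 1e-6)
  expect_equal(rep$loss_factor, L, tolerance = 1e-9)
  expect_equal(rep$y0_combined, y0_comb, tolerance = 1e-6)
  expect_gt(rep$x_optimal_ng, 0)

  # with L = 1 and the combined plateau on a bead point, copies = pe * fp
  comb2 <- gen_titration(saturation_fit(5000, -4500, -0.01), cv = 0)
  rep2 <- quantify_target(6000, 6000, comb2, beads, fp_ratio = fp)
  expect_equal(rep2$copies,
               10^(slope * log10(5000) + intercept) * fp, tolerance = 1e-9)
})

test_that("end-to-end recovery under noise stays within 10%", {
  slope <- 1; intercept <- 1; fp <- 1
  true_copies <- 80000
  L <- 1.2
  corrected <- 10^((log10(true_copies / fp) - intercept) / slope)
  y0_comb <- corrected / L
  errs <- vapply(1:100, function(s) {
    comb <- gen_titration(saturation_fit(y0_comb, -0.9 * y0_comb, -0.01),
                          cv = 0.05, seed = s)
    surf <- gen_titration(saturation_fit(4000, -3600, -0.012),
                          cv = 0.05, seed = 1000 + s)
    beads <- gen_beads(c(500, 5000, 50000), slope, intercept,
                       cv = 0.02, seed = 2000 + s)
    rep <- quantify_target(surf, fit_saturation(surf)$y0 / L, comb, beads,
                           fp_ratio = fp)
    abs(rep$copies / true_copies - 1)
  }, 0)
  expect_lt(median(errs), 0.1)
})

test_that("component failures surface with a stage label", {
  beads <- gen_beads(c(500, 5000), 1, 1)
  flat <- titration_series("X", c(1000, 500, 250, 125), rep(500, 4),
                           "combined_fixed_perm")
  err <- tryCatch(quantify_target(6000, 6000, flat, beads),
                  ncp_error = identity)
  expect_s3_class(err, "ncp_no_signal_error")
  expect_match(conditionMessage(err), "combined stain")
})
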