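# Spectral reduction: AEW, ANS integration, MRE conversion and specific
# activity.

test_that("compute_aew matches hand values and the quadrature oracle", {
  # delta spectrum: all intensity at one wavelength
  wl <- seq(320, 360, 10)
  inten <- c(0, 0, 1, 0, 0)
  expect_equal(compute_aew(emission_spectrum(wl, inten, "trp")), 340)

  # two-point weighted mean by hand
  sp <- emission_spectrum(c(330, 350), c(1, 3), "trp")
  expect_equal(compute_aew(sp), 345)

  # truncated Gaussian peak vs continuous quadrature oracle; the window
  # asymmetry (310-400 around a 335 nm center) pulls the mean above 335
  f <- function(l) dnorm(l, 335, 15)
  grid <- seq(310, 400, 0.05)
  aew <- compute_aew(emission_spectrum(grid, f(grid), "trp"))
  oracle <- aew_quadrature_oracle(f, 310, 400)
  expect_gt(oracle, 335)
  # the discrete weighted mean converges to the continuous quadrature as
  # the grid refines; at 0.05 nm spacing they agree to a few micro-nm
  # relative
  expect_equal(aew, oracle, tolerance = 1e-4)
})

test_that("compute_aew is scale invariant, window bounded, and rejects degenerate input", {
  set.seed(42)
  for (i in 1:20) {
    wl <- sort(runif(30, 300, 420))
    inten <- runif(30, 0, 5)
    sp <- emission_spectrum(wl, inten, "trp")
    a <- compute_aew(sp)
    expect_gte(a, min(wl)); expect_lte(a, max(wl))
    scaled <- emission_spectrum(wl, inten * runif(1, 0.1, 100), "trp")
    expect_equal(compute_aew(scaled), a, tolerance = 1e-12)
  }
  zero <- emission_spectrum(c(330, 340), c(0, 0), "trp")
  expect_error(compute_aew(zero), "degenerate spectrum")
  expect_error(compute_aew(emission_spectrum(c(330, 340), c(1, -3), "trp")),
               "degenerate spectrum")
  expect_error(compute_aew(emission_spectrum(450:500, rep(1, 51), "ANS")),
               "trp")
})

test_that("integrate_ans matches closed forms and is additive over windows", {
  wl <- seq(450, 550, 5)
  # rectangle: constant 2 over a 100 nm window
  expect_equal(integrate_ans(emission_spectrum(wl, rep(2, length(wl)), "ANS")),
               200)
  expect_equal(integrate_ans(emission_spectrum(wl, rep(0, length(wl)), "ANS")),
               0)
  # triangle: rises to apex mid-window, area = base * height / 2
  tri <- pmax(0, 1 - abs(wl - 500) / 50)
  sp <- emission_spectrum(wl, tri, "ANS")
  expect_equal(integrate_ans(sp), 100 * 1 / 2)
  # fine-grid quadrature oracle agrees
  fine <- seq(450, 550, 0.01)
  sp_fine <- emission_spectrum(fine, pmax(0, 1 - abs(fine - 500) / 50), "ANS")
  expect_equal(integrate_ans(sp_fine), 50, tolerance = 1e-6)
  # additivity over adjacent windows, including off-grid edges
  a1 <- integrate_ans(sp, c(450, 487.5))
  a2 <- integrate_ans(sp, c(487.5, 550))
  expect_equal(a1 + a2, integrate_ans(sp), tolerance = 1e-12)
  expect_error(integrate_ans(sp, c(400, 500)), "window out of range")
})

test_that("mre_from_theta implements the per-residue normalisation", {
  expect_equal(mre_from_theta(cd_record(0, 115, 0.1, 2e-4)), 0)
  # hand evaluation: 0.01 * 115 / (10 * 0.1 * 2e-4)
  expect_equal(mre_from_theta(cd_record(0.01, 115, 0.1, 2e-4)), 5750)
  # sign follows theta; linear in theta, inverse in path and concentration
  expect_equal(mre_from_theta(cd_record(-0.01, 115, 0.1, 2e-4)), -5750)
  base <- mre_from_theta(cd_record(0.02, 110, 0.1, 1e-4))
  expect_equal(mre_from_theta(cd_record(0.04, 110, 0.1, 1e-4)), 2 * base)
  expect_equal(mre_from_theta(cd_record(0.02, 110, 0.2, 1e-4)), base / 2)
  expect_equal(mre_from_theta(cd_record(0.02, 110, 0.1, 2e-4)), base / 2)
  expect_error(cd_record(0.01, 115, 0, 2e-4), "invalid geometry")
  # fractional helix loss arithmetic on an MRE pair
  expect_equal((1 - (-8700) / (-10000)) * 100, 13)
})

test_that("specific_activity converts an A240 slope through Beer-Lambert", {
  flat <- activity_assay(0:5, rep(0.3, 6), protein_mg = 1)
  expect_equal(as.numeric(specific_activity(flat)), 0)
  # slope 0.00244/min with epsilon 2440, 1 cm, 1 mL, 1 mg -> 1 nmol/min/mg
  a <- activity_assay(0:5, 0.1 + 0.00244 * (0:5), protein_mg = 1)
  expect_equal(specific_activity(a), 1.0)
  # linear in slope and in volume
  a2 <- activity_assay(0:5, 0.1 + 2 * 0.00244 * (0:5), protein_mg = 1)
  expect_equal(specific_activity(a2), 2.0)
  a3 <- activity_assay(0:5, 0.1 + 0.00244 * (0:5), volume_ml = 3, protein_mg = 1)
  expect_equal(specific_activity(a3), 3.0)
  # negative slope returns zero with a flag
  neg <- activity_assay(0:5, 0.5 - 0.01 * (0:5), protein_mg = 1)
  expect_warning(v <- specific_activity(neg), "negative")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "negative_slope"))
  # non-linear trace triggers the initial-rate warning
  curved <- activity_assay(0:5, 0.1 + 0.05 * sqrt(0:5), protein_mg = 1)
  expect_warning(specific_activity(curved), "not linear")
})

test_that("activity recovery ratio of refolded versus native protein", {
  # specific activities via the assay reduction: native 4.4, refolded 1.1
  native <- activity_assay(0:5, 4.4 * 2440 * 1e-6 * (0:5), protein_mg = 1)
  refolded <- activity_assay(0:5, 1.1 * 2440 * 1e-6 * (0:5), protein_mg = 1)
  recovery <- 100 * specific_activity(refolded) / specific_activity(native)
  expect_equal(recovery, 25)
})

test_that("subtract_blank is pointwise and interpolates mismatched grids", {
  wl <- seq(450, 550, 5)
  sp <- emission_spectrum(wl, rep(5, length(wl)), "ANS")
  bl <- emission_spectrum(wl, rep(1, length(wl)), "ANS")
  expect_equal(subtract_blank(sp, bl)$intensities, rep(4, length(wl)))
  bl2 <- emission_spectrum(seq(450, 550, 10), rep(1, 11), "ANS")
  expect_equal(subtract_blank(sp, bl2)$intensities, rep(4, length(wl)))
  expect_error(subtract_blank(sp, emission_spectrum(wl, rep(1, 21), "ThT")),
               "probes differ")
})

test_that("build_curve reduces and orders per-condition spectra", {
  mk_delta <- function(center, conc) {
    wl <- seq(320, 380, 1)
    emission_spectrum(wl, as.numeric(wl == center), "trp",
                      condition = list(denaturant = "urea", conc_M = conc))
  }
  # supplied out of order; curve must come back sorted by concentration
  cu <- build_curve(list(mk_delta(355, 4), mk_delta(335, 0), mk_delta(345, 2)))
  expect_s3_class(cu, "denaturation_curve")
  expect_equal(cu$concentrations_M, c(0, 2, 4))
  expect_equal(cu$values, c(335, 345, 355))
  expect_equal(cu$observable, "aew")
  expect_error(build_curve(list()), "no spectra")
  expect_error(build_curve(list(mk_delta(335, 1), mk_delta(345, 1))),
               "ambiguous condition")
})
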