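# Fitting: round trips on generated data, global fits, error handling and
# model selection.

test_that("noiseless two-state data round-trips to high accuracy", {
  k <- thermo_constants()
  truth <- k315a_two_state(mf = 0.2, mu = -0.1)
  grid <- seq(0, 4, 0.25)
  cu <- denaturation_curve(grid, eval_two_state(truth, grid, k))
  fit <- fit_two_state(cu, k)
  expect_true(fit$converged)
  for (nm in c("dG0", "m", "yn", "yu", "mf", "mu")) {
    tv <- switch(nm, dG0 = truth$dG0, m = truth$m, yn = truth$yn,
                 yu = truth$yu, mf = truth$mf, mu = truth$mu)
    expect_equal(fit$estimates[[nm]], tv, tolerance = 1e-4)
  }
  expect_equal(fit$midpoints_M[[1]], 6.5 / 3.8, tolerance = 1e-6)
  # reported midpoints always equal dG/m of the estimates
  expect_equal(fit$midpoints_M[[1]],
               fit$estimates[["dG0"]] / fit$estimates[["m"]])
})

test_that("noiseless four-state data round-trips to high accuracy", {
  k <- thermo_constants()
  truth <- k315a_four_state()
  grid <- seq(0, 6, 0.25)
  cu <- denaturation_curve(grid, eval_four_state(truth, grid, k),
                           denaturant = "GdmCl")
  fit <- fit_four_state(cu, k)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[1:3]), c(1.3, 2.6, 8.9), tolerance = 1e-4)
  expect_equal(unname(fit$estimates[4:6]), c(2.1, 1.2, 2.3), tolerance = 1e-4)
  expect_equal(fit$total_dG, 12.8, tolerance = 1e-4)
  # midpoint ordering is enforced by construction
  expect_true(all(diff(fit$midpoints_M) > 0))
})

test_that("global two-state fits share thermodynamics across curves", {
  k <- thermo_constants()
  grid <- seq(0, 4, 0.25)
  # two probes of the same transition: same dG0/m, different signals
  pa <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
  pb <- two_state_params(6.5, 3.8, yn = 100, yu = 40)
  ca <- denaturation_curve(grid, eval_two_state(pa, grid, k))
  cb <- denaturation_curve(grid, eval_two_state(pb, grid, k),
                           observable = "ans_area")
  fit <- fit_two_state(list(ca, cb), k)
  expect_equal(fit$estimates[["dG0"]], 6.5, tolerance = 1e-4)
  expect_equal(fit$estimates[["yn.1"]], 350, tolerance = 1e-3)
  expect_equal(fit$estimates[["yn.2"]], 100, tolerance = 1e-3)
  expect_equal(fit$estimates[["yu.2"]], 40, tolerance = 1e-3)
})

test_that("noisy replicate recovery is unbiased within tolerance", {
  # 12 replicates at the published tetramer-monomer truth; shared-signal
  # global fit recovers dG0 and the midpoint within a few percent
  k <- thermo_constants()
  truth <- k315a_two_state()
  cfg <- generator_config("two_state", truth, seq(0, 4, 0.25),
                          noise_sigma = 0.2, n_replicates = 12, seed = 11)
  fit <- fit_two_state(gen_unfolding_curve(cfg), k,
                       fit_options(n_starts = 10, seed = 1,
                                   share_signals = TRUE))
  expect_equal(fit$estimates[["dG0"]], 6.5, tolerance = 0.1)
  expect_equal(fit$midpoints_M[[1]], 6.5 / 3.8, tolerance = 0.05)
})

test_that("non-identifiable and under-sized curves are rejected", {
  flat <- denaturation_curve(seq(0, 5, 1), rep(350, 6))
  expect_error(fit_two_state(flat), "non-identifiable")
  short <- denaturation_curve(c(0, 1, 2), c(350, 352, 355))
  expect_error(fit_two_state(short), "at least 6")
  expect_error(fit_four_state(denaturation_curve(seq(0, 5, 0.5),
                                                 rep(1, 11))),
               "non-identifiable|at least 12")
})

test_that("two-state-shaped data flags degenerate intermediates in a four-state fit", {
  k <- thermo_constants()
  p2 <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
  grid <- seq(0, 6, 0.25)
  cu <- denaturation_curve(grid, eval_two_state(p2, grid, k))
  fit <- suppressWarnings(fit_four_state(cu, k, fit_options(n_starts = 10)))
  expect_true(length(fit$flags) > 0)
  expect_match(fit$flags[1], "degenerate intermediate")
})

test_that("model_select usually chooses the generating state count", {
  # AICc selection is itself a random variable, so assert on the majority
  # over noise realisations rather than a single draw
  k <- thermo_constants()
  grid2 <- seq(0, 4, 0.2)
  y2 <- eval_two_state(k315a_two_state(), grid2, k)
  pick2 <- vapply(1:7, function(s) {
    cu <- denaturation_curve(grid2, y2 + .rnorm_seeded(length(y2), 0.05, s))
    suppressWarnings(model_select(cu, k, fit_options(n_starts = 6))$selected)
  }, character(1))
  expect_gte(mean(pick2 == "2_state"), 5 / 7)

  grid4 <- seq(0, 6, 0.2)
  y4 <- eval_four_state(k315a_four_state(yN = 340, yI1 = 350,
                                         yI2 = 358, yU = 368), grid4, k)
  pick4 <- vapply(1:7, function(s) {
    cu <- denaturation_curve(grid4, y4 + .rnorm_seeded(length(y4), 0.05, s),
                             denaturant = "GdmCl")
    suppressWarnings(model_select(cu, k, fit_options(n_starts = 6))$selected)
  }, character(1))
  expect_gte(mean(pick4 == "4_state"), 5 / 7)

  one <- denaturation_curve(grid4,
                            y4 + .rnorm_seeded(length(y4), 0.05, 1),
                            denaturant = "GdmCl")
  sel <- suppressWarnings(model_select(one, k, fit_options(n_starts = 6)))
  expect_true(all(c("aicc", "f_p_vs_simpler") %in% names(sel$table)))

  flat6 <- denaturation_curve(seq(0, 5, 1), rep(1, 6))
  expect_error(model_select(flat6, k), "no model fits")
})

test_that("standard errors cover the truth at reasonable rates", {
  # on noisy data the reported SE of dG0 should be of the right order:
  # the absolute error should rarely exceed 3 SE
  k <- thermo_constants()
  truth <- k315a_two_state()
  cfg <- generator_config("two_state", truth, seq(0, 4, 0.25),
                          noise_sigma = 0.2, n_replicates = 8, seed = 31)
  curves <- gen_unfolding_curve(cfg)
  covered <- vapply(curves, function(cu) {
    f <- suppressWarnings(fit_two_state(cu, k, fit_options(n_starts = 8)))
    abs(f$estimates[["dG0"]] - 6.5) < 3 * f$standard_errors[["dG0"]]
  }, logical(1))
  expect_gte(mean(covered), 0.75)
})
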