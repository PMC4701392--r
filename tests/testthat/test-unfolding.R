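# Model evaluation: two-state and four-state linear-extrapolation models,
# state populations and derived quantities, checked against independent
# oracles.

test_that("eval_two_state reproduces the midpoint and hand-evaluated values", {
  k <- thermo_constants()
  p <- two_state_params(6, 3, yn = 0, yu = 100)
  # at D = dG0/m with flat baselines the signal is halfway between states
  expect_equal(eval_two_state(p, 2, k), 50)
  # published tetramer-monomer parameters: midpoint dG0/m
  pk <- k315a_two_state()
  expect_equal(midpoints(pk)[["T-M"]], 6.5 / 3.8)
  expect_equal(round(midpoints(pk)[["T-M"]], 1), 1.7)
  # scalar hand evaluation of the closed form at D = 0
  K <- exp(-6.5 / k$RT)
  expect_equal(eval_two_state(pk, 0, k), (350 + 355 * K) / (1 + K))
  # sloped baselines enter the branch signals
  ps <- two_state_params(6, 3, yn = 10, yu = 20, mf = 1, mu = -1)
  K2 <- exp(-(6 - 3 * 1) / k$RT)
  expect_equal(eval_two_state(ps, 1, k), (11 + 19 * K2) / (1 + K2))
})

test_that("eval_two_state is overflow-safe and monotone between baselines", {
  k <- thermo_constants()
  huge <- two_state_params(1e6, 3, yn = 1, yu = 2)
  expect_equal(eval_two_state(huge, 0, k), 1)
  tiny <- two_state_params(1e-6, 1e6, yn = 1, yu = 2)
  expect_equal(eval_two_state(tiny, 5, k), 2)
  p <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
  y <- eval_two_state(p, seq(0, 6, 0.01), k)
  expect_true(all(diff(y) >= 0))
})

test_that("eval_four_state and state_fractions agree with the partition-sum oracle", {
  k <- thermo_constants()
  p <- k315a_four_state()
  for (D in c(0, 0.5, 1, 2, 3, 3.9, 5, 6)) {
    oracle <- partition_oracle(p, D)
    expect_equal(as.numeric(state_fractions(p, D, k)), oracle$fractions,
                 tolerance = 1e-12)
    expect_equal(eval_four_state(p, D, k), oracle$signal, tolerance = 1e-12)
  }
  # native limit: enormous step free energies pin the population on N
  stiff <- four_state_params(1e6, 1e6, 1e6, 2, 2, 2, 10, 20, 30, 40)
  expect_equal(eval_four_state(stiff, 3, k), 10)
  expect_equal(as.numeric(state_fractions(stiff, 0, k)), c(1, 0, 0, 0))
})

test_that("state fractions are a unit partition and weight the signal", {
  k <- thermo_constants()
  p <- k315a_four_state()
  D <- seq(0, 10, 0.1)
  f <- state_fractions(p, D, k)
  expect_true(all(f >= 0))
  expect_lt(max(abs(rowSums(f) - 1)), 1e-12)
  # signal equals the fraction-weighted state signals
  y <- f %*% c(p$yN, p$yI1, p$yI2, p$yU)
  expect_equal(as.numeric(y), eval_four_state(p, D, k), tolerance = 1e-12)
  # at the second midpoint the flanking intermediates are equally populated
  fmid <- state_fractions(p, p$dG2 / p$m2, k)
  expect_equal(fmid[1, "I1"], fmid[1, "I2"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the four-state model collapses to two-state in the degenerate limit", {
  k <- thermo_constants()
  p2 <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
  p4 <- four_state_params(6.5, 1e5, 1e5, 3.8, 1, 1,
                          yN = 350, yI1 = 355, yI2 = 355, yU = 355)
  D <- seq(0, 6, 0.05)
  expect_lt(max(abs(eval_four_state(p4, D, k) - eval_two_state(p2, D, k))),
            1e-9)
})

test_that("midpoints are dG/m, match the published values and are signal-scale invariant", {
  p <- k315a_four_state()
  mids <- midpoints(p)
  expect_equal(as.numeric(mids), c(1.3 / 2.1, 2.6 / 1.2, 8.9 / 2.3))
  expect_equal(round(mids[["I2-U"]], 1), 3.9)
  # degenerate zero free energy
  expect_equal(midpoints(two_state_params(1e-300, 2, 0, 1))[[1]], 5e-301)
  # invariance under uniform signal scaling
  p_scaled <- four_state_params(1.3, 2.6, 8.9, 2.1, 1.2, 2.3,
                                yN = 3480, yI1 = 3520, yI2 = 3540, yU = 3570)
  expect_equal(midpoints(p_scaled), mids)
  # bisection oracle: the second midpoint is the root of fI1(D) = fI2(D)
  k <- thermo_constants()
  g <- function(D) {
    f <- state_fractions(p, D, k)
    f[1, "I1"] - f[1, "I2"]
  }
  root <- uniroot(g, c(1, 3), tol = 1e-12)$root
  expect_equal(root, mids[["I1-I2"]], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("total free energy accumulates the step free energies", {
  expect_equal(total_free_energy(k315a_four_state()), 12.8)
  set.seed(7)
  for (i in 1:10) {
    dG <- runif(3, 0.5, 10)
    p <- four_state_params(dG[1], dG[2], dG[3], 2, 2, 2, 1, 2, 3, 4)
    acc <- 0; for (g in dG) acc <- acc + g # independent accumulation
    expect_equal(total_free_energy(p), acc)
  }
})

test_that("parameter constructors enforce invariants", {
  expect_error(two_state_params(6, -3, 0, 1), "m must be positive")
  expect_error(two_state_params(NaN, 3, 0, 1), "finite")
  expect_error(four_state_params(1, 2, 3, 2, -1, 2, 1, 2, 3, 4), "positive")
  expect_error(thermo_constants(T = -1), "positive")
  expect_equal(thermo_constants()$RT, 1.987e-3 * 298.15)
})
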