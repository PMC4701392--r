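# Shared ground-truth parameter sets and independent oracles used across
# the test files. The tetramer-to-monomer urea transition and the
# monomer unfolding steps in GdmCl use the published K315A values.

k315a_two_state <- function(yn = 350, yu = 355, mf = 0, mu = 0)
  two_state_params(dG0 = 6.5, m = 3.8, yn = yn, yu = yu, mf = mf, mu = mu)

k315a_four_state <- function(yN = 348, yI1 = 352, yI2 = 354, yU = 357)
  four_state_params(dG1 = 1.3, dG2 = 2.6, dG3 = 8.9,
                    m1 = 2.1, m2 = 1.2, m3 = 2.3,
                    yN = yN, yI1 = yI1, yI2 = yI2, yU = yU)

# brute-force partition-sum oracle for the sequential four-state model:
# enumerates the four Boltzmann terms directly, independent of the
# package's softmax evaluation path
partition_oracle <- function(p, D, RT = 1.987e-3 * 298.15) {
  g1 <- -(p$dG1 - p$m1 * D) / RT
  g2 <- g1 - (p$dG2 - p$m2 * D) / RT
  g3 <- g2 - (p$dG3 - p$m3 * D) / RT
  w <- c(1, exp(g1), exp(g2), exp(g3))
  list(fractions = w / sum(w),
       signal = sum(w * c(p$yN, p$yI1, p$yI2, p$yU)) / sum(w))
}

# reproducible noise vector for ad-hoc test data
.rnorm_seeded <- function(n, sd, seed) {
  set.seed(seed)
  rnorm(n, 0, sd)
}

# continuous-quadrature oracle for the average emission wavelength of an
# intensity profile given as a function of wavelength
aew_quadrature_oracle <- function(intensity_fn, lower, upper) {
  num <- stats::integrate(function(l) l * intensity_fn(l), lower, upper,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(intensity_fn, lower, upper, rel.tol = 1e-10)$value
  num / den
}
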