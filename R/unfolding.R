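# Linear-extrapolation equilibrium unfolding models: two-state
# (Santoro-Bolen) and sequential four-state evaluation, state populations
# and derived thermodynamic quantities.

#' Two-state unfolding parameters
#'
#' Parameters of the two-state linear-extrapolation (Santoro-Bolen) model:
#' the native and unfolded baselines are linear in denaturant,
#' `yn + mf*D` and `yu + mu*D`, and the equilibrium constant is
#' `exp(-(dG0 - m*D)/RT)`.
#'
#' @param dG0 unfolding free energy in the absence of denaturant, kcal/mol.
#' @param m dependence of the free energy on denaturant, kcal/(mol M);
#'   positive for a denaturation transition.
#' @param yn,yu native and unfolded signal intercepts (observable units).
#' @param mf,mu native and unfolded baseline slopes (units per M).
#' @return An object of class `two_state_params`.
#' @examples
#' p <- two_state_params(dG0 = 6.5, m = 3.8, yn = 350, yu = 355)
#' midpoints(p) # 6.5 / 3.8
#' @export
two_state_params <- function(dG0, m, yn, yu, mf = 0, mu = 0) {
  vals <- c(dG0 = dG0, m = m, yn = yn, yu = yu, mf = mf, mu = mu)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (m <= 0) stop("m must be positive for a denaturation transition")
  structure(as.list(vals), class = "two_state_params")
}

#' Sequential four-state unfolding parameters
#'
#' Parameters of the sequential model N <-> I1 <-> I2 <-> U with
#' per-transition free energies `dG1..dG3` (kcal/mol) and m-values
#' `m1..m3` (kcal/(mol M)). State signals are flat for the intermediates;
#' optional baseline slopes `sN` and `sU` act on the end states only.
#'
#' @param dG1,dG2,dG3 standard free energies of the N-I1, I1-I2 and I2-U
#'   steps at zero denaturant, kcal/mol.
#' @param m1,m2,m3 m-values of the three steps, kcal/(mol M), all positive.
#' @param yN,yI1,yI2,yU state signals (observable units).
#' @param sN,sU optional baseline slopes of the native and unfolded signals
#'   (units per M), default 0.
#' @return An object of class `four_state_params`.
#' @examples
#' p <- four_state_params(1.3, 2.6, 8.9, 2.1, 1.2, 2.3,
#'                        yN = 348, yI1 = 352, yI2 = 354, yU = 357)
#' midpoints(p)
#' total_free_energy(p)
#' @export
four_state_params <- function(dG1, dG2, dG3, m1, m2, m3,
                              yN, yI1, yI2, yU, sN = 0, sU = 0) {
  vals <- c(dG1 = dG1, dG2 = dG2, dG3 = dG3, m1 = m1, m2 = m2, m3 = m3,
            yN = yN, yI1 = yI1, yI2 = yI2, yU = yU, sN = sN, sU = sU)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (m1 <= 0 || m2 <= 0 || m3 <= 0) stop("m-values must be positive")
  structure(as.list(vals), class = "four_state_params")
}

# ---- internal sequential-model machinery -------------------------------
# A sequential n-state model is described by per-step (dG, m) vectors and
# n state signals; the first/last state may carry a baseline slope. State
# weights are a softmax over cumulative -(dGi - mi*D)/RT, evaluated with
# max-subtraction so large free energies never overflow.

.seq_log_weights <- function(D, dG, m, RT) {
  nD <- length(D)
  steps <- vapply(seq_along(dG),
                  function(i) -(dG[i] - m[i] * D) / RT,
                  numeric(nD))
  steps <- matrix(steps, nrow = nD)
  cum <- steps
  if (ncol(steps) > 1L)
    for (j in 2:ncol(steps)) cum[, j] <- cum[, j - 1L] + steps[, j]
  cbind(0, cum) # state 1 carries log-weight 0
}

.seq_fractions <- function(D, dG, m, RT) {
  lw <- .seq_log_weights(D, dG, m, RT)
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

.seq_signal <- function(D, dG, m, y, slope_first, slope_last, RT) {
  f <- .seq_fractions(D, dG, m, RT)
  n <- length(y)
  Y <- matrix(rep(y, each = length(D)), nrow = length(D))
  Y[, 1L] <- Y[, 1L] + slope_first * D
  Y[, n] <- Y[, n] + slope_last * D
  rowSums(f * Y)
}

#' Evaluate the two-state unfolding model
#'
#' Computes the observed signal
#' \deqn{y(D) = \frac{(y_n + m_f D) + (y_u + m_u D)\,
#'   e^{-(\Delta G_u^0 - m D)/RT}}{1 + e^{-(\Delta G_u^0 - m D)/RT}}}
#' using a numerically stable logistic, so arbitrarily large free energies
#' do not overflow. At the midpoint `D = dG0/m` with flat baselines the
#' value is the mean of `yn` and `yu`.
#'
#' @param p a [two_state_params()] object.
#' @param D denaturant concentration(s), mol/L, non-negative.
#' @param k a [thermo_constants()] object.
#' @return Model signal, same length as `D`.
#' @export
eval_two_state <- function(p, D, k = thermo_constants()) {
  stopifnot(inherits(p, "two_state_params"), inherits(k, "thermo_constants"))
  if (any(D < 0)) stop("denaturant concentrations must be non-negative")
  fu <- stats::plogis(-(p$dG0 - p$m * D) / k$RT)
  (p$yn + p$mf * D) * (1 - fu) + (p$yu + p$mu * D) * fu
}

#' Evaluate the sequential four-state unfolding model
#'
#' Computes the Boltzmann-weighted mean of the four state signals, with
#' cumulative free energies `dG1`, `dG1+dG2`, `dG1+dG2+dG3` for I1, I2 and
#' U relative to N, each depressed linearly by denaturant through its
#' m-value. Weights are evaluated as a max-subtracted softmax so huge free
#' energies stay finite.
#'
#' @param p a [four_state_params()] object.
#' @param D denaturant concentration(s), mol/L, non-negative.
#' @param k a [thermo_constants()] object.
#' @return Model signal, same length as `D`.
#' @export
eval_four_state <- function(p, D, k = thermo_constants()) {
  stopifnot(inherits(p, "four_state_params"), inherits(k, "thermo_constants"))
  if (any(D < 0)) stop("denaturant concentrations must be non-negative")
  .seq_signal(D, c(p$dG1, p$dG2, p$dG3), c(p$m1, p$m2, p$m3),
              c(p$yN, p$yI1, p$yI2, p$yU), p$sN, p$sU, k$RT)
}

#' Equilibrium state populations of the four-state model
#'
#' @param p a [four_state_params()] object.
#' @param D denaturant concentration(s), mol/L.
#' @param k a [thermo_constants()] object.
#' @return A matrix with one row per concentration and columns
#'   `N`, `I1`, `I2`, `U`; rows are non-negative and sum to one.
#'   `eval_four_state()` equals the fraction-weighted mean of the state
#'   signals.
#' @export
state_fractions <- function(p, D, k = thermo_constants()) {
  stopifnot(inherits(p, "four_state_params"), inherits(k, "thermo_constants"))
  if (any(D < 0)) stop("denaturant concentrations must be non-negative")
  f <- .seq_fractions(D, c(p$dG1, p$dG2, p$dG3), c(p$m1, p$m2, p$m3), k$RT)
  colnames(f) <- c("N", "I1", "I2", "U")
  f
}

#' Transition midpoints under the linear extrapolation method
#'
#' The midpoint of each transition is the denaturant concentration at which
#' that step is half complete, `D_1/2 = dG_i / m_i`. Midpoints are
#' invariant to any rescaling of the state signals.
#'
#' @param p a [two_state_params()] or [four_state_params()] object.
#' @return Numeric vector of midpoints in M, one per transition.
#' @export
midpoints <- function(p) UseMethod("midpoints")

#' @export
midpoints.two_state_params <- function(p) {
  if (p$m <= 0) stop("invalid m-value")
  c(`T-M` = p$dG0 / p$m)
}

#' @export
midpoints.four_state_params <- function(p) {
  m <- c(p$m1, p$m2, p$m3)
  if (any(m <= 0)) stop("invalid m-value")
  stats::setNames(c(p$dG1, p$dG2, p$dG3) / m, c("N-I1", "I1-I2", "I2-U"))
}

#' Total unfolding free energy of a sequential model
#'
#' Sum of the per-step free energies, `dG1 + dG2 + dG3`, the total
#' stability of the native state against complete unfolding at zero
#' denaturant.
#'
#' @param p a [four_state_params()] object.
#' @return Total free energy, kcal/mol.
#' @export
total_free_energy <- function(p) {
  stopifnot(inherits(p, "four_state_params"))
  p$dG1 + p$dG2 + p$dG3
}
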