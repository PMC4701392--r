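# Aggregation kinetics: exponential-phase decomposition of turbidity
# (A360 light-scattering) time courses and thioflavin-T enhancement.

#' Construct a turbidity time course
#'
#' @param times_min sampling times in minutes, increasing from 0, at least
#'   8 points.
#' @param a360 light-scattering absorbance at 360 nm at each time.
#' @param condition free-text condition label.
#' @return An object of class `aggregation_trace`.
#' @export
aggregation_trace <- function(times_min, a360, condition = "") {
  times_min <- as.numeric(times_min); a360 <- as.numeric(a360)
  if (length(times_min) < 8L) stop("a trace needs at least 8 points")
  if (length(times_min) != length(a360))
    stop("times and signal must have equal length")
  if (any(!is.finite(times_min)) || any(times_min < 0))
    stop("times must be finite and non-negative")
  if (any(diff(times_min) <= 0)) stop("times must be increasing")
  if (any(!is.finite(a360))) stop("signal must be finite")
  structure(list(times_min = times_min, a360 = a360, condition = condition),
            class = "aggregation_trace")
}

#' @export
print.aggregation_trace <- function(x, ...) {
  cat(sprintf("aggregation_trace: %d points, 0-%.3g min%s\n",
              length(x$times_min), max(x$times_min),
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else ""))
  invisible(x)
}

# y(t) = y0 + sum_i yi * (1 - exp(-ki t))
.agg_model <- function(t, y0, amplitudes, rates) {
  y <- rep(y0, length(t))
  for (i in seq_along(rates))
    y <- y + amplitudes[i] * (1 - exp(-rates[i] * t))
  y
}

.agg_fit_result <- function(model, y_offset, amplitudes, rates, trace,
                            n_param) {
  fitted <- if (model == "linear")
    y_offset + amplitudes[1] * trace$times_min
  else .agg_model(trace$times_min, y_offset, amplitudes, rates)
  resid <- trace$a360 - fitted
  rss <- sum(resid^2)
  n <- length(resid)
  kk <- n_param + 1L
  # floor the RSS at numerical-noise level relative to the signal scale so
  # that exact-fit degeneracies (e.g. a constant trace) do not hand the
  # most complex model an unbounded log-likelihood
  scale <- max(abs(trace$a360), 1)
  rss_eff <- max(rss, n * (1e-10 * scale)^2)
  aicc <- if (n - kk - 1L > 0)
    n * log(rss_eff / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
  else Inf
  structure(list(model = model, y_offset = y_offset,
                 amplitudes = amplitudes, rates = rates,
                 fitted = fitted, residuals = resid,
                 rss = rss, rms = sqrt(rss / n), aicc = aicc,
                 n_param = n_param, condition = trace$condition),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  cat(sprintf("aggregation_fit: %s, RMS %.4g\n", x$model, x$rms))
  if (x$model == "linear") {
    cat(sprintf("  slope = %.4g /min, intercept = %.4g\n",
                x$amplitudes[1], x$y_offset))
  } else {
    for (i in seq_along(x$rates))
      cat(sprintf("  phase %d: k = %.4g /min, amplitude = %.4g\n",
                  i, x$rates[i], x$amplitudes[i]))
    cat(sprintf("  offset y0 = %.4g\n", x$y_offset))
  }
  invisible(x)
}

#' Fit exponential aggregation kinetics
#'
#' Fits the saturating-rise model
#' \deqn{y(t) = y_0 + \sum_{i=1}^{n} y_i\,[1 - e^{-k_i t}]}
#' to a turbidity time course with one or two phases, by
#' Levenberg-Marquardt least squares. `y0` is the offset at time zero and
#' the amplitudes are the asymptotic increments of each phase. Rates are
#' kept positive by a log parameterisation and, for two phases, ordered
#' `k1 > k2` by construction.
#'
#' @param trace an [aggregation_trace()].
#' @param n_phases 1 or 2 exponential phases.
#' @param n_starts number of multi-start optimisations.
#' @param seed seed for start jitter.
#' @return An object of class `aggregation_fit` with `y_offset`,
#'   `amplitudes`, `rates` (1/min), residual `rms` and `aicc`.
#' @examples
#' tr <- aggregation_trace(seq(0, 30, 0.5),
#'                         2 * (1 - exp(-0.1 * seq(0, 30, 0.5))))
#' fit_exponential(tr)$rates # 0.1
#' @export
fit_exponential <- function(trace, n_phases = 1, n_starts = 8, seed = 1) {
  stopifnot(inherits(trace, "aggregation_trace"), n_phases %in% c(1, 2))
  t <- trace$times_min; y <- trace$a360
  rise <- y[length(y)] - y[1]
  # crude rate guess: time to reach half of the total rise
  half <- y[1] + rise / 2
  t_half <- t[which.min(abs(y - half))]
  k0 <- if (t_half > 0) log(2) / t_half else 1 / max(t[t > 0][1], 1e-3)
  k0 <- min(max(k0, 1e-4), 1e3)
  # parameterisation: theta = (y0, amp_1..n, w_1..n) with
  # k_n = exp(w_n), k_{i} = k_{i+1} + exp(w_i) so k1 > k2 > ... > 0
  unpack <- function(th) {
    amps <- th[1 + seq_len(n_phases)]
    w <- th[1 + n_phases + seq_len(n_phases)]
    k <- rev(cumsum(rev(exp(w))))
    list(y0 = th[1], amps = amps, k = k)
  }
  residfun <- function(th) {
    p <- unpack(th)
    .agg_model(t, p$y0, p$amps, p$k) - y
  }
  base <- if (n_phases == 1) c(y[1], rise, log(k0))
          else c(y[1], rise / 2, rise / 2, log(k0 * 4), log(k0 / 4))
  starts <- list(base)
  if (n_starts > 1L)
    starts <- c(starts, .with_seed(seed, lapply(seq_len(n_starts - 1L),
      function(j) {
        th <- base
        th[1 + n_phases + seq_len(n_phases)] <-
          th[1 + n_phases + seq_len(n_phases)] + stats::rnorm(n_phases, 0, 1)
        th[1 + seq_len(n_phases)] <-
          th[1 + seq_len(n_phases)] * exp(stats::rnorm(n_phases, 0, 0.3))
        th
      })))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = residfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("did not converge")
  p <- unpack(best$par)
  if (any(!is.finite(p$k)) || any(p$k <= 0)) stop("invalid kinetics: non-positive rate")
  .agg_fit_result(paste0("exp", n_phases), p$y0, p$amps, p$k, trace,
                  n_param = length(best$par))
}

#' Fit a linear aggregation trace
#'
#' Ordinary least-squares line for traces whose signal rises linearly over
#' the observation window (the slow-growth limit of the exponential
#' model).
#'
#' @param trace an [aggregation_trace()].
#' @return An `aggregation_fit` with `model = "linear"`; the slope
#'   (signal/min) is stored in `amplitudes[1]` and also as `$slope`.
#' @export
fit_linear <- function(trace) {
  stopifnot(inherits(trace, "aggregation_trace"))
  d <- data.frame(times_min = trace$times_min, a360 = trace$a360)
  fit <- stats::lm(a360 ~ times_min, data = d)
  co <- stats::coef(fit)
  out <- .agg_fit_result("linear", unname(co[1]), unname(co[2]), numeric(0),
                         trace, n_param = 2L)
  out$slope <- unname(co[2])
  out$intercept <- unname(co[1])
  out
}

#' Select the kinetic model for an aggregation trace
#'
#' Fits single-exponential, double-exponential and linear growth models
#' and returns the one with the lowest AICc; exact ties go to the simpler
#' model (linear < exp1 < exp2).
#'
#' @param trace an [aggregation_trace()].
#' @param seed seed forwarded to the exponential fits.
#' @return The winning `aggregation_fit`, with the comparison table in
#'   `$selection` (model, rss, aicc).
#' @export
select_kinetic_model <- function(trace, seed = 1) {
  stopifnot(inherits(trace, "aggregation_trace"))
  candidates <- list(
    linear = function() fit_linear(trace),
    exp1 = function() fit_exponential(trace, 1, seed = seed),
    exp2 = function() fit_exponential(trace, 2, seed = seed))
  fits <- list(); errs <- character(0)
  for (nm in names(candidates)) {
    f <- tryCatch(candidates[[nm]](), error = function(e) e)
    if (inherits(f, "error")) errs[nm] <- conditionMessage(f)
    else fits[[nm]] <- f
  }
  if (length(fits) == 0L)
    stop("no model fits: ", paste(errs, collapse = "; "))
  aicc <- vapply(fits, `[[`, 0, "aicc")
  # candidates are ordered simple -> complex, so which.min on the vector
  # already breaks exact ties toward the simpler model
  win <- fits[[which.min(aicc)]]
  win$selection <- data.frame(model = names(fits),
                              rss = vapply(fits, `[[`, 0, "rss"),
                              aicc = aicc, row.names = NULL)
  win
}

#' Thioflavin-T fluorescence enhancement over time
#'
#' Ratio of the mean ThT emission intensity in the peak window (default
#' 475-495 nm) of each timepoint spectrum to that of the corrected
#' zero-time baseline spectrum. Values above 1 indicate growth of
#' ThT-binding (ordered, amyloid-like) aggregates.
#'
#' @param baseline zero-time [emission_spectrum()], probe `"ThT"`.
#' @param timepoints list of ThT spectra on the same wavelength grid.
#' @param window peak-region window in nm.
#' @return Numeric vector of fold-changes, one per timepoint.
#' @export
tht_enhancement <- function(baseline, timepoints, window = c(475, 495)) {
  stopifnot(inherits(baseline, "emission_spectrum"))
  if (inherits(timepoints, "emission_spectrum")) timepoints <- list(timepoints)
  stopifnot(all(vapply(timepoints, inherits, logical(1), "emission_spectrum")))
  if (baseline$probe != "ThT" ||
      any(vapply(timepoints, function(s) s$probe, character(1)) != "ThT"))
    stop("tht_enhancement expects ThT spectra")
  for (s in timepoints)
    if (length(s$wavelengths) != length(baseline$wavelengths) ||
        any(s$wavelengths != baseline$wavelengths))
      stop("all spectra must share the baseline wavelength grid")
  sel <- baseline$wavelengths >= window[1] & baseline$wavelengths <= window[2]
  if (!any(sel)) stop("window outside the recorded grid")
  ref <- mean(baseline$intensities[sel])
  if (!is.finite(ref) || ref <= 0)
    stop("degenerate baseline: non-positive peak-region intensity")
  vapply(timepoints, function(s) mean(s$intensities[sel]) / ref, numeric(1))
}
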