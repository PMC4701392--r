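# Global least-squares fitting of sequential linear-extrapolation
# unfolding models. All fits run through one internal engine that
# parameterises a sequential n-state model by log midpoint increments and
# log m-values, which enforces positive m-values and the transition
# ordering dG1/m1 < dG2/m2 < dG3/m3 without explicit constraints.
# Thermodynamic parameters are shared across curves in a global fit;
# signals and baselines stay per-curve.

#' Options controlling unfolding-model fits
#'
#' @param n_starts number of multi-start optimisations. The first start
#'   uses data-driven heuristics (baselines from the first/last quartiles,
#'   midpoints from the signal-derivative peak); the rest jitter it.
#' @param seed integer seed for the start jitter; recorded in the result.
#' @param maxiter,ftol,ptol Levenberg-Marquardt control passed to
#'   [minpack.lm::nls.lm()].
#' @param end_slopes logical; for three- and four-state fits, free baseline
#'   slopes on the two end states (two-state fits always have them).
#' @param share_signals logical; in a multi-curve global fit, share the
#'   state signals (and baselines) across curves as well as the
#'   thermodynamic parameters. Appropriate when the curves are replicate
#'   measurements of the same experiment; leave `FALSE` (per-curve
#'   signals) when curves come from different probes or conditions.
#' @param weights optional per-point weight vector (or list of vectors for
#'   several curves) for weighted least squares.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 20, seed = 1, maxiter = 500,
                        ftol = 1e-13, ptol = 1e-13,
                        end_slopes = FALSE, share_signals = FALSE,
                        weights = NULL) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxiter = maxiter, ftol = ftol, ptol = ptol,
                 end_slopes = end_slopes, share_signals = share_signals,
                 weights = weights),
            class = "fit_options")
}

# evaluate an expression with a private RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.as_curve_list <- function(curves) {
  if (inherits(curves, "denaturation_curve")) curves <- list(curves)
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "denaturation_curve")))
  curves
}

.check_identifiable <- function(curves, min_points) {
  for (cu in curves) {
    if (length(cu$values) < min_points)
      stop(sprintf("non-identifiable fit: need at least %d points, got %d",
                   min_points, length(cu$values)))
    rng <- diff(range(cu$values))
    if (!is.finite(rng) || rng <= 1e-10 * (abs(mean(cu$values)) + 1))
      stop("non-identifiable fit: flat signal")
  }
  invisible(TRUE)
}

# ---- parameter packing --------------------------------------------------
# theta layout: [u_1..u_s] log midpoint increments, [v_1..v_s] log m,
# then per curve: n state signals (+ 2 end slopes if requested).
.theta_unpack <- function(theta, n_states, n_curves, end_slopes) {
  s <- n_states - 1L
  u <- theta[seq_len(s)]
  v <- theta[s + seq_len(s)]
  Dmid <- cumsum(exp(u))
  m <- exp(v)
  per <- n_states + if (end_slopes) 2L else 0L
  blocks <- matrix(theta[2L * s + seq_len(per * n_curves)], nrow = per)
  sig <- lapply(seq_len(n_curves), function(i) {
    block <- blocks[, i]
    list(y = block[seq_len(n_states)],
         s_first = if (end_slopes) block[n_states + 1L] else 0,
         s_last = if (end_slopes) block[n_states + 2L] else 0)
  })
  list(Dmid = Dmid, m = m, dG = m * Dmid, sig = sig, Ymat = blocks)
}

# flat layout of stacked curves for fast residual evaluation: all
# concentrations concatenated, with an index mapping each point back to
# its curve
.stack_curves <- function(curves, weights, share_signals = FALSE) {
  D <- unlist(lapply(curves, `[[`, "concentrations_M"))
  y <- unlist(lapply(curves, `[[`, "values"))
  n <- vapply(curves, function(cu) length(cu$values), integer(1))
  idx <- if (share_signals) rep(1L, sum(n)) else rep(seq_along(curves), n)
  sw <- if (!is.null(weights)) sqrt(unlist(weights)) else NULL
  list(D = D, y = y, idx = idx,
       n_groups = if (share_signals) 1L else length(curves), sqrt_w = sw)
}

.seq_residuals <- function(theta, stack, n_states, n_curves, end_slopes, RT) {
  s <- n_states - 1L
  u <- theta[seq_len(s)]
  v <- theta[s + seq_len(s)]
  Dmid <- cumsum(exp(u))
  m <- exp(v)
  dG <- m * Dmid
  per <- n_states + if (end_slopes) 2L else 0L
  blocks <- matrix(theta[2L * s + seq_len(per * n_curves)], nrow = per)
  f <- .seq_fractions(stack$D, dG, m, RT)
  # per-point state signals via row indexing of the per-curve blocks
  S <- t(blocks[seq_len(n_states), stack$idx, drop = FALSE])
  yhat <- rowSums(f * S)
  if (end_slopes) {
    yhat <- yhat + f[, 1L] * blocks[n_states + 1L, stack$idx] * stack$D +
      f[, n_states] * blocks[n_states + 2L, stack$idx] * stack$D
  }
  r <- yhat - stack$y
  if (!is.null(stack$sqrt_w)) r <- r * stack$sqrt_w
  r
}

# ---- variable projection ------------------------------------------------
# Given the thermodynamic parameters, the model is linear in every signal
# and baseline-slope parameter: y_hat = X beta with X built from the state
# fractions. The inner linear solve profiles those out per curve, so the
# outer optimiser only sees the 2(n_states - 1) thermodynamic parameters.

.profile_design <- function(fr, D, n_states, end_slopes) {
  if (end_slopes) cbind(fr, fr[, 1L] * D, fr[, n_states] * D) else fr
}

.profile_residuals <- function(thermo_theta, stack, n_states, n_curves,
                               end_slopes, RT, return_beta = FALSE) {
  s <- n_states - 1L
  Dmid <- cumsum(exp(thermo_theta[seq_len(s)]))
  m <- exp(thermo_theta[s + seq_len(s)])
  dG <- m * Dmid
  fr <- .seq_fractions(stack$D, dG, m, RT)
  res <- numeric(length(stack$D))
  beta <- if (return_beta)
    matrix(0, n_states + if (end_slopes) 2L else 0L, n_curves)
  for (i in seq_len(n_curves)) {
    rows <- stack$idx == i
    X <- .profile_design(fr[rows, , drop = FALSE], stack$D[rows],
                         n_states, end_slopes)
    y <- stack$y[rows]
    if (!is.null(stack$sqrt_w)) {
      X <- X * stack$sqrt_w[rows]
      y <- y * stack$sqrt_w[rows]
    }
    fit <- stats::lm.fit(X, y)
    res[rows] <- fit$residuals
    if (return_beta) {
      b <- fit$coefficients
      b[is.na(b)] <- 0
      beta[, i] <- b
    }
  }
  if (return_beta) list(residuals = res, beta = beta) else res
}

# data-driven heuristic start for one curve
.heuristic_start <- function(curves, n_states, RT) {
  D <- unlist(lapply(curves, `[[`, "concentrations_M"))
  y <- unlist(lapply(curves, `[[`, "values"))
  # pool replicate curves: average the signal at duplicated concentrations
  y <- as.numeric(tapply(y, D, mean))
  D <- sort(unique(D))
  nq <- max(2L, ceiling(length(y) / 4))
  y_lo <- mean(utils::head(y, nq)); y_hi <- mean(utils::tail(y, nq))
  span <- max(D) - min(D)
  dy <- diff(y) / pmax(diff(D), 1e-9)
  mid_peak <- (D[-1] + D[-length(D)])[which.max(abs(dy))] / 2
  s <- n_states - 1L
  if (s == 1L) {
    Dmid <- max(mid_peak, 0.05 * span, 0.01)
    m0 <- 4 * RT * max(abs(dy)) / max(abs(y_hi - y_lo), 1e-9)
    m0 <- min(max(m0, 0.3), 10)
    sig <- seq(y_lo, y_hi, length.out = n_states)
    return(list(Dmid = Dmid, m = m0, sig = sig))
  }
  # several transitions: spread midpoints over the span
  Dmid <- min(D) + span * seq(0.2, 0.8, length.out = s)
  Dmid <- pmax(Dmid, 0.01)
  # state signals: ends from the data, intermediates interpolated at the
  # plateaus between consecutive midpoints
  plateau_D <- c(min(D), (Dmid[-s] + Dmid[-1]) / 2, max(D))
  sig <- stats::approx(D, y, xout = plateau_D, rule = 2, ties = mean)$y
  sig[1] <- y_lo; sig[length(sig)] <- y_hi
  list(Dmid = Dmid, m = rep(2, s), sig = sig)
}

# multi-start list of thermodynamic parameter vectors (u = log midpoint
# increments, v = log m); signals are profiled out, so starts only need
# to cover the thermodynamic space
.make_starts <- function(curves, n_states, RT, opts) {
  h <- .heuristic_start(curves, n_states, RT)
  s <- n_states - 1L
  to_theta <- function(Dmid, m)
    c(log(c(Dmid[1], diff(Dmid))), log(m))
  starts <- list(to_theta(h$Dmid, h$m))
  if (opts$n_starts > 1L) {
    extra <- .with_seed(opts$seed, lapply(seq_len(opts$n_starts - 1L), function(j) {
      Dmid <- sort(h$Dmid * exp(stats::rnorm(s, 0, 0.35)))
      Dmid <- Dmid + seq(0, 0.02 * s, length.out = s) # keep increments > 0
      m <- pmin(pmax(h$m * exp(stats::rnorm(s, 0, 0.4)), 0.05), 20)
      to_theta(Dmid, m)
    }))
    starts <- c(starts, extra)
  }
  starts
}

# central-difference Jacobian of a vector function
.num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

.pinv <- function(A, tol = 1e-12) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# natural-parameter names for reporting
.natural_names <- function(n_states, n_curves, end_slopes) {
  thermo <- switch(as.character(n_states),
    "2" = c("dG0", "m"),
    "3" = c("dG1", "dG2", "m1", "m2"),
    "4" = c("dG1", "dG2", "dG3", "m1", "m2", "m3"))
  signal <- switch(as.character(n_states),
    "2" = c("yn", "yu", if (end_slopes) c("mf", "mu")),
    "3" = c("yN", "yI", "yU", if (end_slopes) c("sN", "sU")),
    "4" = c("yN", "yI1", "yI2", "yU", if (end_slopes) c("sN", "sU")))
  if (n_curves == 1L) c(thermo, signal)
  else c(thermo, unlist(lapply(seq_len(n_curves),
                               function(i) paste0(signal, ".", i))))
}

# theta (transformed) -> natural parameter vector
.theta_to_natural <- function(theta, n_states, n_curves, end_slopes) {
  p <- .theta_unpack(theta, n_states, n_curves, end_slopes)
  sig <- unlist(lapply(p$sig, function(b)
    c(b$y, if (end_slopes) c(b$s_first, b$s_last))))
  stats::setNames(c(p$dG, p$m, sig),
                  .natural_names(n_states, n_curves, end_slopes))
}

.transition_names <- function(n_states) {
  switch(as.character(n_states),
    "2" = "N-U", "3" = c("N-I", "I-U"), "4" = c("N-I1", "I1-I2", "I2-U"))
}

# the shared fitting engine
.fit_sequential <- function(curves, n_states, k, opts, end_slopes,
                            min_points) {
  curves <- .as_curve_list(curves)
  .check_identifiable(curves, min_points)
  RT <- k$RT
  weights <- opts$weights
  if (!is.null(weights) && !is.list(weights)) weights <- list(weights)
  stack <- .stack_curves(curves, weights, isTRUE(opts$share_signals))
  n_groups <- stack$n_groups
  starts <- .make_starts(curves, n_states, RT, opts)
  best <- NULL
  n_used <- 0L
  for (th0 in starts) {
    n_used <- n_used + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = .profile_residuals, stack = stack,
                         n_states = n_states, n_curves = n_groups,
                         end_slopes = end_slopes, RT = RT,
                         control = minpack.lm::nls.lm.control(
                           maxiter = opts$maxiter, ftol = opts$ftol,
                           ptol = opts$ptol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("did not converge: no start produced a finite fit")
  # recover the profiled signal parameters at the optimum and assemble the
  # full parameter vector
  prof <- .profile_residuals(best$par, stack, n_states, n_groups,
                             end_slopes, RT, return_beta = TRUE)
  theta <- c(best$par, as.numeric(prof$beta))
  est <- .theta_to_natural(theta, n_states, n_groups, end_slopes)
  # covariance of the natural parameters via finite-difference Jacobian of
  # the residuals with respect to the natural parameterisation
  resid <- .seq_residuals(theta, stack, n_states, n_groups, end_slopes, RT)
  n_obs <- length(resid)
  n_par <- length(theta)
  dof <- max(n_obs - n_par, 1L)
  sigma2 <- best$deviance / dof
  nat_resid <- function(x) {
    th <- .natural_to_theta(x, n_states, n_groups, end_slopes)
    .seq_residuals(th, stack, n_states, n_groups, end_slopes, RT)
  }
  J <- tryCatch(.num_jacobian(nat_resid, est), error = function(e) NULL)
  if (!is.null(J)) {
    covmat <- sigma2 * .pinv(crossprod(J))
    se <- sqrt(pmax(diag(covmat), 0))
    names(se) <- names(est)
    dimnames(covmat) <- list(names(est), names(est))
  } else {
    covmat <- NULL
    se <- rep(NA_real_, length(est))
  }
  s <- n_states - 1L
  dG <- est[seq_len(s)]
  m <- est[s + seq_len(s)]
  mids <- stats::setNames(unname(dG / m), .transition_names(n_states))
  converged <- best$info %in% 1:3
  if (!converged)
    warning("did not converge: Levenberg-Marquardt stopped without meeting tolerance")
  n_param_tot <- n_par + 1L # + residual variance
  aicc <- if (n_obs - n_param_tot - 1L > 0)
    n_obs * log(best$deviance / n_obs) + 2 * n_param_tot +
      2 * n_param_tot * (n_param_tot + 1) / (n_obs - n_param_tot - 1)
  else Inf
  structure(list(model = paste0(n_states, "_state"),
                 n_states = n_states,
                 estimates = est,
                 standard_errors = se,
                 covariance = covmat,
                 residuals = resid,
                 rss = best$deviance,
                 n_obs = n_obs, n_param = n_par,
                 aicc = aicc,
                 converged = converged,
                 midpoints_M = mids,
                 n_starts_used = n_used,
                 n_curves = length(curves),
                 end_slopes = end_slopes,
                 seed = opts$seed),
            class = "unfold_fit")
}

# natural params -> transformed theta (inverse of .theta_to_natural)
.natural_to_theta <- function(nat, n_states, n_curves, end_slopes) {
  s <- n_states - 1L
  dG <- nat[seq_len(s)]
  m <- nat[s + seq_len(s)]
  Dmid <- dG / m
  u <- log(pmax(c(Dmid[1], diff(Dmid)), 1e-12))
  v <- log(pmax(m, 1e-12))
  c(u, v, nat[-seq_len(2L * s)])
}

#' @export
print.unfold_fit <- function(x, ...) {
  cat(sprintf("%s unfolding fit: %d curve(s), %d points, RSS %.4g%s\n",
              x$model, x$n_curves, x$n_obs, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  s <- x$n_states - 1L
  est <- x$estimates; se <- x$standard_errors
  for (i in seq_len(s))
    cat(sprintf("  %-6s dG = %6.2f +/- %.2f kcal/mol, m = %5.2f +/- %.2f, D1/2 = %.2f M\n",
                names(x$midpoints_M)[i], est[i], se[i], est[s + i], se[s + i],
                x$midpoints_M[i]))
  if (!is.null(x$flags) && length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the two-state unfolding model
#'
#' Least-squares fit of the Santoro-Bolen two-state linear-extrapolation
#' model to one or more denaturation curves. When several curves are
#' given the thermodynamic parameters (`dG0`, `m`) are shared across
#' curves and the signal baselines (`yn`, `yu`, `mf`, `mu`) are fitted per
#' curve (a global fit). The optimisation is a trust-region
#' Levenberg-Marquardt run from multiple data-driven starts; `m` is kept
#' positive by a log parameterisation.
#'
#' @param curves a [denaturation_curve()] or list of them, each with at
#'   least 6 points spanning the transition.
#' @param k a [thermo_constants()] object.
#' @param opts a [fit_options()] object.
#' @return An object of class `unfold_fit` with elements `estimates`
#'   (named natural parameters), `standard_errors`, `covariance`,
#'   `residuals`, `converged`, `midpoints_M` (`dG0/m`), `rss`, `aicc` and
#'   `n_starts_used`.
#' @examples
#' truth <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
#' cu <- denaturation_curve(seq(0, 4, 0.25),
#'                          eval_two_state(truth, seq(0, 4, 0.25)))
#' fit <- fit_two_state(cu)
#' fit$midpoints_M
#' @export
fit_two_state <- function(curves, k = thermo_constants(),
                          opts = fit_options()) {
  .fit_sequential(curves, 2L, k, opts, end_slopes = TRUE, min_points = 6L)
}

#' Fit the sequential four-state unfolding model
#'
#' Global least-squares fit of the four-state model N <-> I1 <-> I2 <-> U.
#' The transition ordering `dG1/m1 < dG2/m2 < dG3/m3` is enforced during
#' optimisation by parameterising the fit in the first midpoint and
#' positive midpoint increments; m-values are kept positive by a log
#' transform. Intermediate state signals are flat; set
#' `opts$end_slopes = TRUE` to free baseline slopes on N and U.
#'
#' Fits of data that do not support two intermediates are flagged: when
#' two adjacent state signals or midpoints collapse onto each other the
#' result carries a `"degenerate intermediate"` flag in `$flags`.
#'
#' @inheritParams fit_two_state
#' @param curves curves with at least 12 points spanning all three
#'   transitions.
#' @return An `unfold_fit`; `total_dG` holds `dG1 + dG2 + dG3`.
#' @export
fit_four_state <- function(curves, k = thermo_constants(),
                           opts = fit_options()) {
  fit <- .fit_sequential(curves, 4L, k, opts,
                         end_slopes = opts$end_slopes, min_points = 12L)
  fit$total_dG <- sum(fit$estimates[1:3])
  fit$flags <- .degeneracy_flags(fit)
  fit
}

# flag intermediate states that the data did not resolve
.degeneracy_flags <- function(fit) {
  n <- fit$n_states
  s <- n - 1L
  sig <- fit$estimates[2L * s + seq_len(n)]
  span <- max(abs(diff(range(sig))), 1e-12)
  flags <- character(0)
  if (any(abs(diff(sig)) < 0.02 * span))
    flags <- c(flags, "degenerate intermediate: adjacent state signals collapse")
  mids <- fit$midpoints_M
  dspan <- max(mids) - min(0, min(mids))
  if (any(diff(mids) < 0.02 * max(dspan, 1e-12)))
    flags <- c(flags, "degenerate intermediate: adjacent midpoints collapse")
  flags
}

#' Choose the number of unfolding states by information criterion
#'
#' Fits two-, three- and four-state sequential variants to a curve and
#' selects the state count with the lowest corrected Akaike criterion
#' (AICc); exact ties go to the model with fewer states. An F-test of each
#' model against the next-simpler nested variant is reported alongside.
#'
#' @param curve a [denaturation_curve()].
#' @param k a [thermo_constants()] object.
#' @param opts a [fit_options()] object.
#' @return A list with `selected` (`"2_state"`, `"3_state"` or
#'   `"4_state"`), `n_states`, `fits` (the successful fits), and `table`
#'   (data frame of per-model RSS, AICc and F-test p-values).
#' @export
model_select <- function(curve, k = thermo_constants(),
                         opts = fit_options()) {
  candidates <- list(
    `2_state` = function() .fit_sequential(curve, 2L, k, opts,
                                           end_slopes = TRUE, min_points = 6L),
    `3_state` = function() .fit_sequential(curve, 3L, k, opts,
                                           end_slopes = FALSE, min_points = 9L),
    `4_state` = function() .fit_sequential(curve, 4L, k, opts,
                                           end_slopes = FALSE, min_points = 12L))
  fits <- list()
  errors <- character(0)
  for (nm in names(candidates)) {
    f <- tryCatch(candidates[[nm]](), error = function(e) e)
    if (inherits(f, "error")) errors[nm] <- conditionMessage(f)
    else fits[[nm]] <- f
  }
  if (length(fits) == 0L)
    stop("no model fits: ", paste(errors, collapse = "; "))
  tab <- data.frame(
    model = names(fits),
    n_states = vapply(fits, `[[`, 0L, "n_states"),
    n_param = vapply(fits, `[[`, 0L, "n_param"),
    rss = vapply(fits, `[[`, 0, "rss"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    row.names = NULL)
  # F-test against the next-simpler successful model
  tab$f_p_vs_simpler <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (i == 1L) next
    rss_s <- tab$rss[i - 1L]; p_s <- tab$n_param[i - 1L]
    rss_c <- tab$rss[i]; p_c <- tab$n_param[i]
    n <- fits[[i]]$n_obs
    if (p_c > p_s && n > p_c && rss_c > 0) {
      Fstat <- ((rss_s - rss_c) / (p_c - p_s)) / (rss_c / (n - p_c))
      tab$f_p_vs_simpler[i] <- stats::pf(Fstat, p_c - p_s, n - p_c,
                                         lower.tail = FALSE)
    }
  }
  # lowest AICc; exact ties break to fewer states (rows are ordered by
  # increasing state count already)
  sel <- which.min(tab$aicc)
  list(selected = tab$model[sel], n_states = tab$n_states[sel],
       fits = fits, table = tab, errors = errors)
}

#' Extract fitted parameters as a parameter object
#'
#' Converts a single-curve `unfold_fit` into the matching
#' [two_state_params()] or [four_state_params()] object, convenient for
#' evaluating the fitted model or computing populations.
#'
#' @param fit an `unfold_fit` from a single-curve fit.
#' @param curve which curve's signal block to use (for global fits).
#' @return A `two_state_params` or `four_state_params` object.
#' @export
fitted_params <- function(fit, curve = 1L) {
  stopifnot(inherits(fit, "unfold_fit"))
  s <- fit$n_states - 1L
  per <- fit$n_states + if (fit$end_slopes) 2L else 0L
  block <- fit$estimates[2L * s + (curve - 1L) * per + seq_len(per)]
  e <- fit$estimates
  if (fit$n_states == 2L) {
    two_state_params(e[["dG0"]], e[["m"]], block[[1]], block[[2]],
                     if (fit$end_slopes) block[[3]] else 0,
                     if (fit$end_slopes) block[[4]] else 0)
  } else if (fit$n_states == 4L) {
    four_state_params(e[["dG1"]], e[["dG2"]], e[["dG3"]],
                      e[["m1"]], e[["m2"]], e[["m3"]],
                      block[[1]], block[[2]], block[[3]], block[[4]],
                      if (fit$end_slopes) block[[5]] else 0,
                      if (fit$end_slopes) block[[6]] else 0)
  } else stop("no parameter class for a ", fit$model, " fit")
}
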