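# Synthetic-data generators. Every input the analysis modules consume can
# be produced here with known ground truth embedded in the output, so
# parameter recovery is testable end to end. All generators are
# deterministic given their seed; replicate i of a config draws its noise
# after set.seed(seed + i - 1), so a config with seed 1 and 50 replicates
# reproduces a "seeds 1..50" protocol.

#' Configuration for the unfolding-curve generator
#'
#' @param model `"two_state"` or `"four_state"`.
#' @param true_params matching [two_state_params()] or
#'   [four_state_params()] ground truth.
#' @param grid_M denaturant concentrations, ascending, mol/L.
#' @param noise_sigma standard deviation of i.i.d. Gaussian noise added to
#'   the observable (same units as the observable, e.g. nm for AEW).
#' @param n_replicates number of replicate curves.
#' @param seed integer master seed; replicate i uses `seed + i - 1`.
#' @param denaturant,observable,direction curve metadata, passed through to
#'   [denaturation_curve()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(model = c("two_state", "four_state"),
                             true_params, grid_M, noise_sigma = 0,
                             n_replicates = 1L, seed = 1L,
                             denaturant = c("urea", "GdmCl"),
                             observable = "aew",
                             direction = "unfolding") {
  model <- match.arg(model)
  cls <- switch(model, two_state = "two_state_params",
                four_state = "four_state_params")
  if (!inherits(true_params, cls))
    stop("true_params must be a ", cls, " object for model ", model)
  grid_M <- as.numeric(grid_M)
  if (any(diff(grid_M) <= 0)) stop("grid must be ascending")
  if (any(grid_M < 0)) stop("grid must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(model = model, true_params = true_params, grid_M = grid_M,
                 noise_sigma = noise_sigma,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 denaturant = match.arg(denaturant),
                 observable = observable, direction = direction),
            class = "generator_config")
}

.eval_config_model <- function(cfg, D, k) {
  switch(cfg$model,
         two_state = eval_two_state(cfg$true_params, D, k),
         four_state = eval_four_state(cfg$true_params, D, k))
}

#' Generate synthetic denaturation curves with known truth
#'
#' Evaluates the configured unfolding model on the concentration grid and
#' adds i.i.d. Gaussian noise. The complete ground truth (parameters,
#' noise level, seed) is attached to each curve as the `"truth"`
#' attribute.
#'
#' @param cfg a [generator_config()].
#' @param k a [thermo_constants()] object.
#' @return A list of [denaturation_curve()] objects of length
#'   `cfg$n_replicates`.
#' @examples
#' cfg <- generator_config("two_state",
#'                         two_state_params(6.5, 3.8, 350, 355),
#'                         grid_M = seq(0, 4, 0.25), noise_sigma = 0.2,
#'                         n_replicates = 3, seed = 1)
#' curves <- gen_unfolding_curve(cfg)
#' @export
gen_unfolding_curve <- function(cfg, k = thermo_constants()) {
  stopifnot(inherits(cfg, "generator_config"))
  clean <- .eval_config_model(cfg, cfg$grid_M, k)
  lapply(seq_len(cfg$n_replicates), function(i) {
    noise <- if (cfg$noise_sigma > 0)
      .with_seed(cfg$seed + i - 1L,
                 stats::rnorm(length(clean), 0, cfg$noise_sigma))
    else 0
    cu <- denaturation_curve(cfg$grid_M, clean + noise,
                             observable = cfg$observable,
                             denaturant = cfg$denaturant,
                             direction = cfg$direction,
                             protein_label = sprintf("synthetic rep %d", i))
    attr(cu, "truth") <- list(model = cfg$model, params = cfg$true_params,
                              noise_sigma = cfg$noise_sigma,
                              seed = cfg$seed + i - 1L)
    cu
  })
}

#' Generate per-condition tryptophan emission spectra
#'
#' For each denaturant concentration the equilibrium state populations of
#' the configured model are computed and a mixture spectrum is built: each
#' state contributes a Gaussian emission band whose center interpolates
#' from the native to the unfolded peak position (default 335 to 355 nm,
#' the typical buried-to-exposed tryptophan red shift), weighted by its
#' population and amplitude. At zero noise the AEW of each spectrum
#' reproduces the population-weighted mean of the state centers up to the
#' tiny truncation of the Gaussian tails by the recording window.
#'
#' @param cfg a [generator_config()].
#' @param centers_nm per-state band centers; default interpolates
#'   335-355 nm across the model's states.
#' @param amplitudes per-state band amplitudes, default 1.
#' @param sigma_nm Gaussian band width (s.d.), nm.
#' @param wavelengths recording grid, nm. The wide default keeps window
#'   truncation of the band tails negligible.
#' @param intensity_sd optional Gaussian noise on the intensities.
#' @param k a [thermo_constants()] object.
#' @return List of [emission_spectrum()] objects, one per grid
#'   concentration, each carrying the target AEW in its `"truth"`
#'   attribute.
#' @export
gen_emission_spectra <- function(cfg, centers_nm = NULL, amplitudes = NULL,
                                 sigma_nm = 15,
                                 wavelengths = seq(300, 420, by = 0.5),
                                 intensity_sd = 0,
                                 k = thermo_constants()) {
  stopifnot(inherits(cfg, "generator_config"))
  n_states <- switch(cfg$model, two_state = 2L, four_state = 4L)
  if (is.null(centers_nm))
    centers_nm <- seq(335, 355, length.out = n_states)
  if (is.null(amplitudes)) amplitudes <- rep(1, n_states)
  stopifnot(length(centers_nm) == n_states, length(amplitudes) == n_states)
  frac <- if (cfg$model == "two_state") {
    fu <- stats::plogis(-(cfg$true_params$dG0 - cfg$true_params$m * cfg$grid_M) / k$RT)
    cbind(1 - fu, fu)
  } else {
    state_fractions(cfg$true_params, cfg$grid_M, k)
  }
  lapply(seq_along(cfg$grid_M), function(j) {
    w <- frac[j, ] * amplitudes
    inten <- rowSums(vapply(seq_len(n_states), function(s)
      w[s] * stats::dnorm(wavelengths, centers_nm[s], sigma_nm),
      numeric(length(wavelengths))))
    if (intensity_sd > 0)
      inten <- inten + .with_seed(cfg$seed + j - 1L,
        stats::rnorm(length(inten), 0, intensity_sd))
    sp <- emission_spectrum(wavelengths, inten, probe = "trp",
                            condition = list(denaturant = cfg$denaturant,
                                             conc_M = cfg$grid_M[j]))
    attr(sp, "truth") <- list(fractions = frac[j, ],
                              target_aew = sum(w * centers_nm) / sum(w),
                              centers_nm = centers_nm)
    sp
  })
}

#' Generate a synthetic aggregation trace
#'
#' Evaluates `y(t) = y0 + sum_i amplitudes[i] * (1 - exp(-rates[i] t))`
#' on a time grid and adds Gaussian noise; the ground truth travels in the
#' `"truth"` attribute.
#'
#' @param rates phase rate constants, 1/min, all positive.
#' @param amplitudes phase amplitudes (asymptotic increments).
#' @param y_offset signal at time zero.
#' @param sigma Gaussian noise s.d. (signal units).
#' @param seed integer seed.
#' @param times_min time grid, minutes.
#' @param condition free-text label.
#' @return An [aggregation_trace()].
#' @export
gen_aggregation_trace <- function(rates, amplitudes, y_offset = 0,
                                  sigma = 0, seed = 1L,
                                  times_min = seq(0, 30, by = 0.5),
                                  condition = "synthetic") {
  stopifnot(length(rates) == length(amplitudes))
  if (any(rates <= 0)) stop("rates must be positive")
  clean <- .agg_model(times_min, y_offset, amplitudes, rates)
  noise <- if (sigma > 0)
    .with_seed(seed, stats::rnorm(length(clean), 0, sigma)) else 0
  tr <- aggregation_trace(times_min, clean + noise, condition = condition)
  attr(tr, "truth") <- list(rates = rates, amplitudes = amplitudes,
                            y_offset = y_offset, sigma = sigma, seed = seed)
  tr
}

#' Generate a toy tetramer structure
#'
#' Builds a minimal four-chain (A, B, C, D) model of a double-dimer
#' tetramer with marker residues at the three kinds of subunit interface:
#' residues 237/182 face the primary-dimer partner (A-C and B-D), 302/330
#' the secondary partner (A-D and B-C), and residue 315 faces the diagonal
#' partner (A-B and C-D) so the two 315 C-alphas sit exactly
#' `diagonal_gap_A` apart. Each marker residue also carries backbone N and
#' O atoms, and residue 315 a side-chain NZ, so polar-contact analysis has
#' donors/acceptors to find. With `contact_pair = TRUE` the A:315 NZ and
#' B:313 O atoms are placed `contact_distance_A` apart, emulating the
#' lysine hydrogen bond across the diagonal interface.
#'
#' @param chain_sep_A centroid separation of adjacent chains, Angstrom.
#' @param primary_gap_A C-alpha gap of the 237-182 pair across the primary
#'   interface.
#' @param secondary_gap_A C-alpha gap of the 302-330 pair.
#' @param diagonal_gap_A C-alpha gap of the 315-315 diagonal pair.
#' @param contact_pair logical; add the NZ...O=C contact fixture.
#' @param contact_distance_A NZ-O distance for the contact fixture.
#' @return A `structure_model` with four chains.
#' @export
gen_toy_tetramer <- function(chain_sep_A = 30, primary_gap_A = 6,
                             secondary_gap_A = 6, diagonal_gap_A = 10,
                             contact_pair = FALSE,
                             contact_distance_A = 2.9) {
  s <- chain_sep_A
  cent <- list(A = c(0, 0, 0), C = c(s, 0, 0), D = c(0, s, 0), B = c(s, s, 0))
  rows <- list()
  add <- function(chain, resno, resid, elety, elesy, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = elety, elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  add_residue <- function(chain, resno, resid, ca) {
    add(chain, resno, resid, "CA", "C", ca)
    add(chain, resno, resid, "N", "N", ca + c(-0.7, 0.7, 0.5))
    add(chain, resno, resid, "O", "O", ca + c(0.7, -0.7, 0.5))
  }
  # place the two residues of an interface pair on the segment between the
  # chain centroids, gap apart and centred on the interface midpoint
  place_pair <- function(ch1, res1, name1, ch2, res2, name2, gap, z_off = 0) {
    p1 <- cent[[ch1]]; p2 <- cent[[ch2]]
    mid <- (p1 + p2) / 2 + c(0, 0, z_off)
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    add_residue(ch1, res1, name1, mid - u * gap / 2)
    add_residue(ch2, res2, name2, mid + u * gap / 2)
  }
  pairings <- list(
    list(res = c(237L, 182L), names = c("ASP", "ARG"),
         gap = primary_gap_A, chains = list(c("A", "C"), c("B", "D"))),
    list(res = c(302L, 330L), names = c("ARG", "GLU"),
         gap = secondary_gap_A, chains = list(c("A", "D"), c("B", "C"))))
  for (p in pairings)
    for (ch in p$chains) {
      place_pair(ch[1], p$res[1], p$names[1], ch[2], p$res[2], p$names[2],
                 p$gap)
      # the reciprocal copies of the homotetramer, offset in z so they
      # neither clash with nor sit in contact range of the first copy
      place_pair(ch[2], p$res[1], p$names[1], ch[1], p$res[2], p$names[2],
                 p$gap, z_off = 8)
    }
  for (ch in list(c("A", "B"), c("C", "D"))) {
    p1 <- cent[[ch[1]]]; p2 <- cent[[ch[2]]]
    mid <- (p1 + p2) / 2
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    ca1 <- mid - u * diagonal_gap_A / 2
    ca2 <- mid + u * diagonal_gap_A / 2
    add_residue(ch[1], 315L, "LYS", ca1)
    add(ch[1], 315L, "LYS", "NZ", "N", ca1 + c(0, 0, 1.5))
    add_residue(ch[2], 315L, "LYS", ca2)
    add(ch[2], 315L, "LYS", "NZ", "N", ca2 + c(0, 0, 1.5))
  }
  atoms <- do.call(rbind, rows)
  if (contact_pair) {
    nz <- atoms$chain == "A" & atoms$resno == 315L & atoms$elety == "NZ"
    pos <- as.numeric(atoms[nz, c("x", "y", "z")]) +
      c(0, 0, contact_distance_A)
    extra <- data.frame(chain = "B", resno = 313L, insert = "",
                        resid = "VAL", elety = "O", elesy = "O",
                        x = pos[1], y = pos[2], z = pos[3],
                        stringsAsFactors = FALSE)
    atoms <- rbind(atoms, extra)
  }
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$elety), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = "toy tetramer"),
            class = "structure_model")
}

#' Generate a trajectory of rigid chain translations
#'
#' Starting from a base structure, each chain is translated linearly at
#' its own velocity, with optional Gaussian coordinate jitter, emulating
#' subunit separation in a dissociation trajectory. With zero jitter the
#' distance between atoms of two chains moving apart along their
#' separation axis grows exactly linearly.
#'
#' @param base a `structure_model` (e.g. [gen_toy_tetramer()]).
#' @param velocities named list of per-chain velocity 3-vectors in
#'   Angstrom/ps; chains not listed stay fixed.
#' @param n_frames number of frames.
#' @param dt_ps frame spacing, ps.
#' @param jitter Gaussian s.d. of per-coordinate jitter, Angstrom.
#' @param seed integer seed for the jitter.
#' @return A `fold_trajectory` with the truth (velocities, jitter, seed)
#'   in its `"truth"` attribute.
#' @export
gen_trajectory <- function(base, velocities = list(), n_frames = 101,
                           dt_ps = 1, jitter = 0, seed = 1L) {
  stopifnot(inherits(base, "structure_model"))
  for (v in velocities)
    if (length(v) != 3L || any(!is.finite(v)))
      stop("each velocity must be a finite 3-vector")
  xyz0 <- as.matrix(base$atoms[c("x", "y", "z")])
  times <- (seq_len(n_frames) - 1) * dt_ps
  coords <- array(0, c(n_frames, nrow(xyz0), 3))
  vmat <- matrix(0, nrow(xyz0), 3)
  for (ch in names(velocities))
    vmat[base$atoms$chain == ch, ] <-
      matrix(velocities[[ch]], sum(base$atoms$chain == ch), 3, byrow = TRUE)
  noise <- if (jitter > 0)
    .with_seed(seed, array(stats::rnorm(length(coords), 0, jitter),
                           dim(coords)))
  else 0
  for (f in seq_len(n_frames))
    coords[f, , ] <- xyz0 + vmat * times[f]
  coords <- coords + noise
  traj <- structure(list(atoms = base$atoms[c("chain", "resno", "insert",
                                              "resid", "elety", "elesy")],
                         coords = coords, times_ps = times,
                         label = base$label),
                    class = "fold_trajectory")
  attr(traj, "truth") <- list(velocities = velocities, jitter = jitter,
                              seed = seed, dt_ps = dt_ps)
  traj
}
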