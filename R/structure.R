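# Structure and trajectory geometry: PDB parsing (via bio3d), residue-pair
# C-alpha distance tracking across frames, linear separation rates and
# cross-chain polar contact listings.

#' Parse a PDB structure
#'
#' Reads ATOM/HETATM records from a PDB file (or a character vector of PDB
#' lines) into an atom table. Coordinate fields are validated line by line
#' before parsing so malformed input is reported with its line number.
#' Insertion codes are preserved as part of residue identity. For
#' multi-MODEL files the first model is returned; use
#' [parse_trajectory()] for all frames.
#'
#' @param x path to a PDB file, or a character vector of PDB-format lines.
#' @param label free-text label stored with the model.
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame with columns `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`) and `label`.
#' @export
parse_structure <- function(x, label = "") {
  pdb <- .read_pdb_checked(x, multi = FALSE)
  .structure_from_bio3d(pdb, label = label)
}

.read_pdb_checked <- function(x, multi = FALSE) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    path <- x
  } else {
    lines <- if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records")
  for (i in which(is_atom)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (any(is.na(coords)))
      stop(sprintf("parse error at line %d: malformed coordinate field", i))
  }
  bio3d::read.pdb(path, multi = multi, verbose = FALSE)
}

.structure_from_bio3d <- function(pdb, model = 1L, label = "") {
  a <- pdb$atom
  xyz <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) >= model)
    matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  else cbind(a$x, a$y, a$z)
  elesy <- a$elesy
  # element symbol column is optional in PDB; fall back to the first
  # letter of the atom name
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[miss] <- substr(gsub("[^A-Za-z].*$", "",
                             gsub("^[0-9]*", "", a$elety[miss])), 1, 1)
  atoms <- data.frame(chain = a$chain, resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid, elety = a$elety,
                      elesy = toupper(trimws(elesy)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) identity in model")
  structure(list(atoms = atoms, label = label), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, chains %s%s\n",
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ""),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Parse trajectory frames from PDB input
#'
#' Accepts either one multi-MODEL PDB file or an ordered vector of
#' single-frame PDB files. All frames must share the same atom roster.
#' Frame times default to the frame index (0, 1, 2, ... in the supplied
#' time unit) when not given.
#'
#' @param x path to a multi-MODEL PDB file, or a character vector of paths
#'   to single-frame files in frame order.
#' @param times_ps optional numeric vector of frame times in ps,
#'   increasing, one per frame.
#' @param label free-text label.
#' @return An object of class `fold_trajectory`: `atoms` (shared roster),
#'   `coords` (frames x atoms x 3 array, Angstrom) and `times_ps`.
#' @export
parse_trajectory <- function(x, times_ps = NULL, label = "") {
  if (length(x) == 1L) {
    pdb <- .read_pdb_checked(x, multi = TRUE)
    n_frames <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    models <- lapply(seq_len(n_frames), function(i)
      .structure_from_bio3d(pdb, model = i, label = label))
  } else {
    models <- lapply(x, parse_structure, label = label)
  }
  trajectory_from_models(models, times_ps = times_ps, label = label)
}

#' Build a trajectory from in-memory structure models
#'
#' @param models list of [parse_structure()] models with identical atom
#'   rosters, in frame order.
#' @param times_ps optional frame times (ps); defaults to 0, 1, 2, ...
#' @param label free-text label.
#' @return A `fold_trajectory`.
#' @export
trajectory_from_models <- function(models, times_ps = NULL, label = "") {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "structure_model")))
  ref <- models[[1]]$atoms
  ref_key <- paste(ref$chain, ref$resno, ref$insert, ref$elety)
  for (i in seq_along(models)) {
    key <- with(models[[i]]$atoms, paste(chain, resno, insert, elety))
    if (length(key) != length(ref_key) || any(key != ref_key))
      stop(sprintf("frame %d does not share the atom roster of frame 1", i))
  }
  coords <- array(NA_real_, c(length(models), nrow(ref), 3))
  for (i in seq_along(models))
    coords[i, , ] <- as.matrix(models[[i]]$atoms[c("x", "y", "z")])
  if (is.null(times_ps)) times_ps <- seq_along(models) - 1
  times_ps <- as.numeric(times_ps)
  if (length(times_ps) != length(models))
    stop("one time per frame required")
  if (any(diff(times_ps) <= 0)) stop("frame times must be increasing")
  structure(list(atoms = ref[c("chain", "resno", "insert", "resid",
                               "elety", "elesy")],
                 coords = coords, times_ps = times_ps, label = label),
            class = "fold_trajectory")
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat(sprintf("fold_trajectory: %d frames x %d atoms, %.3g-%.3g ps\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times_ps), max(x$times_ps)))
  invisible(x)
}

#' Define a residue pair to track
#'
#' @param chain_a,resno_a,chain_b,resno_b chain identifiers and residue
#'   numbers of the two partners.
#' @param atom atom name used for the distance, default `"CA"`.
#' @return A `residue_pair` object. The character form `"A:237-C:182"` is
#'   accepted wherever a pair is expected.
#' @export
residue_pair <- function(chain_a, resno_a, chain_b, resno_b, atom = "CA") {
  structure(list(a = list(chain = as.character(chain_a),
                          resno = as.integer(resno_a)),
                 b = list(chain = as.character(chain_b),
                          resno = as.integer(resno_b)),
                 atom = atom),
            class = "residue_pair")
}

.as_pair <- function(p) {
  if (inherits(p, "residue_pair")) return(p)
  if (is.character(p) && length(p) == 1L) {
    m <- regmatches(p, regexec("^([A-Za-z0-9]+):([0-9]+)-([A-Za-z0-9]+):([0-9]+)$", p))[[1]]
    if (length(m) != 5L) stop("cannot parse residue pair spec: ", p)
    return(residue_pair(m[2], m[3], m[4], m[5]))
  }
  stop("unsupported residue pair specification")
}

.pair_label <- function(p) {
  sprintf("%s:%d-%s:%d", p$a$chain, p$a$resno, p$b$chain, p$b$resno)
}

.atom_index <- function(atoms, chain, resno, atom_name) {
  idx <- which(atoms$chain == chain & atoms$resno == resno &
               atoms$elety == atom_name)
  if (length(idx) == 0L)
    stop(sprintf("atom not found: %s %s:%d", atom_name, chain, resno))
  idx[1]
}

#' Distance between two residues' atoms in one model
#'
#' Euclidean distance in Angstrom between the named atom (default CA) of
#' two residues. Symmetric and invariant under rigid-body motion of the
#' whole model.
#'
#' @param model a [parse_structure()] model.
#' @param pair a [residue_pair()] or string `"A:315-B:315"`.
#' @param atom_name atom name; overrides the pair's atom when given.
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(model, pair, atom_name = NULL) {
  stopifnot(inherits(model, "structure_model"))
  pair <- .as_pair(pair)
  atom_name <- atom_name %||% pair$atom
  ia <- .atom_index(model$atoms, pair$a$chain, pair$a$resno, atom_name)
  ib <- .atom_index(model$atoms, pair$b$chain, pair$b$resno, atom_name)
  sqrt(sum((as.numeric(model$atoms[ia, c("x", "y", "z")]) -
            as.numeric(model$atoms[ib, c("x", "y", "z")]))^2))
}

#' Track residue-pair distances along a trajectory
#'
#' Measures the per-frame distance between the tracked atoms of each pair
#' and fits a least-squares line of distance versus time, whose slope is
#' the subunit separation rate. The fit window defaults to the whole
#' trajectory and can be restricted to any time interval (useful when a
#' pair only starts separating late in the run).
#'
#' @param traj a [parse_trajectory()] / [trajectory_from_models()] object.
#' @param pairs list of [residue_pair()] objects or strings.
#' @param atom_name atom used for all pairs (default each pair's own,
#'   normally CA).
#' @param window optional `c(t_min, t_max)` in ps restricting the rate fit.
#' @return A list of `residue_pair_track` objects, each with `pair`,
#'   `distances_A`, `times_ps`, `rate_A_per_ps` and `rate_se`.
#' @export
track_distances <- function(traj, pairs, atom_name = NULL, window = NULL) {
  stopifnot(inherits(traj, "fold_trajectory"))
  if (inherits(pairs, "residue_pair") || is.character(pairs) && length(pairs) == 1L)
    pairs <- list(pairs)
  pairs <- lapply(pairs, .as_pair)
  t <- traj$times_ps
  sel <- if (is.null(window)) rep(TRUE, length(t))
         else t >= window[1] & t <= window[2]
  if (sum(sel) < 2L) stop("rate window must contain at least two frames")
  lapply(pairs, function(p) {
    an <- atom_name %||% p$atom
    ia <- .atom_index(traj$atoms, p$a$chain, p$a$resno, an)
    ib <- .atom_index(traj$atoms, p$b$chain, p$b$resno, an)
    d <- sqrt(rowSums((traj$coords[, ia, , drop = FALSE] -
                       traj$coords[, ib, , drop = FALSE])^2))
    fit <- stats::lm(d[sel] ~ t[sel])
    rss <- sum(stats::residuals(fit)^2)
    sxx <- sum((t[sel] - mean(t[sel]))^2)
    n <- sum(sel)
    se <- if (n > 2 && sxx > 0) sqrt(rss / (n - 2) / sxx) else NA_real_
    structure(list(pair = p, label = .pair_label(p),
                   times_ps = t, distances_A = as.numeric(d),
                   rate_A_per_ps = unname(stats::coef(fit)[2]),
                   rate_se = se,
                   window = window),
              class = "residue_pair_track")
  })
}

#' @export
print.residue_pair_track <- function(x, ...) {
  cat(sprintf("residue_pair_track %s: %d frames, rate %.4g A/ps\n",
              x$label, length(x$distances_A), x$rate_A_per_ps))
  invisible(x)
}

#' List cross-chain polar contacts between two chains
#'
#' Finds all nitrogen/oxygen atom pairs across two chains within a
#' distance cutoff (default 3.5 Angstrom), a distance-only
#' donor/acceptor heuristic for hydrogen bonds and salt bridges at a
#' subunit interface. Results are sorted by distance.
#'
#' @param model a [parse_structure()] model.
#' @param chain_a,chain_b chain identifiers; both must exist in the model.
#' @param cutoff_A distance cutoff in Angstrom.
#' @return Data frame with one row per contact: chain, residue, residue
#'   name and atom name of both partners plus `distance_A`.
#' @export
interface_contacts <- function(model, chain_a, chain_b, cutoff_A = 3.5) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  for (ch in c(chain_a, chain_b))
    if (!any(at$chain == ch)) stop("chain not found: ", ch)
  polar <- at$elesy %in% c("N", "O")
  a_idx <- which(at$chain == chain_a & polar)
  b_idx <- which(at$chain == chain_b & polar)
  out <- data.frame(chain_a = character(0), resno_a = integer(0),
                    resid_a = character(0), elety_a = character(0),
                    chain_b = character(0), resno_b = integer(0),
                    resid_b = character(0), elety_b = character(0),
                    distance_A = numeric(0))
  if (length(a_idx) == 0L || length(b_idx) == 0L || cutoff_A <= 0) return(out)
  A <- as.matrix(at[a_idx, c("x", "y", "z")])
  B <- as.matrix(at[b_idx, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff_A^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(out)
  ia <- a_idx[hit[, 1]]; ib <- b_idx[hit[, 2]]
  out <- data.frame(chain_a = at$chain[ia], resno_a = at$resno[ia],
                    resid_a = at$resid[ia], elety_a = at$elety[ia],
                    chain_b = at$chain[ib], resno_b = at$resno[ib],
                    resid_b = at$resid[ib], elety_b = at$elety[ib],
                    distance_A = sqrt(pmax(d2[hit], 0)),
                    stringsAsFactors = FALSE)
  out[order(out$distance_A), , drop = FALSE]
}

#' Write a structure or trajectory to PDB format
#'
#' @param x a `structure_model` or `fold_trajectory`.
#' @param file output path. Trajectories are written as MODEL/ENDMDL
#'   blocks.
#' @return The file path, invisibly.
#' @export
write_structure_pdb <- function(x, file) {
  if (inherits(x, "structure_model")) {
    a <- x$atoms
    bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, elety = a$elety,
                     chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, ""),
                     elesy = a$elesy)
  } else if (inherits(x, "fold_trajectory")) {
    a <- x$atoms
    n_frames <- dim(x$coords)[1]
    xyz <- t(vapply(seq_len(n_frames),
                    function(i) as.numeric(t(x$coords[i, , ])),
                    numeric(3 * nrow(a))))
    bio3d::write.pdb(file = file, xyz = xyz,
                     resno = a$resno, resid = a$resid, elety = a$elety,
                     chain = a$chain, elesy = a$elesy)
  } else stop("unsupported object")
  invisible(file)
}
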