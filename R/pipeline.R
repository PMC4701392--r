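# Config-driven orchestration: reduce -> fit -> report, with stage-labelled
# errors and machine-readable JSON reports. A thin command-line wrapper
# over these functions ships in inst/cli/deltafold.R.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file (by extension) or passes a list
#' through unchanged. One config file drives all pipeline entry points;
#' any fit or generator default can be overridden there.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return The configuration list.
#' @export
read_run_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L)
  if (!file.exists(config)) stop("config file not found: ", config)
  ext <- tolower(tools::file_ext(config))
  if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
  else yaml::read_yaml(config)
}

.cfg_constants <- function(cfg) {
  cc <- cfg$constants
  thermo_constants(R = cc$R %||% 1.987e-3, T = cc$T %||% 298.15)
}

.cfg_fit_options <- function(cfg) {
  fo <- cfg$fit
  fit_options(n_starts = fo$n_starts %||% 20,
              seed = fo$seed %||% cfg$seed %||% 1,
              end_slopes = isTRUE(fo$end_slopes))
}

.check_files <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("[%s] input file not found: %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(paths)
}

.fit_report <- function(fit) {
  rep <- list(model = fit$model,
              estimates = as.list(fit$estimates),
              standard_errors = as.list(fit$standard_errors),
              midpoints_M = as.list(fit$midpoints_M),
              rss = fit$rss, aicc = fit$aicc,
              converged = fit$converged,
              n_starts_used = fit$n_starts_used,
              seed = fit$seed)
  if (!is.null(fit$total_dG)) rep$total_dG_kcal_mol <- fit$total_dG
  if (!is.null(fit$flags) && length(fit$flags)) rep$flags <- fit$flags
  rep
}

#' Run the unfolding analysis pipeline
#'
#' Loads denaturation curves (directly from curve CSVs and/or reduced from
#' per-condition spectrum CSVs), fits the configured unfolding model
#' globally within each (observable, denaturant, direction) group, and
#' reports estimates, midpoints, total free energy and an
#' unfolding-versus-refolding midpoint comparison.
#'
#' Config fields: `curve_files` (vector of curve CSVs), `spectra_files`
#' (vector of spectrum CSVs reduced to one curve), `model` (`"two_state"`,
#' `"four_state"` or `"auto"`), `constants` (`R`, `T`), `fit`
#' (`n_starts`, `seed`, `end_slopes`), `out_dir`.
#'
#' @param config path to a YAML/JSON config, or an equivalent list.
#' @return The report list, invisibly written to
#'   `out_dir/unfolding_report.json` when `out_dir` is set.
#' @export
run_unfolding_analysis <- function(config) {
  cfg <- .stage("config", read_run_config(config))
  k <- .stage("config", .cfg_constants(cfg))
  opts <- .stage("config", .cfg_fit_options(cfg))
  curves <- list()
  if (!is.null(cfg$curve_files)) {
    .check_files(cfg$curve_files, "input")
    curves <- c(curves, .stage("input",
      lapply(cfg$curve_files, read_curve_csv)))
  }
  if (!is.null(cfg$spectra_files)) {
    .check_files(cfg$spectra_files, "input")
    spectra <- .stage("input", lapply(cfg$spectra_files, read_spectrum_csv))
    curves <- c(curves, list(.stage("reduce", build_curve(
      spectra,
      denaturant = cfg$denaturant %||% "urea",
      direction = cfg$direction %||% "unfolding"))))
  }
  if (length(curves) == 0L)
    stop("[input] no curves supplied (curve_files or spectra_files required)",
         call. = FALSE)
  groups <- split(curves, vapply(curves, function(cu)
    paste(cu$observable, cu$denaturant, cu$direction, sep = "|"),
    character(1)))
  model <- cfg$model %||% "auto"
  fits <- .stage("fit", lapply(groups, function(g) {
    if (model == "two_state") fit_two_state(g, k, opts)
    else if (model == "four_state") fit_four_state(g, k, opts)
    else {
      sel <- model_select(g[[1]], k, opts)
      sel$fits[[sel$selected]]
    }
  }))
  reversibility <- NULL
  dir_of <- function(key) strsplit(key, "|", fixed = TRUE)[[1]][3]
  keys <- names(fits)
  unf <- keys[vapply(keys, dir_of, character(1)) == "unfolding"]
  ref <- keys[vapply(keys, dir_of, character(1)) == "refolding"]
  if (length(unf) && length(ref)) {
    mu <- fits[[unf[1]]]$midpoints_M
    mr <- fits[[ref[1]]]$midpoints_M
    n <- min(length(mu), length(mr))
    reversibility <- list(
      unfolding_midpoints_M = as.list(mu),
      refolding_midpoints_M = as.list(mr),
      midpoint_differences_M = as.list(mu[seq_len(n)] - mr[seq_len(n)]))
  }
  report <- list(
    analysis = "unfolding",
    provenance = list(package = "deltafold",
                      version = as.character(utils::packageVersion("deltafold")),
                      seed = opts$seed),
    n_curves = length(curves),
    curves = lapply(curves, function(cu) list(
      observable = cu$observable, denaturant = cu$denaturant,
      direction = cu$direction, n_points = length(cu$values),
      conc_range_M = range(cu$concentrations_M))),
    fits = lapply(fits, .fit_report),
    reversibility = reversibility)
  .write_report(report, cfg$out_dir, "unfolding_report.json")
}

#' Run the aggregation-kinetics pipeline
#'
#' Fits each turbidity trace with the configured kinetic model (or selects
#' one by AICc with `model: auto`) and, when ThT spectra are configured,
#' reports the fold-enhancement series.
#'
#' Config fields: `trace_files`, `model` (`"auto"`, `"exp1"`, `"exp2"`,
#' `"linear"`), `tht` (`baseline`, `timepoints` spectrum CSVs), `seed`,
#' `out_dir`.
#'
#' @param config path to a YAML/JSON config, or an equivalent list.
#' @return The report list.
#' @export
run_aggregation_analysis <- function(config) {
  cfg <- .stage("config", read_run_config(config))
  if (is.null(cfg$trace_files) || length(cfg$trace_files) == 0L)
    stop("[input] no aggregation traces configured", call. = FALSE)
  .check_files(cfg$trace_files, "input")
  traces <- .stage("input", lapply(cfg$trace_files, read_trace_csv))
  model <- cfg$model %||% "auto"
  seed <- cfg$seed %||% 1
  fits <- .stage("fit", lapply(traces, function(tr) {
    switch(model,
           auto = select_kinetic_model(tr, seed = seed),
           exp1 = fit_exponential(tr, 1, seed = seed),
           exp2 = fit_exponential(tr, 2, seed = seed),
           linear = fit_linear(tr),
           stop("unknown kinetic model: ", model))
  }))
  tht <- NULL
  if (!is.null(cfg$tht)) {
    .check_files(c(cfg$tht$baseline, cfg$tht$timepoints), "input")
    tht <- .stage("tht", {
      base <- read_spectrum_csv(cfg$tht$baseline)
      tps <- lapply(cfg$tht$timepoints, read_spectrum_csv)
      list(fold_change = tht_enhancement(base, tps))
    })
  }
  report <- list(
    analysis = "aggregation",
    provenance = list(package = "deltafold",
                      version = as.character(utils::packageVersion("deltafold")),
                      seed = seed),
    traces = lapply(seq_along(traces), function(i) {
      f <- fits[[i]]
      list(file = cfg$trace_files[i], condition = traces[[i]]$condition,
           model = f$model,
           rates_per_min = as.list(f$rates),
           amplitudes = as.list(f$amplitudes),
           y_offset = f$y_offset, rms = f$rms, aicc = f$aicc)
    }),
    tht = tht)
  .write_report(report, cfg$out_dir, "aggregation_report.json")
}

#' Run the structure-geometry pipeline
#'
#' Tracks configured residue pairs across a trajectory, fits separation
#' rates, and optionally lists interface contacts on a single structure.
#'
#' Config fields: `trajectory` (one multi-MODEL PDB or vector of frames),
#' `times_ps`, `pairs` (strings like `"A:315-B:315"`), `window`
#' (`c(t_min, t_max)` ps), `contacts` (`chain_a`, `chain_b`, `cutoff_A`),
#' `structure` (PDB for contacts; defaults to the first frame), `out_dir`.
#'
#' @param config path to a YAML/JSON config, or an equivalent list.
#' @return The report list.
#' @export
run_structure_analysis <- function(config) {
  cfg <- .stage("config", read_run_config(config))
  tracks <- NULL
  traj <- NULL
  if (!is.null(cfg$trajectory)) {
    .check_files(cfg$trajectory, "input")
    traj <- .stage("input",
      parse_trajectory(cfg$trajectory,
                       times_ps = cfg$times_ps))
    if (!is.null(cfg$pairs))
      tracks <- .stage("track", track_distances(
        traj, as.list(cfg$pairs),
        window = if (!is.null(cfg$window)) as.numeric(cfg$window)))
  }
  contacts <- NULL
  if (!is.null(cfg$contacts)) {
    model <- if (!is.null(cfg$structure)) {
      .check_files(cfg$structure, "input")
      .stage("input", parse_structure(cfg$structure))
    } else if (!is.null(traj)) {
      .stage("input", structure(list(
        atoms = cbind(traj$atoms,
                      as.data.frame(matrix(traj$coords[1, , ], ncol = 3,
                                           dimnames = list(NULL, c("x", "y", "z"))))),
        label = traj$label), class = "structure_model"))
    } else stop("[input] contacts requested but no structure or trajectory given",
                call. = FALSE)
    contacts <- .stage("contacts", interface_contacts(
      model, cfg$contacts$chain_a, cfg$contacts$chain_b,
      cutoff_A = cfg$contacts$cutoff_A %||% 3.5))
  }
  report <- list(
    analysis = "structure",
    provenance = list(package = "deltafold",
                      version = as.character(utils::packageVersion("deltafold"))),
    tracks = if (!is.null(tracks)) lapply(tracks, function(tr) list(
      pair = tr$label, n_frames = length(tr$distances_A),
      rate_A_per_ps = tr$rate_A_per_ps, rate_se = tr$rate_se,
      initial_distance_A = tr$distances_A[1],
      final_distance_A = tr$distances_A[length(tr$distances_A)])),
    contacts = if (!is.null(contacts)) contacts)
  .write_report(report, cfg$out_dir, "structure_report.json")
}

.write_report <- function(report, out_dir, filename) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, filename),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
  }
  invisible(report)
}

#' Materialise a synthetic fixture set
#'
#' Writes a complete, self-consistent set of pipeline inputs with known
#' ground truth into a directory: two-state and four-state denaturation
#' curve CSVs (unfolding and refolding), single- and double-exponential
#' aggregation traces, a toy tetramer PDB and a separating-trajectory
#' multi-MODEL PDB. Used by the command-line `fixtures` subcommand and by
#' the test suite.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; all randomness derives from it.
#' @return Named list of the written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  two <- two_state_params(6.5, 3.8, yn = 350, yu = 355)
  cfg2 <- generator_config("two_state", two, seq(0, 4, 0.25),
                           noise_sigma = 0.05, n_replicates = 2, seed = seed)
  curves <- gen_unfolding_curve(cfg2)
  curves[[2]]$direction <- "refolding"
  paths$two_state_unfolding <- file.path(dir, "curve_two_state_unfolding.csv")
  paths$two_state_refolding <- file.path(dir, "curve_two_state_refolding.csv")
  write_curve_csv(curves[[1]], paths$two_state_unfolding)
  write_curve_csv(curves[[2]], paths$two_state_refolding)
  four <- four_state_params(1.3, 2.6, 8.9, 2.1, 1.2, 2.3,
                            yN = 348, yI1 = 352, yI2 = 354, yU = 357)
  # a single fixture curve must keep the four-state model identifiable, so
  # its noise sits below the replicate-recovery level
  cfg4 <- generator_config("four_state", four, seq(0, 6, 0.25),
                           noise_sigma = 0.05, n_replicates = 1,
                           seed = seed, denaturant = "GdmCl")
  paths$four_state <- file.path(dir, "curve_four_state.csv")
  write_curve_csv(gen_unfolding_curve(cfg4)[[1]], paths$four_state)
  tr1 <- gen_aggregation_trace(0.14, 1, sigma = 0.02, seed = seed,
                               condition = "fast refolding aggregation")
  tr2 <- gen_aggregation_trace(c(0.5, 0.02), c(0.6, 0.4), sigma = 0.02,
                               seed = seed + 1,
                               times_min = seq(0, 120, 1),
                               condition = "biphasic aggregation")
  paths$trace_exp1 <- file.path(dir, "trace_exp1.csv")
  paths$trace_exp2 <- file.path(dir, "trace_exp2.csv")
  write_trace_csv(tr1, paths$trace_exp1)
  write_trace_csv(tr2, paths$trace_exp2)
  tet <- gen_toy_tetramer(contact_pair = TRUE)
  paths$tetramer <- file.path(dir, "toy_tetramer.pdb")
  write_structure_pdb(tet, paths$tetramer)
  v <- 0.1 / sqrt(2)
  traj <- gen_trajectory(gen_toy_tetramer(),
                         velocities = list(B = c(v, v, 0)),
                         n_frames = 101, dt_ps = 1, seed = seed)
  paths$trajectory <- file.path(dir, "toy_trajectory.pdb")
  write_structure_pdb(traj, paths$trajectory)
  invisible(paths)
}
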