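# Reduction of raw spectroscopic measurements to scalar denaturation
# observables: average emission wavelength (AEW), integrated ANS emission
# area, mean residue ellipticity (MRE) and lyase specific activity.

#' Construct a fluorescence emission spectrum
#'
#' One probe's wavelength/intensity scan recorded at a single solution
#' condition. The condition metadata travels with the spectrum so that
#' curves assembled from many spectra know their denaturant axis.
#'
#' @param wavelengths numeric vector of emission wavelengths (nm), strictly
#'   increasing, length >= 2.
#' @param intensities numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelengths`, all finite.
#' @param probe one of `"trp"` (intrinsic tryptophan), `"ANS"`
#'   (1-anilinonaphthalene-8-sulfonate) or `"ThT"` (thioflavin T).
#' @param excitation_nm excitation wavelength (nm). Defaults follow the
#'   conventional settings for each probe: 295 (trp), 370 (ANS), 440 (ThT).
#' @param condition list of condition metadata; recognised fields are
#'   `denaturant` (name), `conc_M` (mol/L), `protein_mg_ml` and
#'   `timepoint_min`.
#' @return An object of class `emission_spectrum`.
#' @examples
#' sp <- emission_spectrum(320:380, dnorm(320:380, 340, 12), probe = "trp")
#' compute_aew(sp)
#' @export
emission_spectrum <- function(wavelengths, intensities,
                              probe = c("trp", "ANS", "ThT"),
                              excitation_nm = NULL,
                              condition = list()) {
  probe <- match.arg(probe)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least two wavelength points")
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities)))
    stop("wavelengths and intensities must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(excitation_nm))
    excitation_nm <- switch(probe, trp = 295, ANS = 370, ThT = 440)
  structure(list(wavelengths = wavelengths,
                 intensities = intensities,
                 probe = probe,
                 excitation_nm = as.numeric(excitation_nm),
                 condition = condition),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("emission_spectrum: %s probe, %d points, %.0f-%.0f nm (ex %.0f nm)\n",
              x$probe, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$excitation_nm))
  if (!is.null(x$condition$conc_M))
    cat(sprintf("  condition: %s %.3g M\n",
                x$condition$denaturant %||% "denaturant", x$condition$conc_M))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average emission wavelength of a tryptophan spectrum
#'
#' The intensity-weighted mean wavelength,
#' \eqn{\langle\lambda\rangle = \sum_i \lambda_i F_i / \sum_i F_i},
#' the standard scalar reduction of an intrinsic-fluorescence scan. AEW
#' red-shifts as buried tryptophans become solvent exposed, which makes it
#' a robust unfolding observable: it uses the whole band rather than the
#' (noisier) peak position.
#'
#' @param spectrum an [emission_spectrum()] recorded with the `"trp"` probe.
#' @return Average emission wavelength in nm; always inside the recorded
#'   wavelength range.
#' @examples
#' sp <- emission_spectrum(c(330, 350), c(1, 3), probe = "trp")
#' compute_aew(sp) # 345
#' @export
compute_aew <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (spectrum$probe != "trp")
    stop("compute_aew expects a tryptophan ('trp') spectrum")
  total <- sum(spectrum$intensities)
  if (!is.finite(total) || total <= 0)
    stop("degenerate spectrum: total intensity is zero or negative")
  sum(spectrum$wavelengths * spectrum$intensities) / total
}

#' Integrated area of an ANS emission spectrum
#'
#' Trapezoidal integral of intensity over an analysis window, by default the
#' 450-550 nm acquisition window used for ANS. Window edges that fall
#' between recorded wavelengths are handled by linear interpolation, so the
#' integral is additive over adjacent windows.
#'
#' @param spectrum an [emission_spectrum()] recorded with the `"ANS"` probe.
#' @param window numeric length-2 vector, integration limits in nm. Must lie
#'   within the recorded wavelength range.
#' @return Integrated area in AU * nm.
#' @examples
#' sp <- emission_spectrum(seq(450, 550, 5), rep(2, 21), probe = "ANS")
#' integrate_ans(sp) # 200
#' @export
integrate_ans <- function(spectrum, window = c(450, 550)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (spectrum$probe != "ANS")
    stop("integrate_ans expects an ANS spectrum")
  stopifnot(length(window) == 2L, window[1] < window[2])
  wl <- spectrum$wavelengths
  if (window[1] < min(wl) || window[2] > max(wl))
    stop("window out of range: integration window must lie within the recorded spectrum")
  .trapz_window(wl, spectrum$intensities, window)
}

# trapezoid rule on the recorded grid, clipped to [w1, w2] with linear
# interpolation at the window edges
.trapz_window <- function(x, y, window) {
  lo <- window[1]; hi <- window[2]
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[keep],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Construct a circular-dichroism record
#'
#' Holds one observed ellipticity value together with the optical geometry
#' needed to normalise it per residue.
#'
#' @param theta_obs observed ellipticity, degrees.
#' @param mrw mean residue weight, g/mol (protein molar mass divided by the
#'   number of residues; about 110-115 for most proteins).
#' @param path_cm cuvette path length, cm (> 0).
#' @param conc_g_per_ml protein concentration, g/mL (> 0).
#' @param wavelength_nm wavelength of the reading, nm (222 for helix content).
#' @return An object of class `cd_record`.
#' @export
cd_record <- function(theta_obs, mrw, path_cm, conc_g_per_ml,
                      wavelength_nm = 222) {
  stopifnot(is.numeric(theta_obs), is.finite(theta_obs),
            is.numeric(mrw), is.numeric(path_cm), is.numeric(conc_g_per_ml))
  if (mrw <= 0) stop("mean residue weight must be positive")
  if (path_cm <= 0 || conc_g_per_ml <= 0)
    stop("invalid geometry: path length and concentration must be positive")
  structure(list(theta_obs = theta_obs, mrw = mrw, path_cm = path_cm,
                 conc_g_per_ml = conc_g_per_ml,
                 wavelength_nm = wavelength_nm),
            class = "cd_record")
}

#' Mean residue ellipticity from observed ellipticity
#'
#' Converts an observed ellipticity \eqn{\Theta} (degrees) to mean residue
#' ellipticity \eqn{[\Theta] = \Theta \cdot M_{MRW} / (10\, d\, c)} in
#' deg cm^2/dmol, where \eqn{d} is the path in cm and \eqn{c} the protein
#' concentration in g/mL. MRE is linear in \eqn{\Theta} and inversely
#' linear in both path and concentration.
#'
#' @param record a [cd_record()].
#' @return Mean residue ellipticity, deg cm^2/dmol; sign follows the input.
#' @examples
#' mre_from_theta(cd_record(0.01, 115, 0.1, 2e-4)) # 5750
#' @export
mre_from_theta <- function(record) {
  stopifnot(inherits(record, "cd_record"))
  record$theta_obs * record$mrw / (10 * record$path_cm * record$conc_g_per_ml)
}

#' Construct an argininosuccinate-lyase activity assay trace
#'
#' Fumarate release is followed by its absorbance at 240 nm; the default
#' molar absorption coefficient is 2440 / (M cm).
#'
#' @param times_min sampling times, minutes, increasing, >= 3 points.
#' @param a240 absorbance at 240 nm at each time.
#' @param epsilon_M_cm fumarate molar absorption coefficient, 1/(M cm).
#' @param path_cm optical path, cm.
#' @param volume_ml assay volume, mL.
#' @param protein_mg protein amount in the assay, mg (> 0).
#' @return An object of class `activity_assay`.
#' @export
activity_assay <- function(times_min, a240, epsilon_M_cm = 2440,
                           path_cm = 1, volume_ml = 1, protein_mg) {
  times_min <- as.numeric(times_min); a240 <- as.numeric(a240)
  if (length(times_min) < 3L) stop("an assay needs at least three time points")
  if (length(times_min) != length(a240))
    stop("times and absorbances must have equal length")
  if (any(diff(times_min) <= 0)) stop("times must be increasing")
  if (epsilon_M_cm <= 0) stop("molar absorption coefficient must be positive")
  if (protein_mg <= 0) stop("protein amount must be positive")
  structure(list(times_min = times_min, a240 = a240,
                 epsilon_M_cm = epsilon_M_cm, path_cm = path_cm,
                 volume_ml = volume_ml, protein_mg = protein_mg),
            class = "activity_assay")
}

#' Specific lyase activity from an absorbance time course
#'
#' Fits the initial-rate slope of A240 versus time by ordinary least
#' squares, converts it through Beer-Lambert
#' (\eqn{\mathrm{d}c/\mathrm{d}t = \mathrm{slope} / (\epsilon d)}) to a
#' molar production rate, scales by the assay volume to nmol/min and
#' normalises by the protein amount.
#'
#' @param assay an [activity_assay()].
#' @param window optional integer index range `c(first, last)` selecting the
#'   initial linear segment; default uses all points.
#' @param r2_min minimum R-squared below which a non-linearity warning is
#'   emitted (the initial-rate assumption is then suspect).
#' @return Specific activity in nmol/(min mg). A negative fitted slope
#'   returns 0 with attribute `negative_slope = TRUE` and a warning.
#' @examples
#' a <- activity_assay(0:5, 0.00244 * (0:5), protein_mg = 1)
#' specific_activity(a) # 1 nmol/min/mg
#' @export
specific_activity <- function(assay, window = NULL, r2_min = 0.98) {
  stopifnot(inherits(assay, "activity_assay"))
  t <- assay$times_min; y <- assay$a240
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1, window[2] <= length(t),
              window[2] - window[1] >= 1)
    idx <- seq(window[1], window[2])
    t <- t[idx]; y <- y[idx]
  }
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  if (tss > 0) {
    r2 <- 1 - sum(stats::residuals(fit)^2) / tss
    if (is.finite(r2) && r2 < r2_min)
      warning(sprintf("initial-rate region not linear (R^2 = %.3f); consider a shorter window", r2))
  }
  if (slope < 0) {
    warning("negative fitted slope; returning zero activity")
    return(structure(0, negative_slope = TRUE))
  }
  # slope [1/min] / (eps * d) -> mol/L/min; * volume [L] -> mol/min; -> nmol
  rate_M_min <- slope / (assay$epsilon_M_cm * assay$path_cm)
  nmol_min <- rate_M_min * (assay$volume_ml / 1000) * 1e9
  nmol_min / assay$protein_mg
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a buffer/denaturant blank from a sample
#' spectrum. When the two wavelength grids differ, the blank is linearly
#' interpolated onto the sample grid.
#'
#' @param spectrum,blank [emission_spectrum()] objects with matching probes.
#' @return A corrected `emission_spectrum`.
#' @export
subtract_blank <- function(spectrum, blank) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (spectrum$probe != blank$probe)
    stop("sample and blank probes differ")
  if (length(blank$wavelengths) == length(spectrum$wavelengths) &&
      all(blank$wavelengths == spectrum$wavelengths)) {
    bl <- blank$intensities
  } else {
    bl <- stats::approx(blank$wavelengths, blank$intensities,
                        xout = spectrum$wavelengths, rule = 2)$y
  }
  spectrum$intensities <- spectrum$intensities - bl
  spectrum
}

#' Construct a denaturation curve
#'
#' A scalar observable as a function of denaturant concentration for one
#' protein, probe and direction (unfolding or refolding).
#'
#' @param concentrations_M denaturant concentrations, mol/L, ascending and
#'   non-negative.
#' @param values observable values, same length.
#' @param observable what the values are: `"aew"` (nm), `"ans_area"`
#'   (AU nm) or `"mre"` (deg cm^2/dmol).
#' @param denaturant `"urea"` or `"GdmCl"`.
#' @param direction `"unfolding"` or `"refolding"`.
#' @param protein_label free-text protein identifier.
#' @return An object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(concentrations_M, values,
                               observable = c("aew", "ans_area", "mre"),
                               denaturant = c("urea", "GdmCl"),
                               direction = c("unfolding", "refolding"),
                               protein_label = "") {
  observable <- match.arg(observable)
  denaturant <- match.arg(denaturant)
  direction <- match.arg(direction)
  concentrations_M <- as.numeric(concentrations_M)
  values <- as.numeric(values)
  if (length(concentrations_M) != length(values))
    stop("concentrations and values must have equal length")
  if (length(concentrations_M) < 1L) stop("empty curve")
  if (any(concentrations_M < 0)) stop("concentrations must be non-negative")
  if (any(diff(concentrations_M) < 0)) {
    o <- order(concentrations_M)
    concentrations_M <- concentrations_M[o]; values <- values[o]
  }
  if (anyDuplicated(concentrations_M))
    stop("ambiguous condition: duplicate denaturant concentrations")
  structure(list(concentrations_M = concentrations_M, values = values,
                 observable = observable, denaturant = denaturant,
                 direction = direction, protein_label = protein_label),
            class = "denaturation_curve")
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat(sprintf("denaturation_curve: %s vs %s, %d points (%.2g-%.2g M), %s%s\n",
              x$observable, x$denaturant, length(x$values),
              min(x$concentrations_M), max(x$concentrations_M), x$direction,
              if (nzchar(x$protein_label)) paste0(", ", x$protein_label) else ""))
  invisible(x)
}

#' @export
plot.denaturation_curve <- function(x, ...) {
  ylab <- switch(x$observable, aew = "AEW (nm)",
                 ans_area = "ANS area (AU nm)",
                 mre = "MRE (deg cm2/dmol)")
  plot(x$concentrations_M, x$values,
       xlab = sprintf("[%s] (M)", x$denaturant), ylab = ylab, ...)
  invisible(x)
}

#' Assemble a denaturation curve from per-condition spectra
#'
#' Reduces each spectrum with [compute_aew()] (trp) or [integrate_ans()]
#' (ANS) and orders the results by the denaturant concentration recorded in
#' each spectrum's condition metadata.
#'
#' @param spectra list of [emission_spectrum()] objects, one per denaturant
#'   concentration, all with the same probe, each carrying `conc_M` in its
#'   condition.
#' @param observable `"aew"` or `"ans_area"`; default chosen from the probe.
#' @param denaturant,direction,protein_label passed to
#'   [denaturation_curve()].
#' @param window ANS integration window, forwarded to [integrate_ans()].
#' @return A [denaturation_curve()].
#' @export
build_curve <- function(spectra, observable = NULL,
                        denaturant = c("urea", "GdmCl"),
                        direction = c("unfolding", "refolding"),
                        protein_label = "", window = c(450, 550)) {
  if (length(spectra) == 0L) stop("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
  probes <- vapply(spectra, function(s) s$probe, character(1))
  if (length(unique(probes)) != 1L)
    stop("all spectra must share the same probe")
  if (is.null(observable))
    observable <- switch(probes[1], trp = "aew", ANS = "ans_area",
                         stop("no default observable for probe ", probes[1]))
  conc <- vapply(spectra, function(s) {
    cm <- s$condition$conc_M
    if (is.null(cm)) stop("spectrum lacks conc_M condition metadata")
    as.numeric(cm)
  }, numeric(1))
  if (anyDuplicated(conc))
    stop("ambiguous condition: duplicate denaturant concentrations")
  vals <- switch(observable,
    aew = vapply(spectra, compute_aew, numeric(1)),
    ans_area = vapply(spectra, integrate_ans, numeric(1), window = window),
    stop("unsupported observable: ", observable))
  o <- order(conc)
  denaturant <- match.arg(denaturant)
  direction <- match.arg(direction)
  denaturation_curve(conc[o], vals[o], observable = observable,
                     denaturant = denaturant, direction = direction,
                     protein_label = protein_label)
}
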