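# Plain-text interchange formats. All files are CSV with optional
# "#key=value" metadata header lines preceding the column header.

.read_meta_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(meta = meta, data = df)
}

.write_meta_csv <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.null(meta[[k]]))
      writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an emission spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `intensity`, preceded by metadata
#' header lines `#probe=`, `#denaturant=`, `#conc_M=`, `#excitation_nm=`.
#'
#' @param path CSV file path.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  x <- .read_meta_csv(path)
  stopifnot(all(c("wavelength_nm", "intensity") %in% names(x$data)))
  m <- x$meta
  emission_spectrum(x$data$wavelength_nm, x$data$intensity,
                    probe = m$probe %||% "trp",
                    excitation_nm = if (!is.null(m$excitation_nm))
                      as.numeric(m$excitation_nm) else NULL,
                    condition = list(
                      denaturant = m$denaturant,
                      conc_M = if (!is.null(m$conc_M)) as.numeric(m$conc_M),
                      protein_mg_ml = if (!is.null(m$protein_mg_ml))
                        as.numeric(m$protein_mg_ml),
                      timepoint_min = if (!is.null(m$timepoint_min))
                        as.numeric(m$timepoint_min)))
}

#' Write an emission spectrum to CSV
#'
#' @param spectrum an [emission_spectrum()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  .write_meta_csv(
    data.frame(wavelength_nm = spectrum$wavelengths,
               intensity = spectrum$intensities),
    list(probe = spectrum$probe,
         denaturant = spectrum$condition$denaturant,
         conc_M = spectrum$condition$conc_M,
         excitation_nm = spectrum$excitation_nm,
         timepoint_min = spectrum$condition$timepoint_min),
    path)
}

#' Read a denaturation curve from CSV
#'
#' Expects columns `conc_M` and `value` with `#observable=`,
#' `#denaturant=`, `#direction=`, `#protein=` headers.
#'
#' @param path CSV file path.
#' @return A [denaturation_curve()].
#' @export
read_curve_csv <- function(path) {
  x <- .read_meta_csv(path)
  stopifnot(all(c("conc_M", "value") %in% names(x$data)))
  m <- x$meta
  denaturation_curve(x$data$conc_M, x$data$value,
                     observable = m$observable %||% "aew",
                     denaturant = m$denaturant %||% "urea",
                     direction = m$direction %||% "unfolding",
                     protein_label = m$protein %||% "")
}

#' Write a denaturation curve to CSV
#'
#' @param curve a [denaturation_curve()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "denaturation_curve"))
  .write_meta_csv(
    data.frame(conc_M = curve$concentrations_M, value = curve$values),
    list(observable = curve$observable, denaturant = curve$denaturant,
         direction = curve$direction, protein = curve$protein_label),
    path)
}

#' Read an aggregation trace from CSV
#'
#' Expects columns `time_min` and `a360` with a `#condition=` header.
#'
#' @param path CSV file path.
#' @return An [aggregation_trace()].
#' @export
read_trace_csv <- function(path) {
  x <- .read_meta_csv(path)
  stopifnot(all(c("time_min", "a360") %in% names(x$data)))
  aggregation_trace(x$data$time_min, x$data$a360,
                    condition = x$meta$condition %||% "")
}

#' Write an aggregation trace to CSV
#'
#' @param trace an [aggregation_trace()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "aggregation_trace"))
  .write_meta_csv(data.frame(time_min = trace$times_min, a360 = trace$a360),
                  list(condition = trace$condition), path)
}

#' Write residue-pair distance tracks to CSV
#'
#' One column `time_ps` plus one `distance_A` column per tracked pair,
#' labelled by the pair.
#'
#' @param tracks list of tracks from [track_distances()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(length(tracks) >= 1L)
  df <- data.frame(time_ps = tracks[[1]]$times_ps)
  for (tr in tracks) df[[tr$label]] <- tr$distances_A
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
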