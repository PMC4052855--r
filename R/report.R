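## Structured run reports and pattern file I/O.

#' Full damage/diffraction report for one exposure
#'
#' Ties the calculators together: dosimetry, gating-regime classification,
#' transparency and turn-off times, and the maximum effective dose at the
#' requested resolution. Deterministic: the same configuration always yields
#' the identical report.
#'
#' @param comp Material ([composition()] or built-in name).
#' @param energy_ev Photon energy, eV.
#' @param photons_per_um2 Photons per um2.
#' @param duration_fs Pulse duration, fs.
#' @param resolution_angstrom Resolution for the turn-off/effective-dose
#'   entries.
#' @param motion A [motion_model()].
#' @return A named list (JSON-serializable; numeric fields carry units in
#'   their names).
#' @examples
#' rep <- run_report("avg_protein", 6000, 1e12, 40)
#' rep$dose_ggy
#' @export
run_report <- function(comp, energy_ev, photons_per_um2, duration_fs,
                       resolution_angstrom = 2, motion = motion_model()) {
  comp <- .fx_as_composition(comp)
  pulse <- pulse_spec(energy_ev, photons_per_um2, duration_fs)
  d <- xray_dose(pulse, comp)
  r <- d / duration_fs
  q <- 1 / resolution_angstrom
  regime <- classify_regime(r)
  list(
    material = comp$name,
    energy_ev = energy_ev,
    photons_per_um2 = photons_per_um2,
    duration_fs = duration_fs,
    fluence_j_cm2 = fluence(pulse),
    intensity_w_cm2 = pulse_intensity(pulse),
    absorption_length_um = absorption_length(comp, energy_ev),
    dose_gy = d,
    dose_ggy = d / 1e9,
    dose_rate_gy_fs = r,
    ev_per_atom = dose_to_ev_per_atom(d, comp),
    temperature_rise_k = adiabatic_heating(d),
    regime = regime$name,
    regime_transition = regime$transition,
    resolution_angstrom = resolution_angstrom,
    transparency_time_fs = transparency_time(r),
    turnoff_time_fs = turnoff_time(q, r, motion),
    effective_dose_gy = effective_dose(r, q, motion)
  )
}

#' Write a diffraction pattern to a text file
#'
#' CSV with a single JSON metadata header line (`# meta ...`) carrying the
#' pattern kind, pulse and seed. Values are written with 17 significant
#' digits, so [read_pattern()] round-trips them bit-for-bit.
#'
#' @param pattern An `fx_pattern`.
#' @param path Output file path (csv).
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  if (!grepl("\\.csv$", path)) {
    stop("unsupported pattern format '", sub("^.*\\.", "", path),
         "'; supported: csv", call. = FALSE)
  }
  meta <- c(attr(pattern, "meta"),
            list(kind = attr(pattern, "kind"),
                 pulse = unclass(attr(pattern, "pulse"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# meta", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                              null = "null", digits = NA)),
             con)
  df <- as.data.frame(pattern)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }), sep = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Read a diffraction pattern written by [write_pattern()]
#'
#' @param path File path.
#' @return An `fx_pattern` tibble with the stored metadata attributes.
#' @export
read_pattern <- function(path) {
  lines <- readLines(path, n = 1)
  if (!startsWith(lines[1], "# meta ")) {
    stop("not a flashxtal pattern file: ", path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^# meta ", "", lines[1]))
  df <- utils::read.csv(path, comment.char = "#")
  out <- tibble::as_tibble(df)
  pulse <- meta$pulse
  meta$pulse <- NULL
  kind <- meta$kind
  meta$kind <- NULL
  structure(out, class = c("fx_pattern", class(out)), kind = kind,
            pulse = structure(pulse, class = "fx_pulse"), meta = meta)
}
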