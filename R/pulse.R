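#' @importFrom rlang %||%
#' @importFrom Rcpp evalCpp
#' @useDynLib flashxtal, .registration = TRUE
NULL

#' Specify an X-ray pulse
#'
#' A flat-top (constant-intensity) pulse, the temporal profile every
#' time-dependent model in the package assumes.
#'
#' @param energy_ev Photon energy, eV.
#' @param photons_per_um2 Incident photons per square micrometre.
#' @param duration_fs Pulse duration, fs.
#' @param beam_area_um2 Optional beam area (um2), used only to report the
#'   total photon count.
#' @return An object of class `fx_pulse`.
#' @examples
#' pulse_spec(6000, 1e12, 40)
#' @export
pulse_spec <- function(energy_ev, photons_per_um2, duration_fs,
                       beam_area_um2 = NULL) {
  stopifnot(energy_ev > 0, photons_per_um2 >= 0, duration_fs > 0)
  structure(list(energy_ev = energy_ev, photons_per_um2 = photons_per_um2,
                 duration_fs = duration_fs, beam_area_um2 = beam_area_um2,
                 profile = "flat-top"),
            class = "fx_pulse")
}

#' @export
print.fx_pulse <- function(x, ...) {
  cat("<pulse> ", x$energy_ev / 1000, " keV, ",
      format(x$photons_per_um2, digits = 3), " photons/um2, ",
      x$duration_fs, " fs (flat-top)\n", sep = "")
  cat("  fluence:", signif(fluence(x), 4), "J/cm2;  intensity:",
      signif(pulse_intensity(x), 4), "W/cm2\n")
  invisible(x)
}

#' Pulse fluence
#'
#' Pulse energy per unit area: photons per area times photon energy.
#'
#' @param pulse A [pulse_spec()].
#' @return Fluence in J/cm2.
#' @examples
#' fluence(pulse_spec(6000, 1e12, 40))  # 96 kJ/cm2
#' @export
fluence <- function(pulse) {
  pulse$photons_per_um2 / .fx$um2_cm2 * pulse$energy_ev * .fx$ev_joule
}

#' Pulse intensity
#'
#' Fluence divided by duration, for the flat-top profile.
#'
#' @inheritParams fluence
#' @return Intensity in W/cm2.
#' @export
pulse_intensity <- function(pulse) {
  fluence(pulse) / (pulse$duration_fs * 1e-15)
}

#' Total photons in the pulse
#'
#' @inheritParams fluence
#' @return Photon count (requires `beam_area_um2`).
#' @export
photon_count <- function(pulse) {
  if (is.null(pulse$beam_area_um2)) {
    stop("pulse has no beam_area_um2", call. = FALSE)
  }
  pulse$photons_per_um2 * pulse$beam_area_um2
}
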