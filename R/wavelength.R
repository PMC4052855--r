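## Wavelength-scaling laws: how total Bragg signal at fixed pulse energy
## scales with photon wavelength, in the motion-gated and ionization-gated
## dose-rate regimes.

#' Scaling regime of the Bragg gate
#'
#' Total Bragg signal at fixed pulse energy factorizes into available photons
#' (proportional to lambda), scattered photons per incident fluence
#' (lambda^3), and the gating time. In the motion-gated regime the gate scales
#' as lambda^(-3/4), for a total exponent of 13/4; in the ionization-gated
#' regime the gate scales as lambda^(-2), for a total exponent of 2.
#'
#' @param name `"motion_gated"` or `"ionization_gated"`.
#' @return A list with the `name`, the three component exponents and
#'   `total_exponent` (their sum).
#' @export
scaling_regime <- function(name = c("motion_gated", "ionization_gated")) {
  name <- match.arg(name)
  gate <- switch(name, motion_gated = -3 / 4, ionization_gated = -2)
  out <- list(name = name, photon_exponent = 1, scattering_exponent = 3,
              gate_exponent = gate,
              total_exponent = 1 + 3 + gate)
  stopifnot(out$total_exponent ==
              out$photon_exponent + out$scattering_exponent + out$gate_exponent)
  out
}

#' Classify the gating regime of a dose rate
#'
#' Below about 100 MGy/fs atomic displacement gates the diffraction; above
#' about 1 GGy/fs complete ionization gates it first. In between, both
#' matter and the regime is flagged as a transition (classified with the
#' motion-gated exponents).
#'
#' @param dose_rate_gy_fs Dose rate, Gy/fs.
#' @return A [scaling_regime()] list with an extra logical field `transition`.
#' @examples
#' classify_regime(1e7)$name   # motion_gated
#' classify_regime(1e10)$name  # ionization_gated
#' @export
classify_regime <- function(dose_rate_gy_fs) {
  stopifnot(dose_rate_gy_fs > 0)
  if (dose_rate_gy_fs < 1e8) {
    out <- scaling_regime("motion_gated")
    out$transition <- FALSE
  } else if (dose_rate_gy_fs > 1e9) {
    out <- scaling_regime("ionization_gated")
    out$transition <- FALSE
  } else {
    out <- scaling_regime("motion_gated")
    out$transition <- TRUE
  }
  out
}

#' Relative Bragg signal between two photon energies
#'
#' `(lambda1/lambda2)^total_exponent = (E2/E1)^total_exponent` at fixed pulse
#' energy. Exact power-law composition:
#' `signal_ratio(E1,E2) * signal_ratio(E2,E3) = signal_ratio(E1,E3)`.
#'
#' @param energy1_ev,energy2_ev Photon energies, eV.
#' @param regime A [scaling_regime()] (or its name).
#' @return Fold change in total Bragg photons at `energy1_ev` relative to
#'   `energy2_ev`.
#' @examples
#' signal_ratio(4000, 8000)  # 2^(13/4), almost 10
#' signal_ratio(4000, 8000, "ionization_gated")  # 4
#' @export
signal_ratio <- function(energy1_ev, energy2_ev,
                         regime = scaling_regime("motion_gated")) {
  stopifnot(all(energy1_ev > 0), all(energy2_ev > 0))
  if (is.character(regime)) regime <- scaling_regime(regime)
  (energy2_ev / energy1_ev)^regime$total_exponent
}

#' Best attainable resolution at a photon energy
#'
#' `d_min = lambda/2`, the complete-backscattering limit.
#'
#' @param energy_ev Photon energy, eV; vectorized.
#' @return Resolution in angstrom.
#' @examples
#' resolution_limit(6199.2)  # 1.0 A
#' @export
resolution_limit <- function(energy_ev) {
  stopifnot(all(energy_ev > 0))
  .fx$hc_ev_angstrom / (2 * energy_ev)
}

#' Scan photon energies for relative Bragg signal
#'
#' Tabulates the relative total Bragg signal (normalized to the first energy),
#' gating regime, attainable resolution, and whether any constituent element
#' has a K edge within 200 eV of the working energy (where the smooth
#' lambda^3 dose scaling breaks down).
#'
#' @param comp Material (for near-edge flags).
#' @param energies_ev Photon energies to scan, eV.
#' @param dose_rate_gy_fs Dose rate, Gy/fs (fixes the regime).
#' @param resolution_angstrom Desired resolution; feasibility column checks
#'   `resolution_limit(E) <= resolution_angstrom`.
#' @return A tibble with one row per energy.
#' @export
scan_wavelength <- function(comp, energies_ev, dose_rate_gy_fs,
                            resolution_angstrom) {
  comp <- .fx_as_composition(comp)
  regime <- classify_regime(dose_rate_gy_fs)
  edges <- kshell_energy(names(comp$counts))
  near_edge <- vapply(energies_ev,
                      function(e) any(abs(e - edges) <= 200), TRUE)
  if (any(near_edge)) {
    warning("some energies are within 200 eV of a constituent K edge; ",
            "the smooth wavelength scaling does not hold there", call. = FALSE)
  }
  regime_name <- regime$name
  transition <- regime$transition
  tibble::tibble(
    energy_ev = energies_ev,
    wavelength_angstrom = .fx$hc_ev_angstrom / energies_ev,
    relative_signal = signal_ratio(energies_ev, energies_ev[1], regime),
    regime = regime_name,
    transition = transition,
    resolution_limit_angstrom = resolution_limit(energies_ev),
    resolution_feasible = resolution_limit(energies_ev) <= resolution_angstrom,
    near_edge = near_edge
  )
}
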