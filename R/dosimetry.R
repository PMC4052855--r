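## Dose and fluence arithmetic: absorbed dose from fluence and attenuation,
## one-photon-per-atom dose scales, hollow-atom dose rates, heating, and
## inverse conversions. The model is thin-sample throughout: samples are
## assumed much thinner than their absorption length, so no depth attenuation
## is applied.

#' Absorbed dose from a pulse
#'
#' Thin-sample dose `D = I0 * mu/rho`: the fluence times the mass attenuation
#' coefficient. Linear in fluence; for a single-element composition this is
#' identical to `I0 * sigma_A * N_A / m_A`.
#'
#' @param pulse A [pulse_spec()].
#' @param comp An [composition()] or built-in material name.
#' @param thickness_um Optional sample thickness; a warning is emitted when it
#'   exceeds a tenth of the absorption length, where the thin-sample premise
#'   starts to fail.
#' @return Dose in Gy.
#' @examples
#' xray_dose(pulse_spec(6000, 1e12, 40), "avg_protein") / 1e9  # about 2.3 GGy
#' @export
xray_dose <- function(pulse, comp, thickness_um = NULL) {
  comp <- .fx_as_composition(comp)
  if (!is.null(thickness_um) &&
      thickness_um > 0.1 * absorption_length(comp, pulse$energy_ev)) {
    warning("sample thickness exceeds a tenth of the absorption length; ",
            "the thin-sample dose is an overestimate at depth", call. = FALSE)
  }
  # g/kg factor: mu/rho is per gram
  fluence(pulse) * mass_attenuation(comp, pulse$energy_ev) * 1e3
}

#' Dose rate of a flat-top pulse
#'
#' @inheritParams xray_dose
#' @return Dose rate in Gy/fs.
#' @export
dose_rate <- function(pulse, comp) {
  xray_dose(pulse, comp) / pulse$duration_fs
}

#' Convert dose to energy per atom
#'
#' `D * m_bar / N_A` expressed in eV: how much absorbed energy each atom
#' receives on average at a given dose. 1 MGy is 0.076 eV/atom in the average
#' protein and 0.062 eV/atom in water.
#'
#' @param dose_gy Dose in Gy; vectorized.
#' @inheritParams xray_dose
#' @return eV per atom.
#' @export
dose_to_ev_per_atom <- function(dose_gy, comp) {
  m_kg <- mean_atomic_mass(comp) * 1e-3
  dose_gy * m_kg / .fx$n_avogadro / .fx$ev_joule
}

#' Convert energy per atom to dose
#'
#' Inverse of [dose_to_ev_per_atom()].
#'
#' @param ev_per_atom Energy per atom in eV; vectorized.
#' @inheritParams xray_dose
#' @return Dose in Gy.
#' @export
ev_per_atom_to_dose <- function(ev_per_atom, comp) {
  ev_per_atom / dose_to_ev_per_atom(1, comp)
}

#' One-photon-per-atom dose of a pure element
#'
#' The dose a pure sample receives when every atom has absorbed one photon:
#' `D1 = h nu * N_A / m_A`. Independent of cross sections and linear in photon
#' energy; heavier elements have lower values.
#'
#' @param element Element symbol.
#' @param energy_ev Photon energy, eV.
#' @return Dose in Gy.
#' @examples
#' one_photon_dose("C", 6000) / 1e9   # 48 GGy
#' one_photon_dose("Mn", 6000) / 1e9  # about 10 GGy
#' @export
one_photon_dose <- function(element, energy_ev) {
  stopifnot(energy_ev > 0)
  m_kg <- .fx_element_row(element)$mass_g_mol * 1e-3
  energy_ev * .fx$ev_joule * .fx$n_avogadro / m_kg
}

#' Saturation fluence of an element
#'
#' The fluence `h nu / sigma_A` at which each atom of the element absorbs one
#' photon on average.
#'
#' @inheritParams one_photon_dose
#' @return Fluence in J/cm2.
#' @examples
#' saturation_fluence("Mn", 6000) / 1e3  # about 140 kJ/cm2
#' @export
saturation_fluence <- function(element, energy_ev) {
  sigma <- cross_section(element, energy_ev) * .fx$barn_cm2
  energy_ev * .fx$ev_joule / sigma
}

#' One-photon-per-atom dose delivered to a host matrix
#'
#' The dose a host material receives at the saturation fluence of a particular
#' (possibly dilute) element: `saturation_fluence(element) * mu/rho (matrix)`.
#'
#' @inheritParams one_photon_dose
#' @inheritParams xray_dose
#' @return Dose in Gy.
#' @examples
#' one_photon_dose_in_matrix("Mn", 6000, "avg_protein") / 1e9  # 3.4 GGy
#' @export
one_photon_dose_in_matrix <- function(element, energy_ev, comp) {
  comp <- .fx_as_composition(comp)
  saturation_fluence(element, energy_ev) *
    mass_attenuation(comp, energy_ev) * 1e3
}

#' Dose rate needed to produce hollow atoms
#'
#' The one-photon-per-atom matrix dose divided by the element's K-hole Auger
#' lifetime: delivering the saturation dose within the Auger lifetime makes a
#' second core-shell ionization probable before the hole is refilled,
#' producing hollow atoms that frustrate further photoabsorption.
#'
#' @inheritParams one_photon_dose_in_matrix
#' @return Dose rate in Gy/fs.
#' @export
hollow_atom_dose_rate <- function(element, energy_ev, comp) {
  one_photon_dose_in_matrix(element, energy_ev, comp) / auger_lifetime(element)
}

#' Per-element dose-scale table
#'
#' One-photon-per-atom matrix doses and hollow-atom dose rates for a set of
#' elements and photon energies in a host material.
#'
#' @param comp Host material (default: the average protein).
#' @param energies_ev Photon energies, eV.
#' @param elements Element symbols (must have bundled Auger lifetimes).
#' @return A tibble with columns `element`, `energy_ev`, `d1_ggy`,
#'   `tau_auger_fs`, `hollow_rate_ggy_fs`.
#' @examples
#' hollow_atom_table()
#' @export
hollow_atom_table <- function(comp = material("avg_protein"),
                              energies_ev = c(6000, 8000),
                              elements = c("C", "N", "O", "S", "Mn", "Fe")) {
  comp <- .fx_as_composition(comp)
  grid <- .fx_grid(elements, energies_ev)
  d1 <- purrr::map2_dbl(grid$element, grid$energy_ev,
                        ~one_photon_dose_in_matrix(.x, .y, comp))
  tau <- unname(vapply(grid$element, auger_lifetime, 0))
  tibble::tibble(
    element = grid$element,
    energy_ev = grid$energy_ev,
    d1_ggy = d1 / 1e9,
    tau_auger_fs = tau,
    hollow_rate_ggy_fs = d1 / tau / 1e9
  )
}

# expand.grid without factor conversion, element-major order
.fx_grid <- function(elements, energies_ev) {
  tibble::tibble(
    element = rep(elements, each = length(energies_ev)),
    energy_ev = rep(energies_ev, times = length(elements))
  )
}

#' Adiabatic temperature rise
#'
#' Temperature rise if the whole dose thermalizes with no heat flow out of
#' the sample: dose divided by heat capacity.
#'
#' @param dose_gy Dose, Gy; vectorized.
#' @param heat_capacity Specific heat capacity, J/(kg K). The default is
#'   water's 4800.
#' @return Temperature rise in K.
#' @examples
#' adiabatic_heating(1e6)  # 208 K
#' @export
adiabatic_heating <- function(dose_gy, heat_capacity = 4800) {
  stopifnot(heat_capacity > 0)
  dose_gy / heat_capacity
}

#' Photons per area needed for a target dose
#'
#' Inverse of [xray_dose()]; round-trips with it to machine precision.
#'
#' @param dose_gy Target dose, Gy.
#' @inheritParams xray_dose
#' @param energy_ev Photon energy, eV.
#' @return Photons per um2.
#' @examples
#' photons_for_dose(1e6, "avg_protein", 6000)  # about 4e8
#' @export
photons_for_dose <- function(dose_gy, comp, energy_ev) {
  comp <- .fx_as_composition(comp)
  per_photon <- xray_dose(pulse_spec(energy_ev, 1, 1), comp)
  dose_gy / per_photon
}

#' Dose equivalent of a bond energy
#'
#' The dose at which the absorbed energy per atom equals a given bond energy:
#' bond energy per atom divided by the mass per atom. Breaking every
#' carbon-carbon bond (about 1 eV, 100 kJ/mol) costs only about 8 MGy.
#'
#' @param bond_energy_ev Bond energy per atom, eV.
#' @inheritParams xray_dose
#' @return Dose in Gy.
#' @examples
#' bond_break_dose(1, "carbon") / 1e6  # about 8 MGy
#' @export
bond_break_dose <- function(bond_energy_ev, comp) {
  stopifnot(bond_energy_ev > 0)
  ev_per_atom_to_dose(bond_energy_ev, comp)
}

#' One-stop dose report for a pulse and material
#'
#' @inheritParams xray_dose
#' @return A one-row tibble with fluence (J/cm2), intensity (W/cm2), dose
#'   (Gy and GGy), dose rate (Gy/fs), energy per atom (eV), absorption length
#'   (um) and the gating-regime label of [classify_regime()].
#' @examples
#' dose_report(pulse_spec(6000, 1e12, 40), "avg_protein")
#' @export
dose_report <- function(pulse, comp) {
  comp <- .fx_as_composition(comp)
  d <- xray_dose(pulse, comp)
  r <- d / pulse$duration_fs
  tibble::tibble(
    material = comp$name,
    energy_ev = pulse$energy_ev,
    photons_per_um2 = pulse$photons_per_um2,
    duration_fs = pulse$duration_fs,
    fluence_j_cm2 = fluence(pulse),
    intensity_w_cm2 = pulse_intensity(pulse),
    dose_gy = d,
    dose_ggy = d / 1e9,
    dose_rate_gy_fs = r,
    ev_per_atom = dose_to_ev_per_atom(d, comp),
    absorption_length_um = absorption_length(comp, pulse$energy_ev),
    regime = classify_regime(r)$name
  )
}
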