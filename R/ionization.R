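## Ionization dynamics: photoelectron/Auger energetics, the secondary-electron
## cascade, average-ionization trajectories, transparency times, and the
## charged-sphere electron-escape criterion.
##
## The average-ionization trajectory is an energy-budget model: absorbed
## energy converts to ionizations at a fixed cost per ionization, delayed by a
## saturating cascade response. It is calibrated to published anchor points
## (transparency after 3 fs at 60 GGy/fs and about 60 fs at 0.6 GGy/fs;
## valence-stripping saturation near 1.3 GGy; one free electron per atom a few
## hundred MGy), not to any particular plasma code's exact curves.

#' Secondary-electron cascade model
#'
#' Parameters of the collisional-ionization cascade triggered by photo- and
#' Auger electrons: one ionization is produced per `eps_ion_ev` of deposited
#' energy once the cascade has developed, with a saturating time response of
#' scale `tau_cascade_fs` (a 5 keV electron thermalizes in about 10 fs and
#' yields about 240 ionizations, roughly 10 of them core-shell).
#'
#' @param eps_ion_ev Mean energy per ionization, eV (default 21).
#' @param tau_cascade_fs Cascade saturation time constant, fs (default 10).
#' @param core_shell_fraction Fraction of cascade ionizations that are
#'   core-shell (default 10/240).
#' @return An object of class `fx_cascade_model`.
#' @export
cascade_model <- function(eps_ion_ev = 21, tau_cascade_fs = 10,
                          core_shell_fraction = 10 / 240) {
  stopifnot(eps_ion_ev > 0, tau_cascade_fs > 0,
            core_shell_fraction >= 0, core_shell_fraction <= 1)
  structure(list(eps_ion_ev = eps_ion_ev, tau_cascade_fs = tau_cascade_fs,
                 core_shell_fraction = core_shell_fraction),
            class = "fx_cascade_model")
}

#' Photoelectron energy
#'
#' Photon energy minus the K-shell binding energy of the absorbing element.
#'
#' @param energy_ev Photon energy, eV.
#' @param element Absorbing element symbol.
#' @return Photoelectron energy, eV.
#' @examples
#' photoelectron_energy(6000, "C")  # 5716 eV
#' @export
photoelectron_energy <- function(energy_ev, element) {
  ek <- kshell_energy(element)
  if (any(energy_ev <= ek)) {
    stop("photon energy at or below the ", element, " K edge (",
         ek, " eV): no K-shell photoionization", call. = FALSE)
  }
  energy_ev - ek
}

#' Electron speed from kinetic energy
#'
#' Non-relativistic `sqrt(2E/m_e)`; adequate below about 10 keV (a 10 keV
#' electron is at 2% relativistic speed correction).
#'
#' @param energy_ev Kinetic energy, eV; vectorized.
#' @return Speed in angstrom/fs.
#' @examples
#' electron_speed(5716)  # about 450 A/fs
#' @export
electron_speed <- function(energy_ev) {
  stopifnot(all(energy_ev >= 0))
  sqrt(2 * energy_ev * .fx$ev_joule / .fx$m_e_kg) * 1e-5  # m/s -> A/fs
}

#' Asymptotic cascade yield
#'
#' Total and core-shell ionization counts eventually produced by an electron
#' (or photon energy budget) of the given energy: `E / eps_ion`.
#'
#' @param e_electron_ev Initial electron energy (or full absorbed-photon
#'   budget), eV; vectorized.
#' @param model A [cascade_model()].
#' @return A tibble with columns `e_electron_ev`, `total`, `core_shell`.
#' @examples
#' cascade_yield(5000)  # about 240 ionizations, 10 core-shell
#' @export
cascade_yield <- function(e_electron_ev, model = cascade_model()) {
  stopifnot(all(e_electron_ev >= 0))
  total <- e_electron_ev / model$eps_ion_ev
  tibble::tibble(e_electron_ev = e_electron_ev, total = total,
                 core_shell = total * model$core_shell_fraction)
}

#' Cascade ionization count versus time
#'
#' Saturating response `N(t) = yield * (1 - exp(-t/tau))`; most secondary
#' electrons exist within 20 fs.
#'
#' @param t_fs Time after the primary ionization, fs; vectorized.
#' @inheritParams cascade_yield
#' @return Ionization count(s) at `t_fs`.
#' @export
cascade_curve <- function(t_fs, e_electron_ev, model = cascade_model()) {
  stopifnot(all(t_fs >= 0))
  (e_electron_ev / model$eps_ion_ev) * (1 - exp(-t_fs / model$tau_cascade_fs))
}

#' Expected photoionization and scattering counts in a volume
#'
#' Per-element expected photoabsorption events,
#' `atoms_of_element * sigma_A * photons_per_area`, plus expected elastically
#' scattered photons via `sigma_S`. Expectations are deterministic; set
#' `sample = TRUE` for a seeded Poisson realization.
#'
#' @param pulse A [pulse_spec()].
#' @param comp Material.
#' @param volume_um3 Illuminated sample volume, um3.
#' @param sample Draw Poisson counts instead of expectations.
#' @param seed Seed for the Poisson draw.
#' @return A tibble with columns `element`, `atoms`, `photoionizations`,
#'   `scattered`; totals available via `colSums` of the numeric columns.
#' @export
photoionization_counts <- function(pulse, comp, volume_um3,
                                   sample = FALSE, seed = NULL) {
  comp <- .fx_as_composition(comp)
  stopifnot(volume_um3 >= 0)
  if (is.null(comp$density)) stop("composition needs a density", call. = FALSE)
  mass_g <- comp$density * volume_um3 * 1e-12  # 1 um3 = 1e-12 cm3
  n_atoms <- mass_g * .fx$n_avogadro /
    sum(comp$counts * .fx_element_row(names(comp$counts))$mass_g_mol) *
    comp$counts  # per element
  photons_cm2 <- pulse$photons_per_um2 / .fx$um2_cm2
  sig_a <- vapply(names(comp$counts), cross_section, 0,
                  energy_ev = pulse$energy_ev) * .fx$barn_cm2
  sig_s <- vapply(names(comp$counts), cross_section, 0,
                  energy_ev = pulse$energy_ev, kind = "elastic") * .fx$barn_cm2
  ion <- n_atoms * sig_a * photons_cm2
  sca <- n_atoms * sig_s * photons_cm2
  if (sample) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    ion <- stats::rpois(length(ion), ion)
    sca <- stats::rpois(length(sca), sca)
  }
  tibble::tibble(element = names(comp$counts), atoms = unname(n_atoms),
                 photoionizations = unname(ion), scattered = unname(sca))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Average-ionization trajectory during a flat-top pulse
#'
#' Energy-budget model of the average ionization per atom: the dose rate is
#' converted to deposited eV per atom per fs, divided by the energy cost per
#' ionization, and delayed by the cascade response, giving the closed form
#' `z(t) = (r/eps) * (t - tau * (1 - exp(-t/tau)))`, capped at the mean
#' electron count per atom. For a given dose rate the trajectory is
#' independent of photon energy, in line with plasma simulations. The bound
#' scattering-strength fraction is `w(t) = 1 - z(t)/z_max`.
#'
#' @param dose_rate_gy_fs Dose rate, Gy/fs.
#' @param duration_fs Pulse duration, fs.
#' @param comp Material.
#' @param model A [cascade_model()].
#' @param n_steps Number of output grid points.
#' @return An `fx_ionization_traj`: a tibble with columns `t_fs`, `z`
#'   (electrons/atom) and `w` (bound fraction), carrying the model parameters
#'   as attributes so it can be evaluated at arbitrary times via
#'   [ionization_at()].
#' @examples
#' tr <- ionization_trajectory(1e9, 40, "avg_protein")
#' head(tr)
#' @export
ionization_trajectory <- function(dose_rate_gy_fs, duration_fs,
                                  comp = material("avg_protein"),
                                  model = cascade_model(), n_steps = 256) {
  stopifnot(dose_rate_gy_fs >= 0, duration_fs > 0, n_steps >= 2)
  comp <- .fx_as_composition(comp)
  t <- seq(0, duration_fs, length.out = n_steps)
  zw <- .fx_zw(t, dose_rate_gy_fs, comp, model)
  out <- tibble::tibble(t_fs = t, z = zw$z, w = zw$w)
  structure(out, class = c("fx_ionization_traj", class(out)),
            dose_rate_gy_fs = dose_rate_gy_fs, duration_fs = duration_fs,
            comp = comp, model = model)
}

# closed-form z(t), w(t)
.fx_zw <- function(t, dose_rate_gy_fs, comp, model) {
  z_max <- mean_electrons_per_atom(comp)
  r_ev <- dose_to_ev_per_atom(dose_rate_gy_fs, comp)  # eV/atom/fs
  tau <- model$tau_cascade_fs
  z <- pmin(r_ev / model$eps_ion_ev * (t - tau * (1 - exp(-t / tau))), z_max)
  list(z = z, w = pmax(1 - z / z_max, 0))
}

#' Evaluate an ionization trajectory at arbitrary times
#'
#' @param traj An `fx_ionization_traj`.
#' @param t_fs Times, fs.
#' @return A list with vectors `z` and `w`.
#' @export
ionization_at <- function(traj, t_fs) {
  .fx_zw(t_fs, attr(traj, "dose_rate_gy_fs"), attr(traj, "comp"),
         attr(traj, "model"))
}

#' Dose for one free electron per atom
#'
#' The end-of-pulse dose at which the average ionization reaches one electron
#' per atom under the energy-budget model, for a flat-top pulse of the given
#' duration. Below this dose scattering is predominantly from pristine atoms.
#'
#' @param comp Material.
#' @param duration_fs Pulse duration, fs.
#' @param model A [cascade_model()].
#' @return Dose in Gy.
#' @export
one_electron_dose <- function(comp = material("avg_protein"),
                              duration_fs = 100, model = cascade_model()) {
  tau <- model$tau_cascade_fs
  ev <- model$eps_ion_ev * duration_fs /
    (duration_fs - tau * (1 - exp(-duration_fs / tau)))
  ev_per_atom_to_dose(ev, comp)
}

#' Valence-stripping saturation dose
#'
#' Collisional ionization saturates when the cascade has removed the valence
#' electrons, at roughly 100 eV of absorbed energy per atom (about 25 eV per
#' valence ionization); in the average protein that is about 1.3 GGy.
#'
#' @param comp Material.
#' @param ev_per_atom Energy per atom at saturation (default 100 eV).
#' @return Dose in Gy.
#' @export
valence_saturation_dose <- function(comp = material("avg_protein"),
                                    ev_per_atom = 100) {
  ev_per_atom_to_dose(ev_per_atom, comp)
}

#' Time to scattering transparency
#'
#' The time at which all electrons are stripped and coherent scattering
#' ceases, as an anchored power law in dose rate:
#' `t_tr = 3 fs * (R / 60 GGy/fs)^(-2/3)`. The -2/3 exponent makes the
#' achievable dose `R * t_tr` grow with the one-third power of dose rate.
#'
#' @param dose_rate_gy_fs Dose rate, Gy/fs; vectorized.
#' @return Transparency time in fs.
#' @examples
#' transparency_time(60e9)   # 3 fs
#' transparency_time(0.6e9)  # about 60 fs
#' @export
transparency_time <- function(dose_rate_gy_fs) {
  stopifnot(all(dose_rate_gy_fs > 0))
  3 * (dose_rate_gy_fs / 60e9)^(-2 / 3)
}

#' Net ionization at which electrons become trapped
#'
#' Uniformly charged sphere model of a small isolated particle: an electron of
#' the given energy, launched at the surface (the weakest-bound geometry), is
#' trapped once `e^2 * Q_net / (4 pi eps0 R) >= E`. Returns the net charge per
#' atom at that threshold. For an 8 nm protein particle and 6 keV electrons
#' this is of order unity, matching the observation that photoelectron escape
#' shuts down once the average ionization is about one.
#'
#' @param diameter_nm Particle diameter, nm.
#' @param comp Material (density required).
#' @param e_electron_ev Electron kinetic energy, eV.
#' @return Net ionization per atom at the trapping threshold.
#' @export
escape_threshold <- function(diameter_nm, comp, e_electron_ev) {
  comp <- .fx_as_composition(comp)
  stopifnot(diameter_nm > 0, e_electron_ev >= 0)
  if (is.null(comp$density)) stop("composition needs a density", call. = FALSE)
  r_a <- diameter_nm * 10 / 2
  vol_cm3 <- 4 / 3 * pi * (diameter_nm * 1e-7 / 2)^3
  n_atoms <- comp$density * vol_cm3 * .fx$n_avogadro / mean_atomic_mass(comp)
  q_net <- e_electron_ev * r_a / .fx$coulomb_ev_angstrom
  q_net / n_atoms
}
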