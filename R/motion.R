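## X-ray-driven atomic displacement: an accelerating-diffusion power law for
## the RMS displacement, the Bragg turn-off time it implies at a given
## resolution, and the maximum effective dose achievable at a given dose rate.

#' Atomic-motion model
#'
#' Power-law parameterization of the RMS atomic displacement during a
#' flat-top pulse, `sigma(t) = C * R^alpha * t^beta` with the dose rate R in
#' GGy/fs and t in fs. `sigma` is the per-axis (1D) RMS displacement that
#' enters the Debye-Waller factor as `exp(-4 pi^2 q^2 sigma^2)`; the 3D RMS
#' displacement is `sqrt(3) * sigma`.
#'
#' Two exponent presets are shipped, because the literature quotes two
#' slightly different scaling sets:
#' \describe{
#'   \item{`"diffusion"`}{`alpha = 1/2`, `beta = 3/2` (the default): RMS
#'     displacement grows as t^(3/2) and with the square root of intensity.
#'     This preset yields a turn-off time proportional to R^(-1/3) and an
#'     effective dose growing as R^(2/3).}
#'   \item{`"wavelength"`}{`alpha = 1/3`, `beta = 4/3`: displacement growing
#'     with the one-third power of dose rate and turn-off time with its
#'     inverse one-fourth power, the set used by the wavelength-scaling
#'     analysis (it makes the gating time scale as lambda^(-3/4)).}
#' }
#'
#' The amplitude `C` is calibrated so that sigma reaches 1 angstrom at the end
#' of a reference pulse of 50 fs at 50 MGy/fs (the worked explosion scenario
#' this package's demo crystal reproduces); it is a first-class parameter.
#'
#' @param preset `"diffusion"` or `"wavelength"`.
#' @param alpha,beta Override the preset exponents (dose-rate and time).
#' @param amplitude Override `C`, in angstrom * (GGy/fs)^(-alpha) * fs^(-beta).
#' @param n_dim Number of spatial dimensions in the diffusion bookkeeping.
#' @return An object of class `fx_motion_model`.
#' @examples
#' motion_model()
#' rms_displacement(50, 5e7, motion_model())  # 1 A by construction
#' @export
motion_model <- function(preset = c("diffusion", "wavelength"),
                         alpha = NULL, beta = NULL, amplitude = NULL,
                         n_dim = 3) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     diffusion = c(alpha = 1 / 2, beta = 3 / 2),
                     wavelength = c(alpha = 1 / 3, beta = 4 / 3))
  alpha <- alpha %||% defaults[["alpha"]]
  beta <- beta %||% defaults[["beta"]]
  stopifnot(alpha > 0, beta > 0, n_dim >= 1)
  # sigma = 1 A at the reference scenario: R0 = 0.05 GGy/fs, T0 = 50 fs
  amplitude <- amplitude %||% (1 / (0.05^alpha * 50^beta))
  stopifnot(amplitude > 0)
  structure(list(preset = preset, alpha = alpha, beta = beta,
                 amplitude = amplitude, n_dim = n_dim),
            class = "fx_motion_model")
}

#' RMS atomic displacement at time t
#'
#' @param t_fs Time into the pulse, fs; vectorized.
#' @param dose_rate_gy_fs Dose rate, Gy/fs.
#' @param model A [motion_model()].
#' @return Per-axis RMS displacement, angstrom.
#' @export
rms_displacement <- function(t_fs, dose_rate_gy_fs, model = motion_model()) {
  stopifnot(all(t_fs >= 0), dose_rate_gy_fs >= 0)
  model$amplitude * (dose_rate_gy_fs / 1e9)^model$alpha * t_fs^model$beta
}

#' Time-dependent diffusion constant
#'
#' The accelerating-diffusion form of the same law: `sigma^2 = 2 N_d
#' integral(D_c dt)` with `D_c(t) = beta/N_d * C^2 * R^(2 alpha) *
#' t^(2 beta - 1)`. Equal to the power-law form by construction.
#'
#' @inheritParams rms_displacement
#' @return D_c in angstrom^2/fs.
#' @export
diffusion_constant <- function(t_fs, dose_rate_gy_fs, model = motion_model()) {
  r <- dose_rate_gy_fs / 1e9
  model$beta / model$n_dim * model$amplitude^2 * r^(2 * model$alpha) *
    t_fs^(2 * model$beta - 1)
}

#' Displacement trajectory over a pulse
#'
#' @param dose_rate_gy_fs Dose rate, Gy/fs.
#' @param duration_fs Pulse duration, fs.
#' @param model A [motion_model()].
#' @param n_steps Number of output grid points.
#' @return An `fx_displacement_traj`: tibble with `t_fs`, `sigma_angstrom`,
#'   carrying the model and dose rate as attributes for exact evaluation at
#'   arbitrary times.
#' @export
displacement_trajectory <- function(dose_rate_gy_fs, duration_fs,
                                    model = motion_model(), n_steps = 256) {
  stopifnot(dose_rate_gy_fs >= 0, duration_fs > 0, n_steps >= 2)
  t <- seq(0, duration_fs, length.out = n_steps)
  out <- tibble::tibble(t_fs = t,
                        sigma_angstrom = rms_displacement(t, dose_rate_gy_fs, model))
  structure(out, class = c("fx_displacement_traj", class(out)),
            dose_rate_gy_fs = dose_rate_gy_fs, duration_fs = duration_fs,
            model = model)
}

#' Evaluate a displacement trajectory at arbitrary times
#'
#' @param traj An `fx_displacement_traj`.
#' @param t_fs Times, fs.
#' @return Per-axis RMS displacements, angstrom.
#' @export
displacement_at <- function(traj, t_fs) {
  rms_displacement(t_fs, attr(traj, "dose_rate_gy_fs"), attr(traj, "model"))
}

#' Bragg turn-off time at a resolution
#'
#' The time at which the displacement low-pass filter reaches a given
#' scattering vector: `sigma(t_off) = 1/(2 pi q)`, i.e.
#' `t_off = (1 / (2 pi q C R^alpha))^(1/beta)`. Monotone decreasing in both
#' `q` and the dose rate.
#'
#' @param q_inv_angstrom Scattering-vector magnitude `q = 1/d`, 1/angstrom;
#'   vectorized.
#' @param dose_rate_gy_fs Dose rate, Gy/fs.
#' @param model A [motion_model()].
#' @return Turn-off time, fs.
#' @export
turnoff_time <- function(q_inv_angstrom, dose_rate_gy_fs,
                         model = motion_model()) {
  stopifnot(all(q_inv_angstrom > 0), dose_rate_gy_fs > 0)
  r <- dose_rate_gy_fs / 1e9
  (1 / (2 * pi * q_inv_angstrom * model$amplitude * r^model$alpha))^(1 / model$beta)
}

#' Maximum effective dose at a resolution
#'
#' Dose rate times the diffraction gate: the earlier of the motion turn-off
#' time and the ionization transparency time. In the motion-gated regime this
#' grows with the two-thirds power of dose rate (under the default exponents);
#' once ionization gates, the growth flattens to the one-third power.
#'
#' @inheritParams turnoff_time
#' @param gate Which gate(s) to apply: `"both"`, `"motion"` or `"ionization"`.
#' @return Effective dose, Gy.
#' @export
effective_dose <- function(dose_rate_gy_fs, q_inv_angstrom,
                           model = motion_model(),
                           gate = c("both", "motion", "ionization")) {
  gate <- match.arg(gate)
  t_m <- turnoff_time(q_inv_angstrom, dose_rate_gy_fs, model)
  t_i <- transparency_time(dose_rate_gy_fs)
  t_gate <- switch(gate, both = pmin(t_m, t_i), motion = t_m, ionization = t_i)
  dose_rate_gy_fs * t_gate
}

#' Is a correlated motion observable before Bragg gating?
#'
#' A correlated displacement (for instance light atoms repelled by a rapidly
#' ionizing heavy atom) contributes coherently to a Bragg peak only if it
#' covers more than `2 pi sigma` before that peak's turn-off time, i.e. it
#' must outrun the diffusive motion by roughly a factor of 2 pi (about six).
#'
#' @param speed_angstrom_fs Speed of the correlated motion, angstrom/fs.
#' @inheritParams turnoff_time
#' @return Logical: `TRUE` when the motion would be observable.
#' @export
correlated_motion_observable <- function(speed_angstrom_fs, q_inv_angstrom,
                                         dose_rate_gy_fs,
                                         model = motion_model()) {
  t_off <- turnoff_time(q_inv_angstrom, dose_rate_gy_fs, model)
  speed_angstrom_fs * t_off >
    2 * pi * rms_displacement(t_off, dose_rate_gy_fs, model)
}
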