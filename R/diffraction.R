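## Diffraction of toy crystals under evolving ionization and displacement.
##
## Conventions: q = 2 sin(theta)/lambda (magnitude 1/d), phase exp(+2 pi i
## q.x), per-axis RMS displacement sigma entering the Debye-Waller factor as
## exp(-4 pi^2 q^2 sigma^2). Ionization uses a binary population: each atom is
## either neutral or fully stripped, with bound probability w, so the average
## structure scatters with w*f0 and random ionization adds a flat (up to the
## f(q) envelope) diffuse term n*w*(1-w)*f0^2. Every analytic decomposition
## here has a Monte-Carlo counterpart computed from the same primitive
## (random draws + exact structure-factor sums), which the tests compare.
## No polarization factor is applied.

#' Build a line of scattering vectors
#'
#' A 1D cut through reciprocal space along a cell axis, the working grid for
#' quantitative peak/background separation.
#'
#' @param q_max Largest |q|, 1/angstrom.
#' @param n Number of nodes.
#' @param axis Unit direction (default x).
#' @param q_min Smallest |q| (avoid 0 to keep the beamstop region out).
#' @param d_omega Solid angle per node, sr.
#' @param wavelength Optional wavelength (angstrom); when given, nodes beyond
#'   the backscattering limit 2/lambda are rejected.
#' @return A tibble with columns `qx`, `qy`, `qz`, `q`, `d_omega`.
#' @export
q_grid_line <- function(q_max, n, axis = c(1, 0, 0), q_min = q_max / n,
                        d_omega = 1e-6, wavelength = NULL) {
  stopifnot(q_max > q_min, q_min > 0, n >= 2, d_omega >= 0)
  axis <- axis / sqrt(sum(axis^2))
  qmag <- seq(q_min, q_max, length.out = n)
  if (!is.null(wavelength) && any(qmag > 2 / wavelength)) {
    stop("grid extends beyond the backscattering limit 2/lambda", call. = FALSE)
  }
  out <- tibble::tibble(qx = qmag * axis[1], qy = qmag * axis[2],
                        qz = qmag * axis[3], q = qmag, d_omega = d_omega)
  attr(out, "wavelength") <- wavelength
  out
}

#' Build a planar grid of scattering vectors
#'
#' A 2D section through reciprocal space (for rendering section images).
#'
#' @param q_max Half-width of the square section, 1/angstrom.
#' @param n Nodes per axis.
#' @param d_omega Solid angle per node, sr.
#' @param wavelength Optional wavelength (angstrom) for the Ewald bound.
#' @return A tibble as in [q_grid_line()].
#' @export
q_grid_plane <- function(q_max, n, d_omega = 1e-6, wavelength = NULL) {
  stopifnot(q_max > 0, n >= 2)
  ax <- seq(-q_max, q_max, length.out = n)
  g <- expand.grid(qx = ax, qy = ax)
  q <- sqrt(g$qx^2 + g$qy^2)
  if (!is.null(wavelength)) {
    keep <- q <= 2 / wavelength
    g <- g[keep, ]
    q <- q[keep]
  }
  out <- tibble::tibble(qx = g$qx, qy = g$qy, qz = 0, q = q, d_omega = d_omega)
  attr(out, "wavelength") <- wavelength
  out
}

# per-element complex phase sums for a site table; returns list(A = m x G
# complex matrix, elements, f = m x G factor matrix)
.fx_phase_decomp <- function(sites, qmat, qmag, weights = NULL) {
  elements <- unique(sites$element)
  group <- match(sites$element, elements)
  w <- weights %||% sites$occupancy
  A <- phase_sums(qmat, cbind(sites$x, sites$y, sites$z), as.numeric(w),
                  as.integer(group), length(elements))
  f <- vapply(elements, function(el) scattering_factor(el, qmag),
              numeric(length(qmag)))
  f <- matrix(f, nrow = length(qmag))
  list(A = A, elements = elements, f = f, group = group)
}

#' Structure factor of a set of atom sites
#'
#' `F(q) = sum_i f_i(q) exp(2 pi i q.x_i)` with neutral-atom factors scaled by
#' `bound_fraction`.
#'
#' @param sites A tibble with `element`, `x`, `y`, `z` (angstrom) and
#'   optionally `occupancy` (see [crystal_sites()]).
#' @param q A numeric length-3 vector, or an n x 3 matrix / q-grid tibble of
#'   scattering vectors (1/angstrom).
#' @param bound_fraction Bound-electron fraction applied to all atoms.
#' @return Complex structure factor(s), electron units.
#' @export
structure_factor <- function(sites, q, bound_fraction = 1) {
  qmat <- .fx_as_qmat(q)
  if (!"occupancy" %in% names(sites)) sites$occupancy <- 1
  qmag <- sqrt(rowSums(qmat^2))
  d <- .fx_phase_decomp(sites, qmat, qmag)
  drop(rowSums(d$A * (d$f * bound_fraction)))
}

.fx_as_qmat <- function(q) {
  if (is.data.frame(q)) {
    as.matrix(q[, c("qx", "qy", "qz")])
  } else if (is.matrix(q)) {
    stopifnot(ncol(q) == 3)
    q
  } else {
    stopifnot(length(q) == 3)
    matrix(q, ncol = 3)
  }
}

#' Bragg/diffuse split under random ionization
#'
#' For `n` atoms of one element with an independently ionized fraction `x`
#' (ionized factor `f0 - delta_f`), the expected intensity is the incoherent
#' sum of the average structure, with factor `fbar = f0 - x*delta_f`, and a
#' difference-structure diffuse term `n*x*(1-x)*delta_f^2` that is flat in q
#' apart from the `delta_f(q)` envelope.
#'
#' @param n Number of atoms.
#' @param x Ionized fraction in `[0, 1]`.
#' @param f0 Neutral scattering factor(s) at the evaluation q.
#' @param delta_f Factor difference neutral minus ionized.
#' @param lattice_sum_sq `|sum_i exp(2 pi i q.x_i)|^2`, the squared phase sum
#'   of the mean structure at the evaluation q.
#' @return A tibble with columns `bragg` and `diffuse` (electron^2 units).
#' @export
ionization_mixture_decomposition <- function(n, x, f0, delta_f,
                                             lattice_sum_sq) {
  stopifnot(all(x >= 0), all(x <= 1), n >= 0)
  fbar <- f0 - x * delta_f
  tibble::tibble(bragg = fbar^2 * lattice_sum_sq,
                 diffuse = n * x * (1 - x) * delta_f^2)
}

#' Bragg/diffuse split under Gaussian displacements
#'
#' Independent isotropic Gaussian displacements of per-axis RMS `sigma` reduce
#' the Bragg term by the Debye-Waller factor `exp(-4 pi^2 q^2 sigma^2)` and
#' redirect the loss into diffuse scattering `n f^2 (1 - DW)`; as sigma grows
#' the total tends to the single-atom limit `n f^2`.
#'
#' @param q Scattering-vector magnitude(s), 1/angstrom.
#' @param sigma Per-axis RMS displacement, angstrom.
#' @param f0_sq `|F0(q)|^2` of the undisplaced structure.
#' @param n Number of atoms.
#' @param f Atomic scattering factor(s) at q.
#' @return A tibble with columns `bragg` and `diffuse`.
#' @export
debye_waller_decomposition <- function(q, sigma, f0_sq, n, f) {
  stopifnot(all(sigma >= 0), all(q >= 0))
  dw <- exp(-4 * pi^2 * q^2 * sigma^2)
  tibble::tibble(bragg = f0_sq * dw, diffuse = n * f^2 * (1 - dw))
}

#' Dynamic disorder function g(q, T)
#'
#' The dimensionless pulse-integrated Bragg gate
#' `g(q,T) = (1/T) integral_0^T w(t)^2 exp(-4 pi^2 q^2 sigma(t)^2) dt`:
#' the fraction of the pulse that effectively contributes to Bragg diffraction
#' at scattering vector q, gated by the RMS displacement growing past the
#' resolution cutoff or the bound-electron fraction w dropping to zero.
#' Equals 1 exactly when both damage trajectories are absent.
#'
#' @param q Scattering-vector magnitude(s), 1/angstrom; vectorized.
#' @param duration_fs Pulse duration, fs.
#' @param motion An `fx_displacement_traj` or `NULL` (no motion).
#' @param ionization An `fx_ionization_traj` or `NULL` (no ionization).
#' @param n_steps Midpoint-rule integration steps.
#' @return g values in `[0, 1]`.
#' @examples
#' sc <- demo_scenario()
#' dynamic_disorder(c(0.1, 0.3), 50, sc$motion)
#' @export
dynamic_disorder <- function(q, duration_fs, motion = NULL, ionization = NULL,
                             n_steps = 512) {
  if (is.null(motion) && is.null(ionization)) return(rep(1, length(q)))
  t <- (seq_len(n_steps) - 0.5) / n_steps * duration_fs
  sig <- if (is.null(motion)) rep(0, n_steps) else displacement_at(motion, t)
  w <- if (is.null(ionization)) rep(1, n_steps) else ionization_at(ionization, t)$w
  vapply(q, function(qi) {
    mean(w^2 * exp(-4 * pi^2 * qi^2 * sig^2))
  }, 0)
}

#' Bragg-to-diffuse contrast scale of a nanocrystal
#'
#' The per-solid-angle contrast of a Bragg peak against the diffuse
#' background scales with the ratio of the peak area to the reciprocal-cell
#' area, `1/N^2`, where N is the crystal width in unit cells.
#'
#' @param n_width Number of unit cells across the crystal.
#' @return `1 / n_width^2`.
#' @export
bragg_to_diffuse_ratio <- function(n_width) {
  stopifnot(all(n_width >= 1))
  1 / n_width^2
}

# intensity prefactor: photons/cm2 * r_e^2 * dOmega
.fx_intensity_scale <- function(pulse, d_omega) {
  pulse$photons_per_um2 / .fx$um2_cm2 * .fx$r_e_cm^2 * d_omega
}

# analytic expected bragg/diffuse (electron^2 units, no prefactor) for a
# static disorder state: per-axis sigma, bound fraction w
.fx_expected_split <- function(decomp, qmag, sigma, w) {
  dw <- exp(-4 * pi^2 * qmag^2 * sigma^2)
  fbar <- decomp$f * w
  f0bar <- rowSums(decomp$A * fbar)
  n_el <- tabulate(decomp$group, nbins = length(decomp$elements))
  diffuse <- as.vector((decomp$f^2 %*% n_el) * (w - w^2 * dw))
  list(bragg = Mod(f0bar)^2 * dw, diffuse = diffuse)
}

.fx_pattern <- function(qgrid, bragg, diffuse, realized, kind, pulse, meta) {
  out <- tibble::tibble(qgrid,
                        bragg = bragg, diffuse = diffuse,
                        intensity = bragg + diffuse,
                        realized = realized)
  structure(out, class = c("fx_pattern", class(out)),
            kind = kind, pulse = pulse, meta = meta)
}

#' Snapshot diffraction pattern
#'
#' The instantaneous pattern of a crystal in a fixed disorder state:
#' expected photons per grid node,
#' `I(q) = photons_per_area * r_e^2 * dOmega * |F(q)|^2`, split into the
#' analytic Bragg and diffuse components, plus (when a seed is given) one
#' Monte-Carlo realization with site displacements drawn as isotropic
#' Gaussians and ionization states drawn Bernoulli.
#'
#' @param crystal An [toy_crystal()].
#' @param qgrid A q-grid tibble ([q_grid_line()] / [q_grid_plane()]).
#' @param pulse A [pulse_spec()] (sets the photon fluence).
#' @param sigma Per-axis RMS displacement, angstrom.
#' @param bound_fraction Bound-electron fraction w (ionized fraction is 1-w).
#' @param seed Integer seed for the realization; `NULL` skips the draw.
#' @return An `fx_pattern` tibble: the q grid plus `bragg`, `diffuse`,
#'   `intensity` (= bragg + diffuse, the expectation) and `realized` (the
#'   seeded draw, or `NA`). Units: expected photons per node.
#' @export
snapshot_pattern <- function(crystal, qgrid, pulse, sigma = 0,
                             bound_fraction = 1, seed = NULL) {
  stopifnot(sigma >= 0, bound_fraction >= 0, bound_fraction <= 1)
  sites <- crystal_sites(crystal)
  qmat <- .fx_as_qmat(qgrid)
  scale <- .fx_intensity_scale(pulse, qgrid$d_omega)
  decomp <- .fx_phase_decomp(sites, qmat, qgrid$q)
  split <- .fx_expected_split(decomp, qgrid$q, sigma, bound_fraction)
  realized <- rep(NA_real_, nrow(qgrid))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    realized <- .fx_realize(sites, qmat, qgrid$q, sigma, bound_fraction) * scale
  }
  .fx_pattern(qgrid, split$bragg * scale, split$diffuse * scale, realized,
              kind = "snapshot", pulse = pulse,
              meta = list(sigma = sigma, bound_fraction = bound_fraction,
                          seed = seed, n_atoms = nrow(sites)))
}

# one MC |F|^2 draw (electron^2)
.fx_realize <- function(sites, qmat, qmag, sigma, w) {
  n <- nrow(sites)
  xyz <- cbind(sites$x, sites$y, sites$z)
  if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  bound <- if (w >= 1) rep(1, n) else stats::rbinom(n, 1, w)
  moved <- sites
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  d <- .fx_phase_decomp(moved, qmat, qmag, weights = sites$occupancy * bound)
  Mod(rowSums(d$A * d$f))^2
}

#' Pulse-integrated diffraction pattern
#'
#' Time-average of snapshot patterns over a flat-top pulse whose disorder
#' follows the given displacement and ionization trajectories. The analytic
#' components integrate the dynamic disorder gate:
#' Bragg `= g(q,T) |F0(q)|^2` and diffuse
#' `= sum_el n_el f_el^2 <w - w^2 DW>_t`, so Bragg peaks whose turn-off time
#' is positive remain visible in the integrated pattern even when absent from
#' the final snapshot. The Monte-Carlo column averages seeded realizations at
#' midpoint times (displacements and ionization drawn independently per
#' realization and step).
#'
#' @inheritParams snapshot_pattern
#' @param motion An `fx_displacement_traj` or `NULL`.
#' @param ionization An `fx_ionization_traj` or `NULL`.
#' @param n_steps Time steps (midpoint rule).
#' @param n_realizations Monte-Carlo realizations per step (0 skips the MC
#'   column).
#' @param seed Root seed; all stochastic output is reproducible given it.
#' @return An `fx_pattern` tibble (see [snapshot_pattern()]); `realized` is
#'   the MC average.
#' @export
pulse_integrated_pattern <- function(crystal, qgrid, pulse, motion = NULL,
                                     ionization = NULL, n_steps = 32,
                                     n_realizations = 8, seed = 1) {
  stopifnot(n_steps >= 2, n_realizations >= 0)
  sites <- crystal_sites(crystal)
  qmat <- .fx_as_qmat(qgrid)
  scale <- .fx_intensity_scale(pulse, qgrid$d_omega)
  decomp <- .fx_phase_decomp(sites, qmat, qgrid$q)
  duration <- pulse$duration_fs
  tmid <- (seq_len(n_steps) - 0.5) / n_steps * duration
  sig <- if (is.null(motion)) rep(0, n_steps) else displacement_at(motion, tmid)
  w <- if (is.null(ionization)) rep(1, n_steps) else ionization_at(ionization, tmid)$w

  bragg <- rep(0, nrow(qgrid)); diffuse <- rep(0, nrow(qgrid))
  for (k in seq_len(n_steps)) {
    s <- .fx_expected_split(decomp, qgrid$q, sig[k], w[k])
    bragg <- bragg + s$bragg / n_steps
    diffuse <- diffuse + s$diffuse / n_steps
  }

  realized <- rep(NA_real_, nrow(qgrid))
  if (n_realizations > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    acc <- rep(0, nrow(qgrid))
    for (r in seq_len(n_realizations)) {
      for (k in seq_len(n_steps)) {
        if (sig[k] == 0 && w[k] >= 1) {
          acc <- acc + .fx_expected_split(decomp, qgrid$q, 0, 1)$bragg
        } else {
          acc <- acc + .fx_realize(sites, qmat, qgrid$q, sig[k], w[k])
        }
      }
    }
    realized <- acc / (n_steps * n_realizations) * scale
  }

  .fx_pattern(qgrid, bragg * scale, diffuse * scale, realized,
              kind = "pulse_integrated", pulse = pulse,
              meta = list(n_steps = n_steps, n_realizations = n_realizations,
                          seed = seed, n_atoms = nrow(sites),
                          dose_rate_gy_fs = attr(motion, "dose_rate_gy_fs")))
}

#' Separate Bragg peaks from the diffuse background
#'
#' Background subtraction around each predicted Bragg node of a pattern
#' computed on a 1D line grid along a cell axis: counts in a window of
#' half-width `1.5/(N a)` around each node, minus the local median background
#' estimated from the flanking `1.5--3/(N a)` annulus; the diffuse map is the
#' pattern outside all peak windows.
#'
#' @param pattern An `fx_pattern` on a [q_grid_line()] along a cell axis.
#' @param crystal The crystal that produced it.
#' @param use Which column to separate: the Monte-Carlo `"realized"` pattern
#'   (default) or the analytic `"intensity"`.
#' @return A list with `peaks` (tibble: `h`, `q`, `counts`, `background`) and
#'   `diffuse` (tibble: `q`, `intensity` outside peak windows).
#' @export
separate_bragg_diffuse <- function(pattern, crystal,
                                   use = c("realized", "intensity")) {
  use <- match.arg(use)
  vals <- pattern[[use]]
  if (anyNA(vals)) stop("pattern has no '", use, "' column values", call. = FALSE)
  # identify the line axis
  ranges <- vapply(c("qx", "qy", "qz"), function(cl) diff(range(pattern[[cl]])), 0)
  axis <- which.max(ranges)
  if (sum(ranges > 1e-12) != 1) {
    stop("separate_bragg_diffuse() needs a 1D line grid along one axis",
         call. = FALSE)
  }
  a <- crystal$cell[axis]
  n_w <- crystal$n_cells[axis]
  qv <- pattern[[c("qx", "qy", "qz")[axis]]]
  spacing <- stats::median(diff(sort(qv)))
  if (spacing > 1 / (5 * n_w * a)) {
    stop("grid too coarse: need at least 5 nodes per peak width 1/(N a)",
         call. = FALSE)
  }
  half <- 1.5 / (n_w * a)
  h_all <- seq(ceiling(min(qv) * a), floor(max(qv) * a))
  h_all <- h_all[h_all != 0]
  in_any_peak <- rep(FALSE, length(qv))
  peaks <- purrr::map_dfr(h_all, function(h) {
    qh <- h / a
    inpk <- abs(qv - qh) <= half
    inbg <- abs(qv - qh) > half & abs(qv - qh) <= 2 * half
    in_any_peak <<- in_any_peak | inpk
    bg <- if (any(inbg)) stats::median(vals[inbg]) else 0
    tibble::tibble(h = h, q = qh,
                   counts = sum(vals[inpk] - bg),
                   background = bg)
  })
  list(peaks = peaks,
       diffuse = tibble::tibble(q = pattern$q[!in_any_peak],
                                intensity = vals[!in_any_peak]))
}
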