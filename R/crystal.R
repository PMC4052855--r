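## Toy crystals: orthorhombic cells, small motifs (inline or from PDB), and
## the demo nanocrystal used throughout the documentation: a 5 x 5 x 5 block
## of 25-angstrom cubic cells holding eight carbon-like pseudo-atoms per cell.

#' Define a crystal motif
#'
#' @param element Element symbols, one per atom.
#' @param x,y,z Coordinates, fractional (default) or cartesian angstrom.
#' @param occupancy Site occupancies.
#' @param fractional Are the coordinates fractions of the cell edges?
#' @return A tibble with columns `element`, `x`, `y`, `z`, `occupancy` and a
#'   `fractional` attribute.
#' @export
crystal_motif <- function(element, x, y, z, occupancy = 1, fractional = TRUE) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  out <- tibble::tibble(element = element, x = x, y = y, z = z,
                        occupancy = occupancy)
  attr(out, "fractional") <- fractional
  out
}

#' Build a toy crystal
#'
#' An orthorhombic block of `n_cells` unit cells, each holding `motif`.
#'
#' @param cell Cell edge lengths `c(a, b, c)` in angstrom (a scalar is used
#'   for all three edges).
#' @param motif A [crystal_motif()].
#' @param n_cells Integer vector `c(N1, N2, N3)` (a scalar is recycled).
#' @return An object of class `fx_crystal`.
#' @export
toy_crystal <- function(cell, motif, n_cells = c(5, 5, 5)) {
  if (length(cell) == 1) cell <- rep(cell, 3)
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 3)
  stopifnot(length(cell) == 3, all(cell > 0),
            length(n_cells) == 3, all(n_cells >= 1))
  structure(list(cell = cell, motif = motif, n_cells = as.integer(n_cells)),
            class = "fx_crystal")
}

#' @export
print.fx_crystal <- function(x, ...) {
  cat("<crystal> ", paste(x$n_cells, collapse = " x "), " cells of ",
      paste(x$cell, collapse = " x "), " A, ",
      nrow(x$motif), "-atom motif (", crystal_atom_count(x), " atoms)\n",
      sep = "")
  invisible(x)
}

#' Total atom count of a crystal
#'
#' @param crystal An [toy_crystal()].
#' @return Motif size times the number of cells.
#' @export
crystal_atom_count <- function(crystal) {
  nrow(crystal$motif) * prod(crystal$n_cells)
}

#' Expand a crystal to cartesian atom sites
#'
#' @param crystal An [toy_crystal()].
#' @return A tibble with columns `element`, `x`, `y`, `z` (angstrom),
#'   `occupancy`.
#' @export
crystal_sites <- function(crystal) {
  m <- crystal$motif
  frac <- isTRUE(attr(m, "fractional"))
  xyz <- cbind(m$x, m$y, m$z)
  if (frac) xyz <- sweep(xyz, 2, crystal$cell, `*`)
  n <- crystal$n_cells
  shifts <- as.matrix(expand.grid(a = seq_len(n[1]) - 1,
                                  b = seq_len(n[2]) - 1,
                                  c = seq_len(n[3]) - 1))
  shifts <- sweep(shifts, 2, crystal$cell, `*`)
  k <- nrow(shifts)
  tibble::tibble(
    element = rep(m$element, times = k),
    x = rep(xyz[, 1], times = k) + rep(shifts[, 1], each = nrow(m)),
    y = rep(xyz[, 2], times = k) + rep(shifts[, 2], each = nrow(m)),
    z = rep(xyz[, 3], times = k) + rep(shifts[, 3], each = nrow(m)),
    occupancy = rep(m$occupancy, times = k)
  )
}

# Fixed fractional positions of the demo motif: eight carbon-like
# pseudo-atoms at arbitrary generic positions (identical across runs).
.fx_demo_motif_xyz <- matrix(c(
  0.1234, 0.5617, 0.8312,
  0.7841, 0.2193, 0.4375,
  0.3527, 0.9081, 0.1746,
  0.6093, 0.6718, 0.7252,
  0.9365, 0.0832, 0.6521,
  0.2418, 0.3856, 0.5189,
  0.5672, 0.8249, 0.3914,
  0.0781, 0.7364, 0.0623), ncol = 3, byrow = TRUE)

#' Demo nanocrystal
#'
#' A 5 x 5 x 5 block of 25-angstrom cubic cells with eight carbon pseudo-atoms
#' per cell at fixed generic fractional positions (1000 atoms in total). The
#' motif content of such toy cells is a documented invention: only qualitative
#' behaviours of its patterns are meaningful, not per-pixel values.
#'
#' @param n_cells Cells per axis.
#' @param cell_a Cubic cell edge, angstrom.
#' @return An [toy_crystal()].
#' @export
demo_crystal <- function(n_cells = c(5, 5, 5), cell_a = 25) {
  m <- crystal_motif(rep("C", 8), .fx_demo_motif_xyz[, 1],
                     .fx_demo_motif_xyz[, 2], .fx_demo_motif_xyz[, 3])
  toy_crystal(cell_a, m, n_cells)
}

#' Demo explosion scenario
#'
#' The demo nanocrystal together with the pulse and damage trajectories of the
#' reference explosion: a 50 fs flat-top pulse at 6 keV delivering
#' 50 MGy/fs to the average protein, under which the per-axis RMS displacement
#' reaches exactly 1 angstrom at the end of the pulse. Ionization gating is
#' off by default (at 50 MGy/fs the motion gate dominates); set
#' `include_ionization = TRUE` to add the average-ionization trajectory.
#'
#' @param include_ionization Also build the ionization trajectory.
#' @return A list with elements `crystal`, `pulse`, `motion` (an
#'   `fx_displacement_traj`), `ionization` (or `NULL`), `dose_rate_gy_fs`.
#' @examples
#' sc <- demo_scenario()
#' displacement_at(sc$motion, sc$pulse$duration_fs)  # exactly 1 A
#' @export
demo_scenario <- function(include_ionization = FALSE) {
  duration_fs <- 50
  dose_rate <- 5e7  # Gy/fs
  comp <- material("avg_protein")
  photons <- photons_for_dose(dose_rate * duration_fs, comp, 6000)
  pulse <- pulse_spec(6000, photons, duration_fs)
  motion <- displacement_trajectory(dose_rate, duration_fs, motion_model())
  ion <- if (include_ionization) {
    ionization_trajectory(dose_rate, duration_fs, comp)
  }
  list(crystal = demo_crystal(), pulse = pulse, motion = motion,
       ionization = ion, dose_rate_gy_fs = dose_rate)
}

#' Read a motif from a PDB file
#'
#' Minimal reader for small atomic motifs: keeps element symbols and
#' cartesian coordinates of ATOM/HETATM records (occupancies kept;
#' B factors ignored with a message). Requires the bio3d package.
#'
#' @param path PDB file path.
#' @return A [crystal_motif()] with cartesian coordinates.
#' @export
read_motif <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_motif() needs the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- at$elesy
  if (any(is.na(elem) | !nzchar(elem))) {
    elem <- sub("^[0-9]*", "", trimws(substr(at$elety, 1, 2)))
    elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2)))
    elem <- trimws(elem)
  }
  if (any(!is.na(at$b) & at$b != 0)) {
    message("B factors present in ", basename(path), " are ignored")
  }
  crystal_motif(elem, at$x, at$y, at$z,
                occupancy = ifelse(is.na(at$o), 1, at$o), fractional = FALSE)
}
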