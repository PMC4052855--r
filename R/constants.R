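#' Physical constants used by flashxtal
#'
#' Returns the centralized set of physical constants and unit conversions the
#' package computes with. All package-internal unit conventions flow from
#' these: energies in eV, atomic lengths in angstrom, attenuation in 1/cm,
#' cross sections in barn, dose in Gy, time in fs, fluence in J/cm2.
#'
#' @return A named list:
#' \describe{
#'   \item{n_avogadro}{Avogadro constant, 1/mol.}
#'   \item{ev_joule}{1 eV in joule.}
#'   \item{barn_cm2}{1 barn in cm2 (1e-24).}
#'   \item{r_e_angstrom, r_e_cm}{Classical electron radius.}
#'   \item{m_e_kg}{Electron rest mass.}
#'   \item{hc_ev_angstrom}{Photon energy-wavelength product, eV*angstrom.}
#'   \item{coulomb_ev_angstrom}{e^2/(4 pi eps0) in eV*angstrom.}
#'   \item{um2_cm2}{1 um2 in cm2.}
#' }
#' @examples
#' xfel_constants()$hc_ev_angstrom / 6000  # wavelength (A) of a 6 keV photon
#' @export
xfel_constants <- function() {
  list(
    n_avogadro = 6.02214076e23,
    ev_joule = 1.602176634e-19,
    barn_cm2 = 1e-24,
    r_e_angstrom = 2.8179403262e-5,
    r_e_cm = 2.8179403262e-13,
    m_e_kg = 9.1093837015e-31,
    hc_ev_angstrom = 12398.425,
    coulomb_ev_angstrom = 14.3996454,
    um2_cm2 = 1e-8
  )
}

# internal shorthand
.fx <- xfel_constants()
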