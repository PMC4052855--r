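---
title: "Methods: dosimetry and diffraction models in flashxtal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry and diffraction models in flashxtal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashxtal)
```

`flashxtal` estimates what happens to a small crystal during a femtosecond
X-ray pulse and what its diffraction pattern looks like while it happens.
This vignette records the model assumptions, conventions and calibrations so
that every number the package produces can be traced to a formula.

## Dosimetry

A pulse is flat-top: `pulse_spec(energy_ev, photons_per_um2, duration_fs)`
fixes the fluence $I_0$ (J/cm²) and intensity $I_0/T$. Samples are treated
as *thin*: the absorbed dose is

$$D = I_0 \, (\mu/\rho),$$

with no depth attenuation; `xray_dose()` warns when a supplied thickness
exceeds a tenth of the absorption length. Useful derived scales:

- `one_photon_dose(el, E)` = $h\nu N_A / m_A$, the dose at which every atom
  of a pure-element sample has absorbed one photon (48.2 GGy for carbon at
  6 keV);
- `saturation_fluence(el, E)` = $h\nu/\sigma_A$, the fluence at one
  absorption per atom of that element;
- `one_photon_dose_in_matrix()` applies that fluence to a host matrix, and
  `hollow_atom_dose_rate()` divides by the K-hole Auger lifetime — the dose
  rate above which double-core-hole (hollow) atoms become probable.
  `hollow_atom_table()` tabulates both at 6 and 8 keV.

### Cross sections and calibration

`inst/extdata/xsections.csv` holds per-element photoabsorption and elastic
cross sections on a log energy grid (2–30 keV, with points on both sides of
each K edge so interpolation never smooths across an edge); interpolation is
log-log linear. Photoabsorption values derive from Henke-type tabulated
scattering factors ($\sigma_A = 2 r_e \lambda f_2$); elastic cross sections
integrate the Thomson cross section weighted by the squared IT92 form factor
over the sphere. One global calibration factor (1.03015) is applied to all
photoabsorption values so that the average protein
(H₅₀C₃₀N₉O₁₀S₁, 1.35 g/cm³) has exactly $\mu = 32.5\ \mathrm{cm^{-1}}$ at
6 keV, a standard reference value; because the factor is uniform, all
*ratios* of cross sections (and hence in-matrix one-photon doses) are
unaffected by it.

The supporting tables are regenerated by `data-raw/generate_tables.py`.

## Ionization dynamics

A K-shell photoionization at 6 keV ejects a 5716 eV photoelectron
(`photoelectron_energy()`, speed ≈ 450 Å/fs) whose collisional cascade
thermalizes in about 10 fs and produces roughly one ionization per
**21 eV** of deposited energy (`cascade_model()`; yields of ~240 at 5 keV
and ~285 at 6 keV, with a 10/240 core-shell fraction). The average
ionization per atom under a flat-top pulse follows the closed form

$$z(t) = \frac{r_{\mathrm{eV}}}{\varepsilon}\left(t - \tau\,(1 - e^{-t/\tau})\right),
\qquad w(t) = 1 - z(t)/\bar Z,$$

capped at the mean electron count $\bar Z$ per atom, where
$r_{\mathrm{eV}}$ is the dose rate in eV/atom/fs, $\varepsilon = 21$ eV and
$\tau = 10$ fs (`ionization_trajectory()`). For a given dose rate the
trajectory is independent of photon energy. The time to full stripping is
parameterized as an anchored power law,

$$t_{\mathrm{tr}}(R) = 3\ \mathrm{fs} \times (R / 60\ \mathrm{GGy/fs})^{-2/3},$$

(`transparency_time()`), which makes the achievable dose $R\,t_{\mathrm{tr}}$
grow as $R^{1/3}$. `escape_threshold()` gives the order-of-magnitude net
charge per atom at which photoelectrons can no longer leave a small particle.

## Atomic motion

The per-axis RMS displacement is a calibrated power law
(`motion_model()`, `rms_displacement()`):

$$\sigma(t) = C\, R^{\alpha} t^{\beta},$$

with $R$ in GGy/fs and two exponent presets: `"diffusion"`
($\alpha = 1/2, \beta = 3/2$, the default; turn-off time $\propto R^{-1/3}$,
effective dose $\propto R^{2/3}$) and `"wavelength"`
($\alpha = 1/3, \beta = 4/3$; turn-off time $\propto R^{-1/4}$, which is the
set the wavelength-scaling analysis uses). $C$ is calibrated so that
$\sigma = 1$ Å at the end of a 50 fs pulse at 50 MGy/fs — the package's
reference explosion scenario (`demo_scenario()`).

A Bragg peak at scattering vector $q$ effectively turns off when
$\sigma(t) = 1/(2\pi q)$ (`turnoff_time()`); `effective_dose()` multiplies
the dose rate by the earlier of the motion turn-off and the ionization
transparency time. `correlated_motion_observable()` implements the coherence
criterion that a correlated displacement must cover more than $2\pi\sigma$
before the corresponding peak gates.

## Diffraction

Conventions: $q = 2\sin\theta/\lambda$ (so $q = 1/d$), phases
$e^{+2\pi i\, q\cdot x}$, per-axis $\sigma$ in the Debye-Waller factor
$e^{-4\pi^2 q^2 \sigma^2}$, IT92 four-Gaussian form factors, no polarization
factor, and expected photons per detector node
$I(q) = N_{\mathrm{ph}}\, r_e^2\, \Delta\Omega\, |F(q)|^2$.

Ionization uses a **binary population**: each atom is independently either
neutral (factor $f$) or fully stripped (factor 0) with bound probability
$w$; ionized factors elsewhere scale proportionally
(`scattering_factor(..., bound_fraction)`), a low-resolution approximation.
For independent Gaussian displacements and Bernoulli stripping the exact
expectation of the intensity decomposes into a Bragg and a diffuse part:

$$\mathbb{E}|F|^2 = w^2 e^{-k}\,|F_0|^2
  + \sum_{\mathrm{el}} n_{\mathrm{el}}\, f_{\mathrm{el}}^2\,(w - w^2 e^{-k}),
\qquad k = 4\pi^2 q^2 \sigma^2.$$

`snapshot_pattern()` evaluates both the analytic split and (when seeded) a
Monte-Carlo realization drawn from the same primitives, so the two can be
compared statistically — the test suite does this to three standard errors.
`pulse_integrated_pattern()` averages the split over midpoint times of the
pulse using the damage trajectories; its Bragg column equals the static
pattern scaled by the gate

$$g(q, T) = \frac{1}{T}\int_0^T w(t)^2\, e^{-4\pi^2 q^2 \sigma(t)^2}\, dt$$

(`dynamic_disorder()`), which is 1 for an undamaged crystal, monotone in
$q$, and tends to $t_{\mathrm{off}}/T$ for a sharp displacement ramp.
Integrated over a full reciprocal cell, Bragg plus diffuse is independent of
$\sigma$: disorder redistributes elastic photons without creating or
destroying them. The Bragg-to-diffuse contrast per solid angle scales as
$1/N^2$ for a crystal $N$ cells wide (`bragg_to_diffuse_ratio()`).

`separate_bragg_diffuse()` integrates peak windows of half-width
$1.5/(Na)$ around reciprocal-lattice nodes of a 1D line grid, subtracting a
median background from the surrounding annulus; it refuses grids coarser
than five nodes per peak width rather than mis-integrating.

## Wavelength scaling

At fixed pulse energy the total Bragg signal factorizes into available
photons ($\propto \lambda$), scattered photons per fluence
($\propto \lambda^3$), and the gating time: $\lambda^{-3/4}$ while motion
gates (total exponent $13/4$: halving the wavelength from 4 keV to 8 keV
costs a factor $2^{13/4} \approx 9.5$) and $\lambda^{-2}$ once ionization
gates (total exponent 2). `classify_regime()` places the boundary between
the regimes at 0.1–1 GGy/fs and flags the transition band.
`scan_wavelength()` tabulates the trade-off and flags energies within
200 eV of a constituent K edge, where the smooth scaling breaks down.

## Problem sizes and determinism

The bundled demo crystal is 5 × 5 × 5 cubic cells of 25 Å holding eight
carbon-like pseudo-atoms at fixed generic positions (1000 atoms): large
enough to show sharp peaks, diffuse floors and $1/N^2$ contrast, small
enough that a 320-node line pattern with 32 time steps and 8 realizations
completes in seconds. Its motif content is an invention — only qualitative
pattern behaviour is meaningful. All Monte-Carlo entry points take explicit
seeds and restore the caller's RNG state; every analytic quantity is
deterministic.

## Limitations

- Flat-top pulses only; no SASE temporal structure.
- Thin-sample dosimetry; no depth or lateral beam profile.
- The ionization population is binary (neutral/stripped); partial charge
  states and form-factor shape changes are folded into a proportional
  scaling, adequate at resolutions coarser than ~1.7 Å.
- Displacements are isotropic, independent Gaussians; correlated motion is
  covered only by an observability criterion, not simulated.
- The transparency-time and displacement power laws are calibrated
  parameterizations of plasma-simulation behaviour, not first-principles
  results; their anchors are documented above and first-class parameters in
  the API.
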