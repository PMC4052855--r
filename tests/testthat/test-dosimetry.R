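# Pulse arithmetic and dose calculators against closed-form hand sums.

ev_j <- 1.602176634e-19
n_a <- 6.02214076e23

test_that("pulse fluence and intensity follow from first principles", {
  p <- pulse_spec(6000, 1e12, 40)
  # 1e12 photons/um2 * 6 keV -> J/cm2 (1 cm2 = 1e8 um2)
  expect_equal(fluence(p), 1e12 * 6000 * ev_j * 1e8)
  expect_equal(pulse_intensity(p), fluence(p) / (40 * 1e-15))
  expect_error(pulse_spec(-1, 1e12, 40))
  expect_output(print(p), "6 keV")
})

test_that("photon_count needs a beam area", {
  p <- pulse_spec(6000, 1e12, 40, beam_area_um2 = 2)
  expect_equal(photon_count(p), 2e12)
  expect_error(photon_count(pulse_spec(6000, 1e12, 40)), "beam_area")
})

test_that("xray_dose equals fluence times mass attenuation", {
  prot <- material("avg_protein")
  p <- pulse_spec(6000, 1e12, 40)
  expect_equal(xray_dose(p, prot),
               fluence(p) * mass_attenuation(prot, 6000) * 1e3)
  expect_equal(dose_rate(p, prot), xray_dose(p, prot) / 40)
  # thin-sample warning once thickness approaches the absorption length
  expect_warning(xray_dose(p, prot, thickness_um = 100), "thin-sample")
  expect_silent(xray_dose(p, prot, thickness_um = 10))
})

test_that("dose <-> eV/atom conversions invert each other", {
  prot <- material("avg_protein")
  expect_equal(ev_per_atom_to_dose(dose_to_ev_per_atom(1e6, prot), prot), 1e6)
  # hand sum: 1 MGy * mean mass / N_A in eV
  expect_equal(dose_to_ev_per_atom(1e6, prot),
               1e6 * mean_atomic_mass(prot) * 1e-3 / n_a / ev_j)
})

test_that("one-photon dose and saturation fluence identities", {
  # D1 = hnu * N_A / m_A, independent of the cross-section tables
  expect_equal(one_photon_dose("C", 6000),
               6000 * ev_j * n_a / (12.011e-3))
  # saturation fluence = hnu / sigma_A
  expect_equal(saturation_fluence("C", 6000),
               6000 * ev_j / (cross_section("C", 6000) * 1e-24))
  # in-matrix dose: saturation fluence times matrix mu/rho
  prot <- material("avg_protein")
  expect_equal(one_photon_dose_in_matrix("C", 6000, prot),
               saturation_fluence("C", 6000) *
                 mass_attenuation(prot, 6000) * 1e3)
})

test_that("hollow-atom table is rate * tau = D1 consistent", {
  tab <- hollow_atom_table(material("avg_protein"))
  expect_equal(tab$hollow_rate_ggy_fs * tab$tau_auger_fs, tab$d1_ggy)
  expect_setequal(unique(tab$element), c("C", "N", "O", "S", "Mn", "Fe"))
  expect_setequal(unique(tab$energy_ev), c(6000, 8000))
})

test_that("adiabatic heating and inverse dose helpers", {
  expect_equal(adiabatic_heating(1e6), 1e6 / 4800)
  expect_equal(adiabatic_heating(2e6, heat_capacity = 4184), 2e6 / 4184)
  prot <- material("avg_protein")
  n_ph <- photons_for_dose(1e6, prot, 6000)
  expect_equal(xray_dose(pulse_spec(6000, n_ph, 40), prot), 1e6)
  expect_equal(bond_break_dose(4, prot), ev_per_atom_to_dose(4, prot))
})

test_that("dose_report is a deterministic one-row tibble", {
  p <- pulse_spec(6000, 1e12, 40)
  rep1 <- dose_report(p, "avg_protein")
  rep2 <- dose_report(p, "avg_protein")
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 1)
  expect_true(all(c("dose_gy", "dose_rate_gy_fs", "regime",
                    "absorption_length_um") %in% names(rep1)))
  expect_equal(rep1$dose_gy, xray_dose(p, material("avg_protein")))
})
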