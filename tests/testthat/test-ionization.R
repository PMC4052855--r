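# Photoelectron energetics, cascades, counts and ionization trajectories.

test_that("photoelectron energy and speed", {
  expect_equal(photoelectron_energy(6000, "C"), 6000 - 284.2)
  expect_error(photoelectron_energy(200, "C"), "K edge")
  # speed from first principles: sqrt(2 E / m_e), in angstrom/fs
  e_j <- 5715.8 * 1.602176634e-19
  v_ms <- sqrt(2 * e_j / 9.1093837015e-31)
  expect_equal(electron_speed(5715.8), v_ms * 1e10 * 1e-15, tolerance = 1e-10)
})

test_that("cascade yields follow the energy budget", {
  y <- cascade_yield(c(5000, 6000))
  expect_equal(y$total, c(5000, 6000) / 21)
  expect_equal(y$core_shell, y$total * 10 / 240)
  # custom model parameters propagate
  m <- cascade_model(eps_ion_ev = 25)
  expect_equal(cascade_yield(5000, m)$total, 200)
  # time curve saturates to the yield
  expect_equal(cascade_curve(1e4, 5000), 5000 / 21, tolerance = 1e-6)
  expect_equal(cascade_curve(0, 5000), 0)
  expect_true(all(diff(cascade_curve(seq(0, 30, 1), 5000)) > 0))
})

test_that("photoionization counts match the hand-summed oracle", {
  prot <- material("avg_protein")
  p <- pulse_spec(6000, 4e8, 40)
  counts <- photoionization_counts(p, prot, volume_um3 = 1)
  # oracle: atoms per element from density/mass, times sigma * I0
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  stoich <- c(H = 50, C = 30, N = 9, O = 10, S = 1)
  mass_g <- 1.35 * 1e-12
  n_atoms <- mass_g * 6.02214076e23 / sum(stoich * masses) * stoich
  i0 <- 4e8 / 1e-8  # photons/cm2
  for (el in names(stoich)) {
    sig <- cross_section(el, 6000) * 1e-24
    expect_equal(counts$photoionizations[counts$element == el],
                 unname(n_atoms[el]) * sig * i0)
    sig_s <- cross_section(el, 6000, kind = "elastic") * 1e-24
    expect_equal(counts$scattered[counts$element == el],
                 unname(n_atoms[el]) * sig_s * i0)
  }
})

test_that("sampled counts are seeded Poisson draws around the expectation", {
  prot <- material("avg_protein")
  p <- pulse_spec(6000, 4e8, 40)
  s1 <- photoionization_counts(p, prot, 1, sample = TRUE, seed = 42)
  s2 <- photoionization_counts(p, prot, 1, sample = TRUE, seed = 42)
  expect_identical(s1, s2)
  mu <- photoionization_counts(p, prot, 1)
  # Poisson: |draw - mean| within 6 sqrt(mean) (counts are > 60 here)
  expect_true(all(abs(s1$photoionizations - mu$photoionizations) <
                    6 * sqrt(mu$photoionizations)))
})

test_that("ionization trajectory follows the closed form and caps at z_max", {
  prot <- material("avg_protein")
  r <- 1e9
  tr <- ionization_trajectory(r, 40, prot)
  r_ev <- dose_to_ev_per_atom(r, prot)
  z_hand <- pmin(r_ev / 21 * (tr$t_fs - 10 * (1 - exp(-tr$t_fs / 10))),
                 mean_electrons_per_atom(prot))
  expect_equal(tr$z, z_hand)
  expect_equal(tr$w, pmax(1 - tr$z / mean_electrons_per_atom(prot), 0))
  expect_true(all(diff(tr$z) >= 0))
  # very high rate fully strips
  hot <- ionization_trajectory(1e12, 40, prot)
  expect_equal(max(hot$z), mean_electrons_per_atom(prot))
  expect_equal(min(hot$w), 0)
  # ionization_at agrees with the stored grid
  at <- ionization_at(tr, tr$t_fs)
  expect_equal(at$z, tr$z)
})

test_that("one-electron dose sits in the few-hundred-MGy range", {
  d <- one_electron_dose()
  expect_gt(d, 2.8e8)
  expect_lt(d, 4e8)
  # shorter pulses need more dose (cascade has less time to develop)
  expect_gt(one_electron_dose(duration_fs = 20), d)
  # infinite-time limit: exactly eps_ion per atom
  expect_equal(one_electron_dose(duration_fs = 1e6),
               ev_per_atom_to_dose(21, material("avg_protein")),
               tolerance = 1e-4)
})

test_that("valence saturation dose is about 1.3 GGy for protein", {
  d <- valence_saturation_dose()
  expect_equal(d / 1e9, 1.3, tolerance = 0.05)
  expect_equal(valence_saturation_dose(ev_per_atom = 50), d / 2)
})

test_that("transparency time is an anchored -2/3 power law", {
  expect_equal(transparency_time(60e9), 3)
  expect_equal(transparency_time(60e9 / 8), 3 * 8^(2/3))
  # achievable dose R * t_tr grows as R^(1/3)
  r <- c(1e9, 8e9)
  gain <- (r[2] * transparency_time(r[2])) / (r[1] * transparency_time(r[1]))
  expect_equal(gain, 2)
})

test_that("escape threshold decreases with particle size", {
  prot <- material("avg_protein")
  e_pe <- photoelectron_energy(6000, "C")
  th <- vapply(c(8, 16, 100), escape_threshold, 0,
               comp = prot, e_electron_ev = e_pe)
  expect_true(all(diff(th) < 0))
  # small particles can lose of order one electron per atom
  expect_gt(th[1], 0.1)
  expect_lt(th[1], 1)
})
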