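# Compositions, bundled element data and cross-section interpolation.

test_that("parse_formula handles counts, repeats and errors", {
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("H50C30N9O10S1"),
               c(H = 50, C = 30, N = 9, O = 10, S = 1))
  # repeated symbols accumulate
  expect_equal(parse_formula("CHC"), c(C = 2, H = 1))
  # fractional counts allowed
  expect_equal(parse_formula("C0.5O1.5"), c(C = 0.5, O = 1.5))
  expect_error(parse_formula("Xx3"), "unknown element")
  expect_error(parse_formula("h2o"), "could not parse")
})

test_that("composition() and material() build consistent objects", {
  prot <- material("avg_protein")
  expect_s3_class(prot, "fx_composition")
  expect_equal(prot$density, 1.35)
  expect_equal(unname(prot$counts[c("H", "C", "N", "O", "S")]),
               c(50, 30, 9, 10, 1))
  same <- composition("H50C30N9O10S1", density = 1.35)
  expect_equal(mean_atomic_mass(same), mean_atomic_mass(prot))
  expect_equal(material("water")$counts, c(H = 2, O = 1))
  expect_error(material("steel"))
  expect_output(print(prot), "avg_protein")
})

test_that("mean atomic mass and electron count match hand sums", {
  prot <- material("avg_protein")
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  zs <- c(H = 1, C = 6, N = 7, O = 8, S = 16)
  counts <- c(H = 50, C = 30, N = 9, O = 10, S = 1)
  expect_equal(mean_atomic_mass(prot),
               sum(masses * counts) / sum(counts))
  expect_equal(mean_electrons_per_atom(prot),
               sum(zs * counts) / sum(counts))
})

test_that("attenuation pins and absorption length", {
  prot <- material("avg_protein")
  mu <- attenuation_coefficient(prot, 6000)
  expect_equal(mu, 32.5, tolerance = 0.03)
  expect_equal(absorption_length(prot, 6000), 1e4 / mu)
  # mass attenuation is density-independent
  thin <- composition("H50C30N9O10S1", density = 0.5)
  expect_equal(mass_attenuation(thin, 6000), mass_attenuation(prot, 6000))
  expect_equal(attenuation_coefficient(thin, 6000), mu * 0.5 / 1.35)
  expect_error(attenuation_coefficient(composition("H2O"), 6000), "density")
})

test_that("photoabsorption cross sections decrease with energy off-edge", {
  e <- c(3000, 4000, 6000, 8000, 10000)
  s <- cross_section("C", e)
  expect_true(all(diff(s) < 0))
  # roughly E^-3 between 6 and 8 keV
  slope <- log(s[4] / s[3]) / log(8000 / 6000)
  expect_gt(slope, -3.5)
  expect_lt(slope, -2.5)
})

test_that("cross-section interpolation is log-log between grid points", {
  tab <- cross_section_table()
  ct <- tab[tab$element == "C", ]
  i <- findInterval(6100, ct$energy_ev)
  e1 <- ct$energy_ev[i]; e2 <- ct$energy_ev[i + 1]
  s1 <- ct$sigma_abs_barn[i]; s2 <- ct$sigma_abs_barn[i + 1]
  expected <- exp(log(s1) + (log(6100) - log(e1)) / (log(e2) - log(e1)) *
                    (log(s2) - log(s1)))
  expect_equal(cross_section("C", 6100), expected)
  expect_error(cross_section("C", 1), "range")
  expect_error(cross_section("C", 1e9), "range")
})

test_that("elastic cross sections exist and are much smaller than photo", {
  s_ph <- cross_section("C", 6000)
  s_el <- cross_section("C", 6000, kind = "elastic")
  expect_gt(s_ph / s_el, 10)
  expect_gt(s_el, 0)
})

test_that("scattering factors: f(0) = Z, decreasing, scaled by bound fraction", {
  zs <- c(H = 1, C = 6, N = 7, O = 8, S = 16)
  for (el in names(zs)) {
    expect_equal(scattering_factor(el, 0), unname(zs[el]), tolerance = 0.01)
  }
  f <- scattering_factor("C", c(0, 0.2, 0.5, 1))
  expect_true(all(diff(f) < 0))
  expect_equal(scattering_factor("C", 0.3, bound_fraction = 0.5),
               0.5 * scattering_factor("C", 0.3))
})

test_that("element data accessors", {
  expect_equal(kshell_energy("C"), 284.2)
  expect_equal(auger_lifetime("C"), 10)
  expect_equal(auger_lifetime("Fe"), 0.55)
  expect_error(auger_lifetime("H"), "Auger")
  expect_error(kshell_energy("Zz"), "unknown element")
  ed <- element_data()
  expect_true(all(c("symbol", "mass_g_mol", "e_k_ev") %in% names(ed)))
})
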