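# Structure factors, analytic Bragg/diffuse decompositions and their
# Monte-Carlo counterparts, peak shapes and peak/background separation.

test_that("q grids are well formed and respect the Ewald bound", {
  g <- q_grid_line(0.5, 100)
  expect_equal(nrow(g), 100)
  expect_equal(g$q, sqrt(g$qx^2 + g$qy^2 + g$qz^2))
  expect_error(q_grid_line(3, 50, wavelength = 1), "backscattering")
  p <- q_grid_plane(0.3, 11)
  expect_equal(nrow(p), 121)
  expect_true(all(p$qz == 0))
})

test_that("structure factor matches closed forms for 1 and 2 atoms", {
  one <- crystal_motif("C", 0, 0, 0, fractional = FALSE)
  q <- c(0.2, 0.1, 0.05)
  f <- scattering_factor("C", sqrt(sum(q^2)))
  expect_equal(structure_factor(one, q), complex(real = f, imaginary = 0))
  # two atoms separated by d: |F|^2 = 2 f^2 (1 + cos(2 pi q . d))
  two <- crystal_motif(c("C", "C"), c(0, 3), c(0, 1), c(0, 2),
                       fractional = FALSE)
  fq <- structure_factor(two, q)
  phase <- 2 * pi * sum(q * c(3, 1, 2))
  expect_equal(Mod(fq)^2, 2 * f^2 * (1 + cos(phase)))
  # bound_fraction scales F linearly
  expect_equal(structure_factor(two, q, bound_fraction = 0.5), fq * 0.5)
})

test_that("ionization mixture decomposition equals the exact enumeration", {
  # three atoms, each independently ionized with probability x:
  # enumerate all 2^3 states and average |F|^2 exactly
  x <- 0.3; f0 <- 6; df <- 6
  pos <- matrix(c(0, 0, 0, 2.1, 0.3, 1.0, 4.7, 3.3, 0.9), ncol = 3,
                byrow = TRUE)
  q <- c(0.21, 0.13, 0.08)
  ph <- exp(2i * pi * as.vector(pos %*% q))
  states <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1)
  e_i2 <- 0
  for (k in seq_len(nrow(states))) {
    b <- as.numeric(states[k, ])
    pr <- prod(ifelse(b == 1, x, 1 - x))
    e_i2 <- e_i2 + pr * Mod(sum((f0 - b * df) * ph))^2
  }
  dec <- ionization_mixture_decomposition(3, x, f0, df,
                                          lattice_sum_sq = Mod(sum(ph))^2)
  expect_equal(dec$bragg + dec$diffuse, e_i2)
})

test_that("Debye-Waller decomposition conserves the total at every q", {
  q <- seq(0.05, 0.5, 0.05)
  f <- scattering_factor("C", q)
  f0_sq <- (10 * f)^2  # an in-phase 10-atom reference
  dec <- debye_waller_decomposition(q, sigma = 0.5, f0_sq = f0_sq,
                                    n = 10, f = f)
  # bragg decays, diffuse grows, undisplaced limit recovers f0_sq
  expect_true(all(diff(dec$bragg / f0_sq) < 0))
  dec0 <- debye_waller_decomposition(q, 0, f0_sq, 10, f)
  expect_equal(dec0$bragg, f0_sq)
  expect_equal(dec0$diffuse, rep(0, length(q)))
  # strong-disorder limit: all intensity diffuse, n f^2
  dec_inf <- debye_waller_decomposition(q, 50, f0_sq, 10, f)
  expect_equal(dec_inf$diffuse, 10 * f^2, tolerance = 1e-6)
})

test_that("dynamic disorder g(q,T) is a proper gate", {
  sc <- demo_scenario(include_ionization = TRUE)
  q <- c(0.05, 0.1, 0.2, 0.4)
  g <- dynamic_disorder(q, 50, sc$motion, sc$ionization)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) < 0))
  expect_equal(dynamic_disorder(q, 50), rep(1, 4))
})

test_that("snapshot MC realization is unbiased against the analytic split", {
  sc <- demo_scenario()
  grid <- q_grid_line(0.5, 80)
  totals <- vapply(1:20, function(i) {
    sum(snapshot_pattern(demo_crystal(), grid, sc$pulse, sigma = 0.5,
                         bound_fraction = 0.9, seed = 5000 + i)$realized)
  }, 0)
  expected <- sum(snapshot_pattern(demo_crystal(), grid, sc$pulse,
                                   sigma = 0.5, bound_fraction = 0.9)$intensity)
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("snapshot pattern: scaling, determinism and limits", {
  sc <- demo_scenario()
  grid <- q_grid_line(0.4, 40)
  p1 <- snapshot_pattern(demo_crystal(), grid, sc$pulse, sigma = 0.3, seed = 7)
  p2 <- snapshot_pattern(demo_crystal(), grid, sc$pulse, sigma = 0.3, seed = 7)
  expect_identical(p1, p2)
  expect_equal(p1$intensity, p1$bragg + p1$diffuse)
  # intensity is linear in fluence
  half <- pulse_spec(6000, sc$pulse$photons_per_um2 / 2, 50)
  ph <- snapshot_pattern(demo_crystal(), grid, half, sigma = 0.3)
  expect_equal(ph$intensity, p1$intensity / 2)
  # no damage: diffuse identically zero
  p0 <- snapshot_pattern(demo_crystal(), grid, sc$pulse)
  expect_equal(p0$diffuse, rep(0, 40))
})

test_that("pulse-integrated pattern matches the g(q,T)-weighted analytics", {
  sc <- demo_scenario()
  grid <- q_grid_line(0.4, 60)
  pat <- pulse_integrated_pattern(demo_crystal(), grid, sc$pulse,
                                  motion = sc$motion, n_steps = 64,
                                  n_realizations = 4, seed = 9)
  # Bragg column equals the static pattern scaled by g(q, T)
  static <- snapshot_pattern(demo_crystal(), grid, sc$pulse)
  g <- dynamic_disorder(grid$q, 50, sc$motion, n_steps = 64)
  expect_equal(pat$bragg, static$bragg * g, tolerance = 1e-10)
  # determinism
  pat2 <- pulse_integrated_pattern(demo_crystal(), grid, sc$pulse,
                                   motion = sc$motion, n_steps = 64,
                                   n_realizations = 4, seed = 9)
  expect_identical(pat, pat2)
})

test_that("Bragg peak width scales inversely with crystal size", {
  # analytic bragg profile around the h=2 node for N=3 and N=6 cells of a
  # one-atom cell (so the motif factor does not modulate the line shape)
  a <- 25
  fwhm <- vapply(c(3, 6), function(nw) {
    cr <- toy_crystal(a, crystal_motif("C", 0.3, 0.4, 0.2),
                      n_cells = c(nw, 1, 1))
    grid <- q_grid_line(2 / a + 0.02, 400, q_min = 2 / a - 0.02)
    pulse <- pulse_spec(6000, 1e10, 50)
    pat <- snapshot_pattern(cr, grid, pulse)
    half <- max(pat$bragg) / 2
    diff(range(grid$q[pat$bragg > half]))
  }, 0)
  expect_equal(fwhm[1] / fwhm[2], 2, tolerance = 0.15)
  expect_equal(bragg_to_diffuse_ratio(c(1, 5)), c(1, 1 / 25))
})

test_that("separation recovers peaks at reciprocal-lattice nodes", {
  sc <- demo_scenario()
  grid <- q_grid_line(0.5, 320)
  pat <- pulse_integrated_pattern(demo_crystal(), grid, sc$pulse,
                                  motion = sc$motion, n_steps = 16,
                                  n_realizations = 8, seed = 21)
  sep <- separate_bragg_diffuse(pat, demo_crystal())
  expect_equal(sep$peaks$q, sep$peaks$h / 25)
  # MC peak counts track the analytic decomposition within 5%
  sep_a <- separate_bragg_diffuse(pat, demo_crystal(), use = "intensity")
  expect_equal(sep$peaks$counts / sep_a$peaks$counts,
               rep(1, nrow(sep$peaks)), tolerance = 0.05)
  # coarse grids are rejected rather than silently mis-integrated
  coarse <- pulse_integrated_pattern(demo_crystal(), q_grid_line(0.5, 60),
                                     sc$pulse, motion = sc$motion,
                                     n_steps = 8, n_realizations = 1, seed = 1)
  expect_error(separate_bragg_diffuse(coarse, demo_crystal()), "too coarse")
})

test_that("autoplot methods return ggplot objects", {
  sc <- demo_scenario(include_ionization = TRUE)
  expect_s3_class(ggplot2::autoplot(sc$motion), "ggplot")
  expect_s3_class(ggplot2::autoplot(sc$ionization), "ggplot")
  pat <- snapshot_pattern(demo_crystal(), q_grid_line(0.4, 30), sc$pulse)
  expect_s3_class(ggplot2::autoplot(pat), "ggplot")
})
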