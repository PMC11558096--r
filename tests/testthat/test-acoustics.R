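# Acoustics: contrast factor, radiation force, node structure, migration.

test_that("acoustic contrast factor: matched medium, gold oracle, rigid limit,
           monotonicity in particle density", {
  m <- water_medium()
  matched <- particle_spec(20e-9, m$density, m$compressibility)
  expect_equal(acoustic_contrast_factor(matched, m), 0)

  # gold in water at rho_m = 1000: 1 + 3*18320/39640, rigid (beta_p = 0);
  # frozen from an independent hand/script evaluation
  m1000 <- medium_spec(density = 1000, sound_speed = 1497,
                       dynamic_viscosity = 8.9e-4, temperature = 298)
  gold <- particle_spec(20e-9, 19320, 0)
  expect_equal(acoustic_contrast_factor(gold, m1000), 2.386478304742684,
               tolerance = 1e-12)

  # rigid particles at least as dense as the medium attract to nodes
  for (rho_p in c(997, 1200, 2650, 19320)) {
    p <- particle_spec(20e-9, rho_p, 0)
    expect_gt(acoustic_contrast_factor(p, m), 0)
  }

  # Phi is monotone increasing in rho_p for fixed medium and beta_p
  rhos <- seq(200, 25000, length.out = 60)
  phis <- vapply(rhos, function(r) {
    acoustic_contrast_factor(particle_spec(20e-9, r, 0), m)
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("standing-wave field invariants and resonance predicate", {
  f <- fundamental_field()
  expect_equal(f$wavelength * f$wavenumber, 2 * pi, tolerance = 1e-12)
  expect_true(is_resonant(f))
  expect_identical(mode_number(f), 1L)

  f3 <- standing_wave_field(1e5, cavity_length = 3 * f$wavelength / 2,
                            sound_speed = f$sound_speed)
  expect_identical(mode_number(f3), 3L)

  off <- standing_wave_field(1e5, cavity_length = 1.13 * f$wavelength / 2,
                             sound_speed = f$sound_speed)
  expect_false(is_resonant(off))
  expect_error(pressure_nodes(off), "not resonant")
})

test_that("primary radiation force: zeros, sign convention, symmetry, fixture", {
  m <- water_medium()
  p <- gold_nanoparticle()          # 40 nm
  f <- fundamental_field(pressure_amplitude = 1e5)
  lam <- f$wavelength

  # F = 0 exactly where sin(2kx) = 0 (nodes and antinodes)
  expect_equal(primary_radiation_force(c(0, lam / 4, lam / 2), p, m, f),
               c(0, 0, 0), tolerance = 1e-25)

  # matched contrast kills the force everywhere
  matched <- particle_spec(20e-9, m$density, m$compressibility)
  xs <- seq(0, f$cavity_length, length.out = 33)
  expect_equal(primary_radiation_force(xs, matched, m, f), rep(0, 33))

  # frozen regression fixture: Pa = 1e5 Pa, 40 nm gold, water, 700 kHz,
  # x = lambda/8; magnitude pi*Pa^2*Vp*beta_m/(2*lambda)*Phi, direction
  # toward the node at lambda/4 (positive x)
  expect_equal(primary_radiation_force(lam / 8, p, m, f),
               2.629383043819751e-19, tolerance = 1e-12)

  # period lambda/2 and odd symmetry about the node
  node <- f$cavity_length / 2
  for (delta in c(1e-5, 5e-5, 2e-4)) {
    expect_equal(primary_radiation_force(node + delta, p, m, f),
                 -primary_radiation_force(node - delta, p, m, f),
                 tolerance = 1e-12)
  }
  f2 <- standing_wave_field(1e5, cavity_length = lam,
                            sound_speed = f$sound_speed)
  x0 <- lam / 16
  expect_equal(primary_radiation_force(x0, p, m, f2),
               primary_radiation_force(x0 + lam / 2, p, m, f2),
               tolerance = 1e-12)

  # restoring about the node for Phi > 0
  expect_lt(primary_radiation_force(node + 1e-5, p, m, f), 0)
  expect_gt(primary_radiation_force(node - 1e-5, p, m, f), 0)
})

test_that("pressure node structure: fundamental single node, mode m count,
           antinode trapping for negative contrast", {
  f1 <- fundamental_field()
  nodes1 <- pressure_nodes(f1, contrast_sign = 1)
  expect_length(nodes1, 1)
  expect_equal(nodes1, f1$cavity_length / 2)

  f2 <- standing_wave_field(1e5, cavity_length = f1$wavelength,
                            sound_speed = f1$sound_speed)
  expect_length(pressure_nodes(f2, 1), 2)
  expect_equal(pressure_nodes(f2, 1),
               c(f2$wavelength / 4, 3 * f2$wavelength / 4))

  # negative contrast: stable at interior antinodes (none for fundamental)
  expect_length(pressure_nodes(f1, -1), 0)
  expect_equal(pressure_nodes(f2, -1), f2$wavelength / 2)

  for (mode in 1:5) {
    fm <- standing_wave_field(1e5, cavity_length = mode * f1$wavelength / 2,
                              sound_speed = f1$sound_speed)
    expect_length(pressure_nodes(fm, 1), mode)
  }
})

test_that("migration: stationary at node, mirror symmetry, full convergence,
           Lyapunov descent, reproducibility, dt guard", {
  m <- water_medium()
  p <- cluster_particle()
  f <- fundamental_field()
  node <- f$cavity_length / 2

  # particle starting exactly at the node stays put
  tr <- simulate_migration(node, p, m, f, duration = 5, dt = 0.05)
  expect_equal(max(abs(tr$positions - node)), 0, tolerance = 1e-12)

  # mirror-symmetric trajectories about the node (brownian off)
  delta <- f$wavelength / 10
  tr2 <- simulate_migration(c(node - delta, node + delta), p, m, f,
                            duration = 20, dt = 0.05)
  expect_equal(tr2$positions[1, ] - node, node - tr2$positions[2, ],
               tolerance = 1e-9 * f$cavity_length)

  # 100 particles, uniform deterministic spread, sufficient duration:
  # everyone converges, and the distance to the node never increases
  init <- (seq_len(100) - 0.5) / 100 * f$cavity_length
  tr3 <- simulate_migration(init, p, m, f, duration = 60, dt = 0.05)
  expect_equal(tr3$converged_fraction, 1.0)
  dists <- abs(tr3$positions - node)
  expect_true(all(t(apply(dists, 1, diff)) <= 1e-12))

  # deterministic and Brownian runs are bit-reproducible under a seed
  tr4a <- simulate_migration(init[1:10], p, m, f, duration = 5, dt = 0.05,
                             brownian = TRUE, seed = 99)
  tr4b <- simulate_migration(init[1:10], p, m, f, duration = 5, dt = 0.05,
                             brownian = TRUE, seed = 99)
  expect_identical(tr4a$positions, tr4b$positions)
  expect_identical(tr4a$enrichment_factor, tr4b$enrichment_factor)

  # oversized dt trips the overshoot guard
  expect_error(
    simulate_migration(init[1:5], p, m,
                       fundamental_field(pressure_amplitude = 1e7),
                       duration = 10, dt = 10),
    "dt.*too large"
  )
})

test_that("enrichment factor: identity, ten-fold window, errors", {
  m <- water_medium()
  p <- cluster_particle()
  f <- fundamental_field()
  L <- f$cavity_length
  init <- (seq_len(100) - 0.5) / 100 * L

  # positions unchanged (zero amplitude -> no force) => factor 1
  f0 <- standing_wave_field(0, cavity_length = L, sound_speed = f$sound_speed)
  tr0 <- simulate_migration(init, p, m, f0, duration = 1, dt = 0.1)
  expect_equal(enrichment_factor(tr0, L / 20), 1)

  # uniform start, full convergence into a window covering L/10 => factor 10
  tr <- simulate_migration(init, p, m, f, duration = 60, dt = 0.05)
  expect_equal(enrichment_factor(tr, L / 20), 10)

  expect_error(enrichment_factor(tr, L), "outside the cavity")
  bad <- tr
  bad$positions <- bad$positions[, 0, drop = FALSE]
  expect_error(enrichment_factor(bad, L / 20), "empty trajectory")
})

test_that("trajectory export writes the CSV schema and JSON summary", {
  m <- water_medium()
  f <- fundamental_field()
  tr <- simulate_migration(c(0.3, 0.6) * f$cavity_length, cluster_particle(),
                           m, f, duration = 1, dt = 0.1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_trajectory(tr, csv, js)
  tab <- read.csv(csv)
  expect_named(tab, c("time_s", "particle_id", "x_m"))
  expect_equal(nrow(tab), 2 * length(tr$times))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$converged_fraction, tr$converged_fraction)
})
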