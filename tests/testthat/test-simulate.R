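# synthetic-data generators: Poisson sampler, Metropolis MC, artefacts

test_that("Poisson sampler honours counts, bounds and seeds", {
  box <- box_geometry(c(100, 100, 50), origin = c(10, 0, -5))
  ps <- sample_poisson(box, n = 100, seed = 1)
  expect_equal(n_particles(ps), 100)
  expect_true(all(tomopip:::.inside_box(ps$coordinates, box)))

  expect_identical(sample_poisson(box, n = 100, seed = 1)$coordinates,
                   ps$coordinates)

  frames <- sample_poisson(box_geometry(c(10, 10, 10)), density = 0.05,
                           n_frames = 1000, ensemble = "grand", seed = 55)
  ns <- vapply(frames, n_particles, numeric(1))
  expect_lt(abs(mean(ns) - 50), 3 * sqrt(50 / 1000))
  expect_lt(abs(var(ns) / mean(ns) - 1), 3 * sqrt(2 / 1000 + 1 / 50 / 1000))
})

test_that("MC sampling is exact for ideal gases and respects hard cores", {
  box <- box_geometry(c(100, 100, 100), periodic = TRUE)
  mc <- run_mc(potential_spec("ideal"), box, 200, n_sweeps_equil = 50,
               n_frames = 5, sample_every = 2, seed = 3)
  expect_equal(mc$acceptance_rate, 1.0)

  hs <- run_mc(potential_spec("hard_sphere", sigma = 8), box, 150,
               n_sweeps_equil = 100, n_frames = 10, sample_every = 2,
               seed = 4)
  for (f in hs$frames) {
    d <- f$coordinates[rep(1:150, 150), ] - f$coordinates[rep(1:150, each = 150), ]
    d <- d - 100 * round(d / 100)
    r2 <- rowSums(d^2)
    expect_gte(min(r2[r2 > 0]), 64)
  }
  expect_lt(hs$energy_drift, 1e-9)

  expect_error(suppressWarnings(
    run_mc(potential_spec("hard_sphere", sigma = 8),
           box_geometry(c(30, 30, 30), periodic = TRUE), 100,
           n_frames = 1)), "insert")
})

test_that("MC trajectories are bit-exact per seed and track energy", {
  box <- box_geometry(c(150, 150, 150), periodic = TRUE)
  pot <- potential_spec("yukawa", sigma = 7, epsilon = 2, kappa = 0.5)
  a <- run_mc(pot, box, 100, n_sweeps_equil = 100, n_frames = 5,
              sample_every = 3, seed = 11)
  b <- run_mc(pot, box, 100, n_sweeps_equil = 100, n_frames = 5,
              sample_every = 3, seed = 11)
  for (k in 1:5)
    expect_identical(a$frames[[k]]$coordinates, b$frames[[k]]$coordinates)
  c <- run_mc(pot, box, 100, n_sweeps_equil = 100, n_frames = 5,
              sample_every = 3, seed = 12)
  expect_false(identical(a$frames[[1]]$coordinates,
                         c$frames[[1]]$coordinates))
  expect_lt(a$energy_drift, 1e-9)
})

test_that("two-particle square-well states follow Boltzmann weights", {
  # coarse state space: shell A (inside the well, weight e^eps) vs shell B
  # (outside); minimum-image shells below half the box are full spheres
  box <- box_geometry(c(30, 30, 30), periodic = TRUE)
  mc <- run_mc(potential_spec("square_well", sigma = 3, epsilon = 1,
                              well_width = 3),
               box, 2, n_sweeps_equil = 1000, n_frames = 50000,
               sample_every = 2, max_displacement = 4, seed = 77,
               tune = FALSE)
  r <- vapply(mc$frames, function(f) {
    d <- f$coordinates[1, ] - f$coordinates[2, ]
    d <- d - 30 * round(d / 30)
    sqrt(sum(d^2))
  }, numeric(1))
  nA <- sum(r >= 3 & r < 6)
  nB <- sum(r >= 6 & r < 9)
  ratio <- nA / nB
  expected <- exp(1) * (6^3 - 3^3) / (9^3 - 6^3)
  se <- ratio * sqrt(1 / nA + 1 / nB)
  expect_lt(abs(ratio - expected), 3 * se)
  # hard core never violated
  expect_gte(min(r), 3)
})

test_that("dilute Yukawa MC satisfies the inversion identity g = exp(-beta U)", {
  mc <- run_mc(potential_spec("yukawa", sigma = 7, epsilon = 2, kappa = 0.5),
               box_geometry(c(600, 600, 100), periodic = TRUE), 525,
               n_sweeps_equil = 300, n_frames = 60, sample_every = 5,
               seed = 19)
  rdf <- compute_rdf_frames(mc$frames)
  bu <- pair_energy(fx_yukawa_pot(), rdf$r_centers)
  sel <- rdf$g > 0.1
  # counting-noise-normalised residuals should be chi-square-like; the
  # tight absolute RMS check runs on the large validation world in the
  # acceptance suite
  sig_w <- rdf_count_sigma(rdf)[sel] / rdf$g[sel]
  chi2 <- mean(((-log(rdf$g[sel]) - bu[sel]) / sig_w)^2)
  expect_lt(chi2, 2.5)
})

test_that("artefact injection emulates tilt and surface enrichment", {
  box <- box_geometry(c(800, 800, 100))
  ps <- sample_poisson(box, n = 10000, seed = 21)

  same <- inject_artifacts(ps, tilt_x = 0, surface_enrichment = 1)
  expect_identical(same$coordinates, ps$coordinates)

  tilted <- inject_artifacts(ps, tilt_x = 2, seed = 1)
  ti <- estimate_tilt(tilted)
  expect_lt(abs(ti$angle_x - 2), 0.15)

  enr <- inject_artifacts(ps, surface_enrichment = 2, depth = 10, seed = 2)
  prof <- concentration_profile(enr, dz = 10)
  bulk <- median(prof$number_density[2:9])
  for (k in c(1, 10)) {
    ratio <- prof$number_density[k] / bulk
    expect_lt(abs(ratio - 2), 3 * 2 / sqrt(prof$counts[k]))
  }
  expect_error(inject_artifacts(ps, surface_enrichment = 0.5), ">= 1")
})
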