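# coordinate I/O, tilt handling, concentration profiles, cropping

test_that("CSV and XYZ round-trip bit-exactly and enforce the format", {
  box <- box_geometry(c(10, 10, 10))
  ps <- particle_set(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)), box)
  for (fmt in c("csv", "xyz")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_particles(ps, f, format = fmt)
    back <- load_particles(f, format = fmt, box = box)
    expect_identical(back$coordinates, ps$coordinates)
    expect_equal(n_particles(back), 3)
  }

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,z_nm", "1,2,3", "NaN,2,3"), f)
  expect_error(load_particles(f, "csv", box = box), "line 3")

  writeLines(c("x_nm,y_nm,z_nm", "1,2,not_a_number"), f)
  expect_error(load_particles(f, "csv", box = box), "line 2")

  writeLines("x_nm,y_nm,z_nm", f)
  expect_error(load_particles(f, "csv", box = box), "zero")

  fx <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "comment", "P 1 2 3", "P 4 5 6"), fx)
  expect_error(load_particles(fx, "xyz", box = box), "declares 5")

  expect_error(load_particles("no/such/file.csv", "csv", box = box),
               "does not exist")
})

test_that("out-of-box records honour the strictness option", {
  box <- box_geometry(c(10, 10, 10))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,z_nm", "1,2,3", "11,2,3"), f)
  expect_error(load_particles(f, "csv", box = box), "outside")
  expect_warning(ps <- load_particles(f, "csv", box = box, strict = "drop"),
                 "dropping 1")
  expect_equal(n_particles(ps), 1)
  ps <- load_particles(f, "csv", box = box, strict = "keep")
  expect_equal(n_particles(ps), 2)
})

test_that("tilt estimation recovers applied tilts and flags isotropic clouds", {
  slab <- box_geometry(c(800, 800, 100))
  ps <- sample_poisson(slab, n = 50000, seed = 301)

  t0 <- estimate_tilt(ps)
  expect_lt(abs(t0$angle_x), 0.2)
  expect_lt(abs(t0$angle_y), 0.2)
  expect_true(t0$slab_like)

  # angle noise is ~1/(aspect * sqrt(N)) rad ~ 0.03 deg here, so the
  # 0.1 deg recovery bound is a 3-sigma test
  t1 <- estimate_tilt(tilt_particles(ps, 2, 0))
  expect_lt(abs(t1$angle_x - 2), 0.1)
  expect_lt(abs(t1$angle_y), 0.1)
  t2 <- estimate_tilt(tilt_particles(ps, 1.5, -2.5))
  expect_lt(abs(t2$angle_x - 1.5), 0.1)
  expect_lt(abs(t2$angle_y + 2.5), 0.1)

  cube <- sample_poisson(box_geometry(c(100, 100, 100)), n = 5000, seed = 5)
  tc <- estimate_tilt(cube)
  expect_false(tc$slab_like)
  expect_lt(abs(tc$angle_x), 2)
  # closed-form least-squares oracle for the plane fit (before the
  # attenuation correction, which is skipped for isotropic clouds)
  X <- cbind(1, cube$coordinates[, 1:2])
  beta <- solve(crossprod(X), crossprod(X, cube$coordinates[, 3]))
  expect_equal(unname(tc$plane_coefficients[["b"]]), beta[2], tolerance = 1e-9)

  expect_error(estimate_tilt(sample_poisson(slab, n = 5, seed = 1)),
               "at least 10")
})

test_that("tilt correction is a rigid motion and inverts a known tilt", {
  slab <- box_geometry(c(200, 200, 50))
  ps <- sample_poisson(slab, n = 400, seed = 17)

  same <- apply_tilt_correction(ps, tilt_estimate(0, 0))
  expect_identical(same$coordinates, ps$coordinates)
  expect_identical(same$box$extents, ps$box$extents)

  tilted <- tilt_particles(ps, 3.2, -1.4)
  back <- apply_tilt_correction(tilted, tilt_estimate(3.2, -1.4))
  expect_lt(max(abs(back$coordinates - ps$coordinates)), 1e-9)

  d0 <- dist(ps$coordinates)
  expect_lt(max(abs(dist(tilted$coordinates) - d0)), 1e-9)
  expect_lt(max(abs(dist(back$coordinates) - d0)), 1e-9)
})

test_that("concentration profile converts units, conserves counts and finds the plateau", {
  box <- box_geometry(c(800, 800, 100))
  # 1e4 particles give rho = 1.5625e-4 nm^-3 and, at the BSA molecular
  # weight, 17.3 mg/mL by the closed-form unit conversion
  ps <- sample_poisson(box, n = 10000, seed = 23)
  ps$molecular_weight <- 66500

  prof <- concentration_profile(ps, dz = 100)   # one bin = bulk value
  rho <- 10000 / (800 * 800 * 100)
  # oracle: rho * MW / N_A with 1 L = 1e24 nm^3
  expect_equal(prof$number_density, rho)
  expect_equal(prof$mass_concentration,
               rho * 66500 / 6.02214076e23 * 1e24, tolerance = 1e-12)
  expect_equal(round(prof$mass_concentration, 1), 17.3)

  prof2 <- concentration_profile(ps, dz = 5)
  expect_identical(sum(prof2$counts), 10000L)
  expect_equal(prof2$number_density * 800 * 800 * 5, prof2$counts)

  # uniform slab: plateau spans (essentially) the whole height
  big <- sample_poisson(box, n = 20000, seed = 24)
  p3 <- concentration_profile(big, dz = 5)
  expect_lte(p3$plateau_range[1], 10)
  expect_gte(p3$plateau_range[2], 90)

  # doubled density in the top 10 nm: plateau excludes the enriched band
  enr <- inject_artifacts(big, surface_enrichment = 3, depth = 10, seed = 25)
  p4 <- concentration_profile(enr, dz = 5)
  expect_gte(p4$plateau_range[1], 10)
  expect_lte(p4$plateau_range[2], 90)

  expect_error(concentration_profile(ps, dz = 101), "exceeds")
})

test_that("cropping is half-open, exact and supports auto mode", {
  box <- box_geometry(c(10, 10, 100))
  coords <- rbind(c(5, 5, 10), c(5, 5, 90), c(5, 5, 50), c(5, 5, 89.999999))
  ps <- particle_set(coords, box)
  crop <- crop_central_slab(ps, 10, 90)
  # z = z_lo kept, z = z_hi excluded, bit-exact
  expect_equal(n_particles(crop), 3)
  expect_equal(crop$box$extents[3], 80)
  expect_equal(crop$box$origin[3], 10)

  big <- sample_poisson(box_geometry(c(800, 800, 100)), n = 20000, seed = 31)
  full <- crop_central_slab(big, 0, 100)
  expect_identical(full$coordinates, big$coordinates)

  mid <- crop_central_slab(big, 10, 90)
  frac <- n_particles(mid) / 20000
  expect_lt(abs(frac - 0.8), 4 * sqrt(0.8 * 0.2 / 20000))

  expect_error(crop_central_slab(ps, 90, 10), "below")
  expect_error(crop_central_slab(ps, 40, 45), "fewer than 2")
})

test_that("auto-crop removes enriched surface bands without touching the bulk", {
  box <- box_geometry(c(800, 800, 100))
  ps <- sample_poisson(box, n = 20000, seed = 33)
  enr <- inject_artifacts(ps, surface_enrichment = 2, depth = 10, seed = 34)
  crop <- crop_central_slab(enr)
  z0 <- crop$box$origin[3]
  z1 <- z0 + crop$box$extents[3]
  expect_gte(z0, 10)
  expect_lte(z1, 90)
  # interior density unchanged within 3 sigma of counting noise
  nexp <- 20000 / 100 * crop$box$extents[3]
  expect_lt(abs(n_particles(crop) - nexp), 3 * sqrt(nexp))
})
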