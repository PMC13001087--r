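# shell volumes, boundary-corrected g(r), PMF inversion, effective PIP

test_that("clipped shell volumes match closed forms and a Monte-Carlo oracle", {
  b <- box_geometry(c(100, 100, 100))
  expect_equal(shell_volume_in_box(c(50, 50, 50), 0, 10, b),
               4 * pi / 3 * 1000, tolerance = 1e-12)
  expect_equal(shell_volume_in_box(c(50, 50, 50), 4, 9, b),
               4 * pi / 3 * (729 - 64), tolerance = 1e-12)
  # octant / quadrant symmetry at a corner and an edge
  expect_equal(shell_volume_in_box(c(0, 0, 0), 0, 10, b),
               4 * pi / 3 * 1000 / 8, tolerance = 1e-10)
  expect_equal(shell_volume_in_box(c(0, 0, 50), 2, 10, b),
               4 * pi / 3 * (1000 - 8) / 4, tolerance = 1e-10)

  # rejection-sampling oracle for a generic clipped shell
  set.seed(41)
  ctr <- c(4, 7, 95); rin <- 6; rout <- 11
  M <- 1e6
  u <- runif(M); r <- (u * (rout^3 - rin^3) + rin^3)^(1 / 3)
  z <- runif(M, -1, 1); phi <- runif(M, 0, 2 * pi); s <- sqrt(1 - z^2)
  x <- ctr[1] + r * s * cos(phi); y <- ctr[2] + r * s * sin(phi)
  zz <- ctr[3] + r * z
  f <- mean(x >= 0 & x < 100 & y >= 0 & y < 100 & zz >= 0 & zz < 100)
  vfull <- 4 * pi / 3 * (rout^3 - rin^3)
  vmc <- f * vfull
  sig <- vfull * sqrt(f * (1 - f) / M)
  expect_lt(abs(shell_volume_in_box(ctr, rin, rout, b) - vmc), 3 * sig)

  expect_error(shell_volume_in_box(c(150, 50, 50), 0, 5, b), "outside")
  expect_error(shell_volume_in_box(c(50, 50, 50), 5, 5, b), "r_in < r_out")
})

test_that("compute_rdf counts pairs and normalises correctly", {
  big <- box_geometry(c(1000, 1000, 1000))
  two <- particle_set(rbind(c(500, 500, 500), c(505, 500, 500)), big)
  rdf <- compute_rdf(two, bin_width = 0.3, n_bins = 100)
  expect_equal(sum(rdf$pair_counts), 1)
  expect_equal(rdf$pair_counts[floor(5 / 0.3) + 1], 1)

  expect_error(compute_rdf(particle_set(matrix(1, 1, 3), big)), "at least 2")
  small <- box_geometry(c(20, 20, 20))
  expect_warning(compute_rdf(sample_poisson(small, n = 30, seed = 2)),
                 "half the smallest")
})

test_that("Poisson gas gives g = 1 within counting error, including near walls", {
  # this is the test that the shell-volume boundary correction is right:
  # in an 800 x 800 x 100 slab most particles sit within the 30 nm RDF
  # range of a wall
  box <- box_geometry(c(800, 800, 100))
  rdf <- compute_rdf_frames(sample_poisson(box, n = 5000, n_frames = 4,
                                           ensemble = "grand", seed = 47))
  sig <- rdf_count_sigma(rdf)
  expect_lt(max(abs(rdf$g - 1) / sig), 4)
})

test_that("hard cores leave g identically zero below contact", {
  mc <- run_mc(potential_spec("hard_sphere", sigma = 7),
               box_geometry(c(150, 150, 150), periodic = TRUE), 100,
               n_sweeps_equil = 200, n_frames = 10, sample_every = 5,
               seed = 53)
  rdf <- compute_rdf_frames(mc$frames)
  expect_true(all(rdf$g[rdf$r_centers < 6.85] == 0))
})

test_that("replicate averaging pools information and tracks spread", {
  box <- box_geometry(c(200, 200, 100))
  r1 <- compute_rdf(sample_poisson(box, n = 500, seed = 61))
  expect_identical(average_rdfs(list(r1)), r1)

  avg2 <- average_rdfs(list(r1, r1))
  expect_equal(avg2$g, r1$g)
  expect_equal(avg2$replicate_std, rep(0, length(r1$g)))
  expect_equal(avg2$pair_counts, 2 * r1$pair_counts)

  ra <- r1; rb <- r1
  ra$g <- rep(0.9, length(r1$g)); rb$g <- rep(1.1, length(r1$g))
  m <- average_rdfs(list(ra, rb))
  expect_equal(m$g, rep(1.0, length(r1$g)))
  expect_equal(m$replicate_std, rep(sd(c(0.9, 1.1)), length(r1$g)),
               tolerance = 1e-12)

  rshift <- compute_rdf(sample_poisson(box, n = 500, seed = 62),
                        bin_width = 0.5)
  expect_error(average_rdfs(list(r1, rshift)), "do not match")
})

test_that("PMF inversion follows the reversible work theorem and masks zeros", {
  rdf <- step_rdf(function(r) rep(1, length(r)))
  w <- pmf_from_rdf(rdf)
  expect_equal(w$value, rep(0, length(w$r)))

  rdf$g <- rep(exp(-1), length(rdf$g))
  w <- pmf_from_rdf(rdf)
  expect_equal(w$value, rep(1, length(w$r)), tolerance = 1e-12)

  rdf$g[5] <- 0
  rdf$g[9] <- 5e-4   # below the default floor
  w <- pmf_from_rdf(rdf)
  expect_false(w$valid[5])
  expect_false(w$valid[9])
  expect_true(all(is.finite(w$value[w$valid])))
  expect_true(all(is.na(w$value[!w$valid])))
})

test_that("effective PIP pools concentration-series PMFs and flags spread", {
  rdf <- step_rdf(function(r) ifelse(r < 7, 0, 1))
  w <- pmf_from_rdf(rdf)
  res <- effective_pip(list(w, w))
  expect_equal(res$max_deviation, 0)
  expect_false(res$flag)
  expect_equal(res$pip$kind, "PIP")

  w2 <- w; w2$value <- w$value + 0.05
  res <- effective_pip(list(w, w2))
  expect_equal(res$max_deviation, 0.05, tolerance = 1e-12)
  expect_false(res$flag)
  res <- effective_pip(list(w, w2), threshold = 0.04)
  expect_true(res$flag)

  one <- effective_pip(list(w))
  expect_true(is.na(one$max_deviation))
  expect_false(one$flag)
})

test_that("the PMF of a dilute Yukawa fluid is concentration independent", {
  # two dilute densities (rho*sigma^3 = 0.005 and 0.0025) of the same
  # fluid, sampled to matched pair statistics: the PMFs agree bin by bin,
  # so the pooled curve is a genuine pair interaction potential
  fxd <- fx_yukawa_two_densities()
  res <- effective_pip(list(fxd$pmfA, fxd$pmfB))
  sel <- res$pip$valid & fxd$rdfA$g > 0.1 & fxd$rdfB$g > 0.1
  dev <- abs(fxd$pmfA$value - fxd$pmfB$value)
  expect_lt(max(dev[sel]), 0.15)
  expect_false(res$flag)
})
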