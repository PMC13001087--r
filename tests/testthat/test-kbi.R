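# Kirkwood-Buff integrals: direct, sub-box, from potentials

test_that("direct KBI integration matches piecewise closed forms", {
  flat <- step_rdf(function(r) rep(1, length(r)))
  expect_equal(kbi_direct(flat, 30)$G_inf, 0)

  hs <- step_rdf(function(r) ifelse(r < 7, 0, 1))
  G <- kbi_direct(hs, 30)$G_inf
  expect_equal(G, -4 * pi / 3 * 343, tolerance = 1e-12)  # exact on aligned edges

  sw <- step_rdf(function(r) ifelse(r < 7, 0, ifelse(r < 8, 2, 1)))
  expect_equal(kbi_direct(sw, 30)$G_inf,
               -4 * pi / 3 * 343 + 4 * pi / 3 * (512 - 343),
               tolerance = 1e-12)

  # trapezoid route agrees on smooth g
  smooth <- step_rdf(function(r) 1 - exp(-r / 5), bin_width = 0.05,
                     n_bins = 600)
  gh <- kbi_direct(smooth, 30, method = "histogram")$G_inf
  gt <- kbi_direct(smooth, 30, method = "trapezoid")$G_inf
  expect_equal(gh, gt, tolerance = 1e-3)

  cum <- kbi_direct(hs, 30)
  expect_equal(cum$G_of_r[1], 0)
  # continuity: no jump exceeds one bin's worst-case contribution
  expect_lt(max(abs(diff(cum$G_of_r))),
            max(abs(hs$g - 1)) * 4 * pi * 30^2 * hs$bin_width + 1e-9)
  expect_error(kbi_direct(hs, 31), "exceeds")
})

test_that("Mayer quadrature reproduces closed-form B22 and KBI values", {
  hs <- potential_to_curve(potential_spec("hard_sphere", sigma = 7),
                           r_max = 30, dr = 0.1)
  expect_equal(b22_from_potential(hs, 30), 2 * pi / 3 * 343,
               tolerance = 1e-12)
  expect_equal(kbi_from_pmf(hs, 30), -4 * pi / 3 * 343, tolerance = 1e-12)

  zero <- potential_curve(seq(0.05, 29.95, 0.1), rep(0, 300))
  expect_equal(b22_from_potential(zero, 30), 0)
  expect_equal(kbi_from_pmf(zero, 30), 0)

  sw <- potential_to_curve(potential_spec("square_well", sigma = 7,
                                          epsilon = 0.5, well_width = 1),
                           r_max = 30, dr = 0.1)
  # independent quadrature oracle (the spec sheet's printed 499.6 is a
  # miscalculation of its own formula; the closed form gives 488.8)
  oracle <- -2 * pi * integrate(function(r)
    (exp(-pair_energy(potential_spec("square_well", sigma = 7,
                                     epsilon = 0.5, well_width = 1), r)) - 1)
    * r^2, 0, 30, subdivisions = 2000)$value
  expect_equal(oracle, 2 * pi / 3 * (343 - (exp(0.5) - 1) * (512 - 343)),
               tolerance = 1e-6)
  expect_equal(b22_from_potential(sw, 30), oracle, tolerance = 1e-6)

  expect_error(b22_from_potential(hs, 40), "exceeds")
})

test_that("G = -2 B22 holds to machine precision for every potential", {
  pots <- list(
    potential_to_curve(potential_spec("hard_sphere", sigma = 7), 30, 0.1),
    potential_to_curve(potential_spec("yukawa", sigma = 7, epsilon = 2,
                                      kappa = 0.5), 30, 0.1),
    potential_to_curve(potential_spec("square_well", sigma = 5,
                                      epsilon = 1.2, well_width = 2), 30, 0.1))
  set.seed(83)
  for (i in 1:5) {
    r <- seq(0.05, 29.95, 0.1)
    pots[[length(pots) + 1]] <- potential_curve(r, rnorm(length(r), 0, 0.5))
  }
  for (U in pots) {
    b <- b22_from_potential(U, 30)
    g <- kbi_from_pmf(U, 30)
    expect_equal(g / b, -2, tolerance = 1e-12)
  }
})

test_that("sub-box scan reproduces ensemble closed forms", {
  box <- box_geometry(c(800, 800, 100))
  # grand-canonical Poisson: variance = mean, so G_eff = 0 at every L
  frames <- fx_poisson_null()$frames
  scan <- kbi_subbox(frames, L = seq(10, 50, 10))
  expect_equal(scan$SV, 2 / 100 + 4 / scan$L)
  expect_true(all(scan$n_subboxes >= 1))
  # honest binomial-oracle noise bound per L (conservative effective
  # sample count: non-overlapping windows per frame)
  mu <- 5000 * scan$L^2 / 800^2
  neff <- (800 / scan$L)^2 * length(frames)
  sdG <- (6.4e7 / 5000) * sqrt((2 + 1 / mu) / neff)
  expect_true(all(abs(scan$G_eff) < 3 * sdG))

  # single-frame canonical sampling: G_eff = -V_sub / N exactly in
  # expectation (binomial sub-sampling); resolved with many frames
  nf <- 6000
  set.seed(88)
  frames2 <- lapply(seq_len(nf), function(i) {
    xyz <- matrix(runif(5000 * 3), ncol = 3) %*% diag(c(800, 800, 100))
    particle_set(xyz, box, validate = FALSE)
  })
  scan2 <- kbi_subbox(frames2, L = 50, stride = 25)
  mu <- 5000 * (50 / 800)^2
  sdG <- (6.4e7 / 5000) * sqrt((2 + 1 / mu) / ((800 / 50)^2 * nf))
  expect_lt(abs(scan2$G_eff - (-50 * 50 * 100 / 5000)), 3 * sdG)

  expect_error(kbi_subbox(frames, L = numeric(0)), "empty")
  expect_error(kbi_subbox(frames, L = 900), "lateral")
})

test_that("halving the stride changes the scan by less than sampling error", {
  frames <- fx_poisson_null()$frames
  L <- seq(10, 40, 10)
  s3 <- kbi_subbox(frames, L = L, stride = 3)
  s6 <- kbi_subbox(frames, L = L, stride = 6)
  # per-L inter-frame standard error from the per-frame moments
  per_frame_g <- function(scan) {
    vapply(seq_len(scan$n_frames), function(j)
      tomopip:::.subbox_g(scan$frame_moments[, j, , drop = TRUE],
                          scan$L, scan$H),
      numeric(length(scan$L)))
  }
  se <- apply(per_frame_g(s3), 1, sd) / sqrt(s3$n_frames)
  expect_true(all(abs(s3$G_eff - s6$G_eff) < 3 * se))
})

test_that("sub-box scan is invariant under permutation and periodic translation", {
  box <- box_geometry(c(120, 120, 60), periodic = TRUE)
  ps <- sample_poisson(box, n = 400, seed = 91)
  scan <- kbi_subbox(ps, L = c(12, 24), stride = 3)

  set.seed(92)
  perm <- particle_set(ps$coordinates[sample(400), ], box)
  expect_equal(kbi_subbox(perm, L = c(12, 24), stride = 3)$G_eff, scan$G_eff)

  shifted <- ps$coordinates
  shifted[, 1] <- (shifted[, 1] + 9) %% 120
  shifted[, 2] <- (shifted[, 2] + 27) %% 120
  tr <- particle_set(shifted, box)
  expect_equal(kbi_subbox(tr, L = c(12, 24), stride = 3)$G_eff, scan$G_eff,
               tolerance = 1e-9)
})

test_that("S/V extrapolation recovers exact linear scans and the null case", {
  L <- seq(6, 50, 4)
  sv <- 2 / 100 + 4 / L
  scan <- structure(list(L = L, stride = 3, H = 100,
                         G_eff = -2400 + 500 * sv, SV = sv,
                         n_subboxes = rep(1000, length(L)), n_frames = 1,
                         frame_moments = NULL),
                    class = "subbox_scan")
  est <- suppressWarnings(kbi_extrapolate(scan, L_max = 50, n_boot = 0))
  expect_equal(est$G_inf, -2400, tolerance = 1e-9)
  expect_equal(est$fit$slope, 500, tolerance = 1e-9)
  expect_equal(est$fit$r_squared, 1, tolerance = 1e-12)

  null_scan <- kbi_subbox(fx_poisson_null()$frames, L = seq(6, 50, 4))
  est0 <- kbi_extrapolate(null_scan, L_max = 50, seed = 5)
  expect_lt(abs(est0$G_inf), 3 * est0$stderr)

  expect_error(kbi_extrapolate(scan, L_max = 10), "fewer than 3")
})

test_that("direct integration amplifies noise relative to the sub-box route", {
  # documented motivation for the sub-box method: across matched
  # replicates, the direct r^2-weighted integral scatters far more than
  # the fluctuation-based estimate
  frames <- fx_poisson_null()$frames
  g_direct <- vapply(frames, function(f)
    kbi_direct(compute_rdf(f), 30)$G_inf, numeric(1))
  g_subbox <- vapply(frames, function(f)
    kbi_extrapolate(kbi_subbox(f, L = seq(6, 50, 4)), n_boot = 0)$G_inf,
    numeric(1))
  expect_gt(var(g_direct), var(g_subbox))
})
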