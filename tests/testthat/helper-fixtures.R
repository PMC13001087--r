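# Shared, lazily built fixtures.  The heavy Monte-Carlo worlds are built
# once per test run and reused across test files; every builder is fully
# seeded so the suite is deterministic.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_env)) assign(name, builder(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# dilute Yukawa reference fluid: beta*eps = 2 at contact, kappa = 0.5 nm^-1,
# sigma = 7 nm, rho*sigma^3 ~ 0.005 in a periodic 2290 x 2290 x 100 nm^3 slab
fx_yukawa_pot <- function() potential_spec("yukawa", sigma = 7, epsilon = 2,
                                           kappa = 0.5)

fx_yukawa_main <- function() fx("yukawa_main", function() {
  pot <- fx_yukawa_pot()
  box <- box_geometry(c(2290, 2290, 100), periodic = TRUE)
  mc <- run_mc(pot, box, 7644, n_sweeps_equil = 300, n_frames = 50,
               sample_every = 10, seed = 42)
  rdf <- compute_rdf_frames(mc$frames)
  scan <- kbi_subbox(mc$frames, L = seq(6, 50, 4))
  list(pot = pot, box = box, mc = mc, rdf = rdf,
       pmf = pmf_from_rdf(rdf), scan = scan,
       est = kbi_extrapolate(scan, L_max = 50, seed = 7),
       b22_true = b22_from_potential(potential_to_curve(pot, r_max = 30,
                                                        dr = 0.05), 30))
})

# same fluid at two dilute densities with matched pair statistics, for the
# concentration-independence check of the PMF
fx_yukawa_two_densities <- function() fx("yukawa_two", function() {
  pot <- fx_yukawa_pot()
  box <- box_geometry(c(2290, 2290, 100), periodic = TRUE)
  mcA <- run_mc(pot, box, 7644, n_sweeps_equil = 300, n_frames = 300,
                sample_every = 5, seed = 101)
  mcB <- run_mc(pot, box, 3822, n_sweeps_equil = 300, n_frames = 1200,
                sample_every = 5, seed = 202)
  rA <- compute_rdf_frames(mcA$frames)
  rB <- compute_rdf_frames(mcB$frames)
  list(rdfA = rA, rdfB = rB, pmfA = pmf_from_rdf(rA), pmfB = pmf_from_rdf(rB))
})

# ideal-gas null world: 20 grand-canonical Poisson slabs, mean N = 5000,
# in the canonical 800 x 800 x 100 nm^3 tomogram volume
fx_poisson_null <- function() fx("poisson_null", function() {
  box <- box_geometry(c(800, 800, 100))
  frames <- sample_poisson(box, n = 5000, n_frames = 20, ensemble = "grand",
                           seed = 7)
  rdf <- compute_rdf_frames(frames)
  list(box = box, frames = frames, rdf = rdf)
})

# per-bin 1-sigma counting deviation of an averaged RDF, from its own
# pooled pair counts and expected-count normalisation
rdf_count_sigma <- function(rdf) {
  2 * sqrt(pmax(rdf$pair_counts, 1)) / rdf$norm
}

# counting-noise sigma of a direct KBI integral, propagated bin-wise
kbi_direct_sigma <- function(rdf, cutoff) {
  edges <- c(rdf$r_centers - rdf$bin_width / 2,
             max(rdf$r_centers) + rdf$bin_width / 2)
  dg <- rdf_count_sigma(rdf)
  w <- 4 * pi / 3 * (pmin(edges[-1], cutoff)^3 -
                     pmin(edges[-length(edges)], cutoff)^3)
  sqrt(sum((w * dg)^2))
}

# step-function RDF fixture on a grid whose edges align with the steps
step_rdf <- function(g_of_r, bin_width = 0.25, n_bins = 120,
                     density = 1e-5, n = 1000) {
  r <- bin_width * (seq_len(n_bins) - 0.5)
  structure(list(r_centers = r, bin_width = bin_width, g = g_of_r(r),
                 pair_counts = rep(1, n_bins), n_particles = n,
                 density = density, replicate_std = NULL,
                 shell_volumes = 4 * pi * r^2 * bin_width * n,
                 norm = rep(1, n_bins), n_replicates = 1L,
                 temperature = 293.15),
            class = "radial_distribution")
}
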