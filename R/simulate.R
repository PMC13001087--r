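#' Pair potential specification for the synthetic-fluid generator
#'
#' Supported forms (energies in kB*T, distances in nm):
#' * `hard_sphere`: infinite below `sigma`, zero above.
#' * `square_well`: hard core plus a well of depth `epsilon` over
#'   `[sigma, sigma + well_width)`.
#' * `yukawa`: hard core plus screened repulsion
#'   `epsilon * (sigma / r) * exp(-kappa (r - sigma))` for `r >= sigma` --
#'   the minimal model of a charge-stabilised soft sphere.
#' * `tabulated`: linear interpolation of a `(r, U)` table, hard below the
#'   first tabulated r, zero beyond the last.
#' * `ideal`: no interactions at all.
#'
#' @param kind one of `"hard_sphere"`, `"square_well"`, `"yukawa"`,
#'   `"tabulated"`, `"ideal"`.
#' @param sigma hard-core diameter in nm.
#' @param epsilon energy scale in kB*T (contact value for yukawa, well
#'   depth for square_well).
#' @param kappa yukawa screening constant in nm^-1.
#' @param well_width square-well width in nm.
#' @param table two-column matrix or data frame `(r, U)` for
#'   `"tabulated"`.
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(kind = c("hard_sphere", "square_well", "yukawa",
                                    "tabulated", "ideal"),
                           sigma = 7, epsilon = 1, kappa = 0.5,
                           well_width = 1, table = NULL) {
  kind <- match.arg(kind)
  if (kind != "ideal" && (!is.finite(sigma) || sigma <= 0))
    stop("`sigma` must be positive")
  if (kind == "tabulated") {
    table <- as.matrix(table)
    if (is.null(table) || ncol(table) != 2 || nrow(table) < 2)
      stop("`table` must be a two-column (r, U) table with >= 2 rows")
    if (any(!is.finite(table)))
      stop("tabulated potential values must be finite")
    if (any(diff(table[, 1]) <= 0))
      stop("tabulated r values must be strictly increasing")
  }
  structure(list(kind = kind, sigma = sigma, epsilon = epsilon,
                 kappa = kappa, well_width = well_width, table = table),
            class = "potential_spec")
}

#' Evaluate a pair potential
#'
#' Vectorised evaluation of the model potential in kB*T, with `Inf` inside
#' hard cores.  This is the ground truth that recovered PMF/PIP curves are
#' validated against.
#'
#' @param pot a [potential_spec()].
#' @param r distances in nm.
#' @return Energies in kB*T.
#' @export
pair_energy <- function(pot, r) {
  stopifnot(inherits(pot, "potential_spec"))
  r <- as.numeric(r)
  switch(pot$kind,
    ideal = rep(0, length(r)),
    hard_sphere = ifelse(r < pot$sigma, Inf, 0),
    square_well = ifelse(r < pot$sigma, Inf,
                         ifelse(r < pot$sigma + pot$well_width,
                                -pot$epsilon, 0)),
    yukawa = ifelse(r < pot$sigma, Inf,
                    pot$epsilon * (pot$sigma / r) *
                      exp(-pot$kappa * (r - pot$sigma))),
    tabulated = {
      tr <- pot$table[, 1]; tu <- pot$table[, 2]
      out <- rep(0, length(r))
      out[r < tr[1]] <- Inf
      mid <- r >= tr[1] & r < tr[length(tr)]
      out[mid] <- approx(tr, tu, xout = r[mid])$y
      out
    })
}

#' Ground-truth potential curve for a model potential
#'
#' Tabulates [pair_energy()] on a uniform grid as a [potential_curve()]
#' (hard-core distances masked invalid), ready for
#' [b22_from_potential()] / [kbi_from_pmf()].
#'
#' @param pot a [potential_spec()].
#' @param r_max grid end in nm.
#' @param dr grid spacing in nm.
#' @param temperature kelvin.
#' @return A `potential_curve` of kind `"model"`.
#' @export
potential_to_curve <- function(pot, r_max = 30, dr = 0.1,
                               temperature = 293.15) {
  r <- seq(dr / 2, r_max - dr / 2, by = dr)
  u <- pair_energy(pot, r)
  potential_curve(r, ifelse(is.finite(u), u, NA_real_),
                  valid = is.finite(u), temperature = temperature,
                  kind = "model")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

#' Sample ideal-gas (Poisson) configurations
#'
#' Canonical ensemble: exactly `n` uniform points per frame.  Grand
#' ensemble: the per-frame count is drawn from Poisson(density * V), the
#' appropriate null model for a subvolume of a macroscopic sample.
#'
#' @param box a [box_geometry()].
#' @param n particle count (canonical; also sets the mean count for the
#'   grand ensemble unless `density` is given).
#' @param density number density in nm^-3 (alternative to `n`).
#' @param n_frames how many independent frames to draw.
#' @param ensemble `"canonical"` or `"grand"`.
#' @param seed RNG seed (restores the caller's RNG state afterwards).
#' @param temperature kelvin, forwarded to the particle sets.
#' @return A [particle_set()] if `n_frames == 1`, else a list of them.
#' @export
sample_poisson <- function(box, n = NULL, density = NULL, n_frames = 1,
                           ensemble = c("canonical", "grand"), seed = NULL,
                           temperature = 293.15) {
  stopifnot(inherits(box, "box_geometry"))
  ensemble <- match.arg(ensemble)
  if (is.null(n) && is.null(density))
    stop("give `n` or `density`")
  lambda <- if (is.null(n)) density * box_volume(box) else n
  if (!is.finite(lambda) || lambda <= 0) stop("particle count must be positive")
  .with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      ni <- if (ensemble == "grand") rpois(1, lambda) else as.integer(round(lambda))
      xyz <- matrix(runif(3 * ni), ncol = 3)
      xyz <- sweep(sweep(xyz, 2, box$extents, `*`), 2, box$origin, `+`)
      particle_set(xyz, box, temperature = temperature)
    })
    if (n_frames == 1) frames[[1]] else frames
  })
}

# interaction cutoff where the model potential becomes negligible
.potential_cutoff <- function(pot, box) {
  cap <- 0.45 * min(box$extents)
  rc <- switch(pot$kind,
    ideal = min(1, cap),
    hard_sphere = pot$sigma,
    square_well = pot$sigma + pot$well_width,
    tabulated = max(pot$table[, 1]),
    yukawa = {
      r <- pot$sigma
      while (r < cap &&
             pot$epsilon * (pot$sigma / r) * exp(-pot$kappa * (r - pot$sigma)) > 1e-4)
        r <- r + 0.25
      r
    })
  min(rc + 1e-9, cap)
}

#' Metropolis Monte Carlo sampling of a pair-potential fluid
#'
#' Single-particle displacement Metropolis sampling of
#' `exp(-sum U / kB T)` in a fully periodic box under the minimum-image
#' convention.  The maximum displacement is auto-tuned toward 30-50%
#' acceptance during equilibration and then frozen, preserving detailed
#' balance during sampling.  The trajectory is bit-exact for a given seed.
#' Incremental energy bookkeeping is verified against full recomputation
#' every 10^3 sweeps; the largest discrepancy is reported as
#' `energy_drift`.
#'
#' @param potential a [potential_spec()].
#' @param box a fully periodic [box_geometry()].
#' @param n_particles number of particles.
#' @param n_sweeps_equil equilibration sweeps (1 sweep = N attempted moves).
#' @param n_frames frames to record after equilibration.
#' @param sample_every sweeps between recorded frames.
#' @param max_displacement initial maximum displacement in nm.
#' @param seed integer RNG seed (the simulation has its own generator and
#'   does not touch R's RNG state).
#' @param temperature kelvin, metadata for the frames.
#' @param cutoff interaction cutoff in nm (default: where the potential
#'   falls below 1e-4 kB*T, capped at 0.45 of the smallest extent).
#' @param tune auto-tune the displacement during equilibration.
#' @return A list of class `mc_result`: `frames` (list of
#'   [particle_set()]), `acceptance_rate` (sampling phase),
#'   `max_displacement` (frozen value), `energy_drift` (kB*T) and the
#'   echoed configuration.
#' @export
run_mc <- function(potential, box, n_particles, n_sweeps_equil = 500,
                   n_frames = 50, sample_every = 10, max_displacement = 3,
                   seed = 1, temperature = 293.15, cutoff = NULL,
                   tune = TRUE) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(box, "box_geometry"))
  if (!all(box$periodic))
    stop("Monte Carlo requires a fully periodic box")
  if (n_particles < 1) stop("`n_particles` must be positive")
  if (n_frames < 1 || sample_every < 1 || n_sweeps_equil < 0)
    stop("sweep counts must be positive")
  if (is.null(cutoff)) cutoff <- .potential_cutoff(potential, box)
  if (cutoff > min(box$extents) / 2)
    stop("interaction cutoff exceeds half the smallest box extent")
  if (potential$kind %in% c("hard_sphere", "square_well", "yukawa")) {
    packing <- n_particles * pi / 6 * potential$sigma^3 / box_volume(box)
    if (packing > 0.3)
      warning(sprintf("hard-core packing fraction %.2f is high; insertion may fail", packing))
  }
  kind_code <- match(potential$kind,
                     c("ideal", "hard_sphere", "square_well", "yukawa",
                       "tabulated")) - 1L
  tab <- if (potential$kind == "tabulated") potential$table else
    matrix(c(0, 1, 0, 0), 2)
  seed <- as.numeric(seed)
  res <- cpp_run_mc(as.integer(n_particles), box$extents, kind_code,
                    potential$sigma, potential$epsilon, potential$kappa,
                    potential$well_width, tab[, 1], tab[, 2], cutoff,
                    as.integer(n_sweeps_equil), as.integer(n_frames),
                    as.integer(sample_every), max_displacement,
                    seed %% 2^32, seed %/% 2^32, tune)
  frames <- lapply(res$frames, function(m) {
    m <- sweep(m, 2, box$origin, `+`)
    particle_set(m, box, temperature = temperature)
  })
  structure(list(frames = frames, acceptance_rate = res$acceptance_rate,
                 max_displacement = res$max_displacement,
                 energy_drift = res$energy_drift,
                 final_energy = res$final_energy,
                 config = list(potential = potential, box = box,
                               n_particles = n_particles,
                               n_sweeps_equil = n_sweeps_equil,
                               n_frames = n_frames,
                               sample_every = sample_every, seed = seed,
                               cutoff = cutoff, temperature = temperature)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s fluid, N = %d, %d frames, acceptance %.2f, max step %.3g nm, energy drift %.2g kT\n",
              x$config$potential$kind, x$config$n_particles,
              length(x$frames), x$acceptance_rate, x$max_displacement,
              x$energy_drift))
  invisible(x)
}

#' Inject tomogram-like artefacts into a particle set
#'
#' Emulates the two dominant preprocessing nuisances of slab tomograms:
#' adsorption layers at both slab surfaces (extra particles resampled into
#' layers of the given depth so the layer density is `factor` times the
#' bulk density) and a rigid sample tilt.  Enrichment is applied first,
#' then the tilt, as for a physically tilted sample.
#'
#' @param ps a [particle_set()] (non-periodic slab).
#' @param tilt_x,tilt_y tilt angles in degrees.
#' @param surface_enrichment density multiplication factor in the surface
#'   layers (>= 1; 1 = no enrichment).
#' @param depth surface layer depth in nm.
#' @param seed RNG seed for the resampled layer particles.
#' @return The corrupted [particle_set()].
#' @export
inject_artifacts <- function(ps, tilt_x = 0, tilt_y = 0,
                             surface_enrichment = 1, depth = 10,
                             seed = NULL) {
  stopifnot(inherits(ps, "particle_set"))
  if (surface_enrichment < 1)
    stop("`surface_enrichment` must be >= 1")
  out <- ps
  if (surface_enrichment > 1) {
    if (2 * depth > ps$box$extents[3])
      stop("surface layers overlap; reduce `depth`")
    rho <- number_density(ps)
    lam <- (surface_enrichment - 1) * rho *
      ps$box$extents[1] * ps$box$extents[2] * depth
    extra <- .with_seed(seed, {
      do.call(rbind, lapply(c(0, 1), function(top) {
        ne <- rpois(1, lam)
        if (ne == 0) return(NULL)
        z0 <- if (top) ps$box$origin[3] + ps$box$extents[3] - depth
              else ps$box$origin[3]
        cbind(ps$box$origin[1] + runif(ne) * ps$box$extents[1],
              ps$box$origin[2] + runif(ne) * ps$box$extents[2],
              z0 + runif(ne) * depth)
      }))
    })
    if (!is.null(extra))
      out <- particle_set(rbind(ps$coordinates, extra), ps$box,
                          ps$temperature, ps$molecular_weight, ps$label)
  }
  if (tilt_x != 0 || tilt_y != 0)
    out <- tilt_particles(out, tilt_x, tilt_y)
  out
}
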