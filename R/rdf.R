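#' Boundary-corrected radial distribution function
#'
#' Computes g(r) on a uniform grid by binning pair separations and
#' normalising each bin, per particle, by the volume of the spherical
#' shell actually available inside the box:
#' `g(r_k) = sum_i n_i(k) / sum_i rho_others * V_shell(x_i, k)` with
#' `rho_others = (N - 1) / V`.  In a thin slab the shell-cuboid clipping
#' dominates the normalisation (the shell range is comparable to the slab
#' height), so edge particles are corrected rather than discarded.  On
#' fully periodic axes the minimum-image convention is used and the shell
#' is not clipped.
#'
#' The default grid, 100 bins of 0.3 nm (one tomogram pixel), reaches
#' r = 30 nm.
#'
#' @param ps a [particle_set()] with at least two particles.
#' @param bin_width bin width in nm.
#' @param n_bins number of bins.
#' @return An object of class `radial_distribution` with fields
#'   `r_centers`, `bin_width`, `g`, `pair_counts` (unordered pairs per
#'   bin), `n_particles`, `density` (nm^-3), `replicate_std` (`NULL` for a
#'   single set) and the normalising `shell_volumes`.
#' @export
compute_rdf <- function(ps, bin_width = 0.3, n_bins = 100) {
  stopifnot(inherits(ps, "particle_set"))
  n <- n_particles(ps)
  if (n < 2) stop("the RDF needs at least 2 particles")
  if (!is.finite(bin_width) || bin_width <= 0) stop("`bin_width` must be positive")
  rmax <- bin_width * n_bins
  if (rmax > min(ps$box$extents) / 2)
    warning(sprintf(
      "RDF range %.3g nm exceeds half the smallest box extent (%.3g nm)",
      rmax, min(ps$box$extents) / 2))
  counts <- cpp_pair_counts(ps$coordinates, bin_width, as.integer(n_bins),
                            ps$box$origin, ps$box$extents, ps$box$periodic)
  edges <- bin_width * (0:n_bins)
  if (all(ps$box$periodic)) {
    shells <- n * 4 * pi / 3 * diff(edges^3)
  } else {
    shells <- cpp_sum_shell_volumes(ps$coordinates, edges, ps$box$origin,
                                    ps$box$extents, ps$box$periodic)
  }
  rho_others <- (n - 1) / box_volume(ps$box)
  norm <- rho_others * shells   # expected ordered pair count per bin at g = 1
  g <- ifelse(norm > 0, 2 * counts / norm, 0)
  structure(list(r_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 bin_width = bin_width, g = as.numeric(g),
                 pair_counts = as.numeric(counts), n_particles = n,
                 density = n / box_volume(ps$box),
                 replicate_std = NULL, shell_volumes = as.numeric(shells),
                 norm = as.numeric(norm),
                 n_replicates = 1L, temperature = ps$temperature),
            class = "radial_distribution")
}

#' RDF averaged over a list of particle sets
#'
#' Convenience wrapper: [compute_rdf()] on each frame, then
#' [average_rdfs()].
#'
#' @param frames list of [particle_set()] objects on a common box.
#' @inheritParams compute_rdf
#' @return A `radial_distribution`.
#' @export
compute_rdf_frames <- function(frames, bin_width = 0.3, n_bins = 100) {
  average_rdfs(lapply(frames, compute_rdf, bin_width = bin_width,
                      n_bins = n_bins))
}

.rdf_edges <- function(rdf) {
  c(rdf$r_centers - rdf$bin_width / 2, tail(rdf$r_centers, 1) + rdf$bin_width / 2)
}

#' Average replicate RDFs
#'
#' Per-bin mean of g weighted by each replicate's expected pair count at
#' g = 1 (density times available shell volume).  This is the pooled
#' estimator `sum(counts) / sum(expected)`: replicates with more pairs
#' carry proportionally more information, but -- unlike weighting by the
#' observed pair counts -- the weights are independent of the counting
#' noise, so sparse bins are not biased upward by self-weighting.  The
#' unweighted per-bin standard deviation across replicates is kept as the
#' replicate spread.
#'
#' @param reps list of `radial_distribution` objects on identical grids.
#' @return A `radial_distribution`; `pair_counts` are summed across
#'   replicates.
#' @export
average_rdfs <- function(reps) {
  if (!is.list(reps) || length(reps) < 1)
    stop("`reps` must be a non-empty list of radial_distribution objects")
  if (length(reps) == 1) return(reps[[1]])
  r0 <- reps[[1]]$r_centers
  bw <- reps[[1]]$bin_width
  for (r in reps) {
    if (length(r$r_centers) != length(r0) || abs(r$bin_width - bw) > 1e-12 ||
        max(abs(r$r_centers - r0)) > 1e-9)
      stop("replicate RDF grids do not match")
  }
  gm <- vapply(reps, function(r) r$g, numeric(length(r0)))
  cm <- vapply(reps, function(r) r$pair_counts, numeric(length(r0)))
  wm <- vapply(reps, function(r) r$norm, numeric(length(r0)))
  wsum <- rowSums(wm)
  g <- ifelse(wsum > 0, rowSums(gm * wm) / wsum, 0)
  out <- reps[[1]]
  out$g <- as.numeric(g)
  out$pair_counts <- rowSums(cm)
  out$replicate_std <- apply(gm, 1, sd)
  out$n_particles <- mean(vapply(reps, function(r) r$n_particles, numeric(1)))
  out$density <- mean(vapply(reps, function(r) r$density, numeric(1)))
  out$shell_volumes <- Reduce(`+`, lapply(reps, function(r) r$shell_volumes))
  out$norm <- wsum
  out$n_replicates <- sum(vapply(reps, function(r) r$n_replicates, integer(1)))
  out
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf("<radial_distribution> %d bins of %.3g nm (r <= %.3g nm), N = %.6g, rho = %.4g nm^-3, %d replicate(s)\n",
              length(x$g), x$bin_width,
              tail(x$r_centers, 1) + x$bin_width / 2, x$n_particles,
              x$density, x$n_replicates))
  invisible(x)
}

#' Potential curve on a distance grid
#'
#' Values are in units of kB*T; `valid` masks bins where the underlying
#' g(r) dropped to (or below) the floor, where the logarithm and the
#' Boltzmann inversion are undefined.  Invalid bins carry `NA`, never a
#' clamped value.
#'
#' @param r distance grid (nm), uniform spacing.
#' @param value potential in kB*T.
#' @param valid logical mask; defaults to finite values.
#' @param temperature kelvin.
#' @param kind `"PMF"`, `"PIP"` or `"model"`.
#' @return An object of class `potential_curve`.
#' @export
potential_curve <- function(r, value, valid = NULL, temperature = 293.15,
                            kind = c("PMF", "PIP", "model")) {
  kind <- match.arg(kind)
  r <- as.numeric(r); value <- as.numeric(value)
  if (length(r) < 2 || length(value) != length(r))
    stop("`r` and `value` must be equal-length vectors (>= 2)")
  dr <- diff(r)
  if (any(dr <= 0) || max(abs(dr - dr[1])) > 1e-9 * dr[1] + 1e-12)
    stop("`r` must be a strictly increasing uniform grid")
  if (is.null(valid)) valid <- is.finite(value)
  if (any(valid & !is.finite(value)))
    stop("potential values must be finite wherever `valid` is TRUE")
  value[!valid] <- NA_real_
  structure(list(r = r, value = value, valid = as.logical(valid),
                 temperature = temperature, kind = kind),
            class = "potential_curve")
}

#' @export
print.potential_curve <- function(x, ...) {
  cat(sprintf("<potential_curve> kind = %s, %d bins (%d valid), T = %.2f K\n",
              x$kind, length(x$r), sum(x$valid), x$temperature))
  invisible(x)
}

#' Potential of mean force from the RDF
#'
#' Applies the reversible work theorem `W(r) = -kB T ln g(r)`, reported in
#' kB*T units.  Bins with `g <= g_floor` are masked invalid rather than
#' clamped, so unresolved repulsion propagates honestly into fits and
#' plots.
#'
#' @param rdf a `radial_distribution`.
#' @param temperature kelvin (metadata only; values are in kB*T).
#' @param g_floor mask threshold on g (default 1e-3).
#' @return A [potential_curve()] of kind `"PMF"`.
#' @export
pmf_from_rdf <- function(rdf, temperature = rdf$temperature, g_floor = 1e-3) {
  stopifnot(inherits(rdf, "radial_distribution"))
  if (is.null(temperature)) temperature <- 293.15
  if (temperature <= 0) stop("`temperature` must be positive")
  valid <- rdf$g > g_floor
  w <- rep(NA_real_, length(rdf$g))
  w[valid] <- -log(rdf$g[valid])
  out <- potential_curve(rdf$r_centers, w, valid = valid,
                         temperature = temperature, kind = "PMF")
  out$g_floor <- g_floor
  out
}

#' Effective pair interaction potential from concentration-series PMFs
#'
#' At infinite dilution the PMF converges to the concentration-independent
#' pair interaction potential.  Given PMFs measured at several
#' concentrations, this reports their pointwise mean as the effective PIP
#' together with the maximum spread across concentrations over bins valid
#' in every curve; a flag marks whether the spread exceeds `threshold`,
#' i.e. whether many-body corrections are in fact visible.
#'
#' @param pmfs list of [potential_curve()] objects on a common grid.
#' @param threshold spread flag threshold in kB*T (default 0.2).
#' @return A list with `pip` (a `potential_curve` of kind `"PIP"`),
#'   `max_deviation` (kB*T; `NA` for a single curve), `flag` and
#'   `threshold`.
#' @export
effective_pip <- function(pmfs, threshold = 0.2) {
  if (inherits(pmfs, "potential_curve")) pmfs <- list(pmfs)
  if (length(pmfs) < 1) stop("need at least one PMF curve")
  r0 <- pmfs[[1]]$r
  for (p in pmfs) {
    stopifnot(inherits(p, "potential_curve"))
    if (length(p$r) != length(r0) || max(abs(p$r - r0)) > 1e-9)
      stop("PMF curves must share a common r grid")
  }
  if (length(pmfs) == 1) {
    pip <- pmfs[[1]]
    pip$kind <- "PIP"
    return(list(pip = pip, max_deviation = NA_real_, flag = FALSE,
                threshold = threshold))
  }
  vals <- vapply(pmfs, function(p) p$value, numeric(length(r0)))
  valid_all <- Reduce(`&`, lapply(pmfs, function(p) p$valid))
  mean_w <- rowMeans(vals)
  mean_w[!valid_all] <- NA_real_
  spread <- apply(vals, 1, function(v) diff(range(v)))
  max_dev <- if (any(valid_all)) max(spread[valid_all]) else NA_real_
  pip <- potential_curve(r0, mean_w, valid = valid_all,
                         temperature = pmfs[[1]]$temperature, kind = "PIP")
  list(pip = pip, max_deviation = max_dev,
       flag = is.finite(max_dev) && max_dev > threshold,
       threshold = threshold)
}
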