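#' Concentration profile along the slab height
#'
#' Bins particles along z and reports per-bin number density (and mass
#' concentration when the molecular weight is known), plus the plateau
#' range: the widest contiguous run of bins whose density lies within
#' `plateau_frac` of the median bin density.  Surface-enriched layers (for
#' instance from adsorption at the air-water interface) fall outside the
#' plateau and can then be cropped away.
#'
#' @param ps a [particle_set()].
#' @param dz z-bin width in nm (must not exceed the slab height).
#' @param plateau_frac relative deviation from the median bin density
#'   tolerated inside the plateau (default 0.2).
#' @return An object of class `concentration_profile` with fields
#'   `z_bin_centers`, `counts`, `number_density` (nm^-3),
#'   `mass_concentration` (mg/mL, `NULL` without molecular weight),
#'   `plateau_range` `(z_lo, z_hi)` and `dz`.  Conservation holds exactly:
#'   `sum(counts) == N` and each `number_density * Lx * Ly * dz == count`.
#' @export
concentration_profile <- function(ps, dz = 2, plateau_frac = 0.2) {
  stopifnot(inherits(ps, "particle_set"))
  H <- ps$box$extents[3]
  if (!is.finite(dz) || dz <= 0) stop("`dz` must be positive")
  if (dz > H) stop("`dz` exceeds the slab height")
  z0 <- ps$box$origin[3]
  nb <- ceiling(H / dz - 1e-12)
  edges <- z0 + dz * (0:nb)
  z <- ps$coordinates[, 3]
  idx <- floor((z - z0) / dz) + 1L          # half-open [lo, hi) bins
  idx[idx > nb] <- nb                        # guard top edge round-off
  counts <- tabulate(idx, nbins = nb)
  area <- ps$box$extents[1] * ps$box$extents[2]
  dens <- counts / (area * dz)
  med <- median(dens)
  ok <- abs(dens - med) <= plateau_frac * med
  plateau <- c(NA_real_, NA_real_)
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values)[which.max(r$lengths[r$values])]
    plateau <- c(edges[starts[best]], edges[ends[best] + 1L])
  }
  structure(list(z_bin_centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 counts = counts, number_density = dens,
                 mass_concentration = if (!is.null(ps$molecular_weight))
                   .mass_concentration(dens, ps$molecular_weight) else NULL,
                 plateau_range = plateau, dz = dz,
                 plateau_frac = plateau_frac, box = ps$box),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> %d bins of %.3g nm, plateau [%.4g, %.4g] nm\n",
              length(x$counts), x$dz, x$plateau_range[1], x$plateau_range[2]))
  if (!is.null(x$mass_concentration))
    cat(sprintf("  median concentration %.3g mg/mL\n",
                median(x$mass_concentration)))
  invisible(x)
}

#' Crop a particle set to the central slab
#'
#' Retains particles with `z` in `[z_lo, z_hi)` (half-open, bit-exact: a
#' particle exactly at `z_hi` is excluded, one at `z_lo` included) and
#' updates the box height and origin accordingly.  In auto mode (both
#' bounds `NULL`) the plateau of a [concentration_profile()] is used,
#' shrunk by one extra bin on each side as a conservative margin against
#' partially enriched edge bins.
#'
#' @param ps a [particle_set()].
#' @param z_lo,z_hi crop bounds in nm, or `NULL` (both) for auto mode.
#' @param dz profile bin width used in auto mode.
#' @param plateau_frac plateau tolerance used in auto mode.
#' @return The cropped [particle_set()].
#' @export
crop_central_slab <- function(ps, z_lo = NULL, z_hi = NULL, dz = 2,
                              plateau_frac = 0.2) {
  stopifnot(inherits(ps, "particle_set"))
  zmin <- ps$box$origin[3]
  zmax <- zmin + ps$box$extents[3]
  if (is.null(z_lo) != is.null(z_hi))
    stop("give both `z_lo` and `z_hi`, or neither for auto mode")
  if (is.null(z_lo)) {
    prof <- concentration_profile(ps, dz = dz, plateau_frac = plateau_frac)
    if (anyNA(prof$plateau_range))
      stop("no density plateau found; supply explicit crop bounds")
    z_lo <- prof$plateau_range[1] + dz
    z_hi <- prof$plateau_range[2] - dz
  }
  if (!(z_lo < z_hi))
    stop("`z_lo` must be below `z_hi`")
  if (z_lo < zmin - 1e-9 || z_hi > zmax + 1e-9)
    stop("crop bounds lie outside the slab")
  z <- ps$coordinates[, 3]
  keep <- z >= z_lo & z < z_hi
  if (sum(keep) < 2)
    stop("cropping would leave fewer than 2 particles")
  box <- box_geometry(c(ps$box$extents[1:2], z_hi - z_lo),
                      origin = c(ps$box$origin[1:2], z_lo),
                      periodic = ps$box$periodic)
  particle_set(ps$coordinates[keep, , drop = FALSE], box, ps$temperature,
               ps$molecular_weight, ps$label)
}
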