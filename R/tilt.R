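#' Estimate slab tilt from particle coordinates
#'
#' Fits the least-squares plane `z = a + b*x + c*y` through all centroids.
#' For a thin slab whose mid-plane is tilted away from the xy-plane the
#' fitted plane tracks the slab, so `atan(b)` and `atan(c)` recover the
#' tilt angles about the y- and x- viewing planes (XZ and YZ tilts).
#'
#' @param ps a [particle_set()] with at least 10 particles.
#' @return An object of class `tilt_estimate` with fields `angle_x` and
#'   `angle_y` (degrees), `plane_coefficients` `(a, b, c)`, `residual_rms`
#'   (nm) and a logical `slab_like` diagnostic: `FALSE` when the residual
#'   spread exceeds 10% of the mean lateral extent, i.e. when the cloud has
#'   no usable slab structure and the angles should not be trusted.
#' @export
estimate_tilt <- function(ps) {
  stopifnot(inherits(ps, "particle_set"))
  xyz <- ps$coordinates
  if (nrow(xyz) < 10)
    stop("tilt estimation needs at least 10 particles")
  fit <- lm(xyz[, 3] ~ xyz[, 1] + xyz[, 2])
  ab <- unname(coef(fit))
  # attenuation correction for slab thickness: a tilted slab of residual
  # variance s^2 shrinks the fitted slope by (1 - s^2 / var(lateral));
  # skipped when the cloud is nearly isotropic (no slab structure)
  s2 <- mean(fit$residuals^2)
  for (k in 2:3) {
    vl <- var(xyz[, k - 1])
    if (s2 < 0.5 * vl) ab[k] <- ab[k] / (1 - s2 / vl)
  }
  angle_x <- atan(ab[2]) * 180 / pi
  angle_y <- atan(ab[3]) * 180 / pi
  if (abs(angle_x) >= 45 || abs(angle_y) >= 45)
    stop("fitted tilt exceeds 45 degrees; the coordinate set is not a slab")
  rms <- sqrt(mean(fit$residuals^2))
  structure(list(angle_x = angle_x, angle_y = angle_y,
                 plane_coefficients = c(a = ab[1], b = ab[2], c = ab[3]),
                 residual_rms = rms,
                 slab_like = rms <= 0.1 * mean(ps$box$extents[1:2])),
            class = "tilt_estimate")
}

#' @export
print.tilt_estimate <- function(x, ...) {
  cat(sprintf("<tilt_estimate> angle_x = %.3f deg, angle_y = %.3f deg, residual rms = %.3g nm%s\n",
              x$angle_x, x$angle_y, x$residual_rms,
              if (!x$slab_like) " [warning: no slab structure]" else ""))
  invisible(x)
}

#' Construct a tilt estimate from known angles
#' @param angle_x,angle_y tilt angles in degrees (|angle| < 45).
#' @return A `tilt_estimate` with the corresponding plane coefficients.
#' @export
tilt_estimate <- function(angle_x, angle_y) {
  if (abs(angle_x) >= 45 || abs(angle_y) >= 45)
    stop("|tilt angles| must be below 45 degrees")
  structure(list(angle_x = angle_x, angle_y = angle_y,
                 plane_coefficients = c(a = 0, b = tan(angle_x * pi / 180),
                                        c = tan(angle_y * pi / 180)),
                 residual_rms = 0, slab_like = TRUE),
            class = "tilt_estimate")
}

# Rodrigues rotation taking unit vector `from` onto unit vector `to`
.rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2))
  cth <- sum(from * to)
  if (s < 1e-15) {
    if (cth > 0) return(diag(3))
    # antiparallel never occurs for |tilt| < 45 deg
    stop("degenerate rotation")
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

.tilt_rotation <- function(tilt) {
  b <- tilt$plane_coefficients[["b"]]
  cc <- tilt$plane_coefficients[["c"]]
  n <- c(-b, -cc, 1)
  n <- n / sqrt(sum(n^2))
  .rotation_between(n, c(0, 0, 1))
}

.rotate_about_centroid <- function(ps, rot) {
  xyz <- ps$coordinates
  ctr <- colMeans(xyz)
  out <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, ctr, `+`)
  if (max(abs(rot - diag(3))) < 1e-15)
    return(particle_set(out, ps$box, ps$temperature, ps$molecular_weight,
                        ps$label))
  if (any(ps$box$periodic))
    stop("cannot rotate a periodic particle set")
  lo <- apply(out, 2, min) - 1e-9
  hi <- apply(out, 2, max) + 1e-9
  box <- box_geometry(hi - lo, origin = lo, periodic = FALSE)
  particle_set(out, box, ps$temperature, ps$molecular_weight, ps$label)
}

#' Remove slab tilt by a rigid rotation
#'
#' Rigidly rotates the coordinates about their centroid so that the fitted
#' slab plane normal aligns with the z-axis.  Being a rigid motion, all
#' pairwise distances are preserved exactly; the box is replaced by the
#' tight bounding box of the rotated coordinates (unchanged when the tilt
#' is zero).
#'
#' @param ps a [particle_set()] (non-periodic).
#' @param tilt a `tilt_estimate`, from [estimate_tilt()] or [tilt_estimate()].
#' @return The corrected [particle_set()].
#' @export
apply_tilt_correction <- function(ps, tilt) {
  stopifnot(inherits(ps, "particle_set"), inherits(tilt, "tilt_estimate"))
  .rotate_about_centroid(ps, .tilt_rotation(tilt))
}

#' Apply a known tilt to a flat slab
#'
#' Inverse of [apply_tilt_correction()] for the same angles; used to build
#' synthetic tilted data and for round-trip checks.
#'
#' @param ps a [particle_set()].
#' @param angle_x,angle_y tilt angles in degrees.
#' @return The tilted [particle_set()] (box replaced by the bounding box).
#' @export
tilt_particles <- function(ps, angle_x, angle_y) {
  rot <- t(.tilt_rotation(tilt_estimate(angle_x, angle_y)))
  .rotate_about_centroid(ps, rot)
}
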