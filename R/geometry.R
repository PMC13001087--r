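#' Axis-aligned box geometry
#'
#' Describes the volume that contains a particle set: an axis-aligned
#' cuboid with an origin, per-axis extents `(Lx, Ly, H)` in nanometres and
#' per-axis periodicity flags.  Tomographic slabs are non-periodic;
#' simulation boxes are fully periodic.
#'
#' @param extents numeric length-3, positive box edge lengths (nm); the
#'   third component is the slab height H.
#' @param origin numeric length-3, coordinates of the lower box corner (nm).
#' @param periodic logical length-3 (or length-1, recycled), whether each
#'   axis is periodic.
#' @return An object of class `box_geometry` with fields `origin`,
#'   `extents` and `periodic`.
#' @examples
#' box_geometry(c(800, 800, 100))
#' @export
box_geometry <- function(extents, origin = c(0, 0, 0), periodic = FALSE) {
  extents <- as.numeric(extents)
  origin <- as.numeric(origin)
  if (length(extents) != 3 || anyNA(extents) || any(!is.finite(extents)))
    stop("`extents` must be three finite numbers")
  if (any(extents <= 0))
    stop("all box extents must be positive")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers")
  if (length(periodic) == 1) periodic <- rep(periodic, 3)
  periodic <- as.logical(periodic)
  if (length(periodic) != 3 || anyNA(periodic))
    stop("`periodic` must be three logical flags")
  structure(list(origin = origin, extents = extents, periodic = periodic),
            class = "box_geometry")
}

#' @export
print.box_geometry <- function(x, ...) {
  cat(sprintf("<box_geometry> %.6g x %.6g x %.6g nm at (%g, %g, %g)%s\n",
              x$extents[1], x$extents[2], x$extents[3],
              x$origin[1], x$origin[2], x$origin[3],
              if (any(x$periodic))
                paste0(", periodic: ",
                       paste(c("x", "y", "z")[x$periodic], collapse = ""))
              else ""))
  invisible(x)
}

#' Box volume in nm^3
#' @param box a [box_geometry()].
#' @return Volume `Lx * Ly * H` in nm^3.
#' @export
box_volume <- function(box) {
  stopifnot(inherits(box, "box_geometry"))
  prod(box$extents)
}

# TRUE for points inside the box under the half-open convention [lo, hi);
# periodic axes are always considered inside.
.inside_box <- function(coords, box, tol = 1e-9) {
  ok <- rep(TRUE, nrow(coords))
  for (a in 1:3) {
    if (box$periodic[a]) next
    lo <- box$origin[a] - tol
    hi <- box$origin[a] + box$extents[a] + tol
    ok <- ok & coords[, a] >= lo & coords[, a] < hi
  }
  ok
}

#' Volume of a spherical shell clipped to a box
#'
#' Volume of `{x : r_in <= |x - center| < r_out}` intersected with the box.
#' Interior shells reduce to the analytic `(4/3) pi (r_out^3 - r_in^3)`;
#' shells cut by one pair of walls use the closed-form spherical-cap
#' expression; the general case is evaluated by panelled Gauss-Legendre
#' quadrature of exact disk-rectangle slice areas, accurate far beyond the
#' 0.5% relative tolerance required by the RDF normalisation.  Periodic
#' axes do not clip.
#'
#' @param center numeric length-3 position inside the box (nm).
#' @param r_in,r_out inner/outer shell radii (nm), `0 <= r_in < r_out`.
#' @param box a [box_geometry()].
#' @return Shell volume in nm^3.
#' @examples
#' b <- box_geometry(c(100, 100, 100))
#' shell_volume_in_box(c(50, 50, 50), 0, 10, b) # 4/3*pi*1000
#' @export
shell_volume_in_box <- function(center, r_in, r_out, box) {
  stopifnot(inherits(box, "box_geometry"))
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("`center` must be three finite numbers")
  if (!is.finite(r_in) || !is.finite(r_out) || r_in < 0 || r_out <= r_in)
    stop("need 0 <= r_in < r_out")
  for (a in 1:3) {
    if (box$periodic[a]) next
    if (center[a] < box$origin[a] ||
        center[a] > box$origin[a] + box$extents[a])
      stop("shell center lies outside the box")
  }
  cpp_shell_volume(center, r_in, r_out, box$origin, box$extents, box$periodic)
}
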