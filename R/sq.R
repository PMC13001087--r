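#' Default wavenumber grid: 120 log-spaced points over 0.05-6 nm^-1
#' @return Numeric vector of q values (nm^-1).
#' @export
default_q_grid <- function() {
  exp(seq(log(0.05), log(6), length.out = 120))
}

#' Isotropic structure factor from a binned RDF
#'
#' Evaluates
#' `S(q) = 1 + 4 pi rho int_0^R (g(r) - 1) w(r) sin(qr)/(qr) r^2 dr`
#' on the histogram grid of the RDF.  The default Lorch window
#' `w(r) = sinc(pi r / R)` damps the hard truncation at the RDF cutoff R,
#' which otherwise produces spurious low-q ripple; `window = "none"`
#' disables it.  Values below `q_min_reliable = 2 pi / R` are reported but
#' should not be read off the curve -- use [s_zero()] instead.
#'
#' @param rdf a `radial_distribution`.
#' @param q wavenumber grid (nm^-1).
#' @param window `"lorch"` (default) or `"none"`.
#' @param density number density used in the transform; defaults to the
#'   RDF's own.
#' @return An object of class `structure_factor` with fields `q`, `S`,
#'   `density`, `q_min_reliable` and `window`.
#' @export
structure_factor <- function(rdf, q = default_q_grid(),
                             window = c("lorch", "none"),
                             density = rdf$density) {
  stopifnot(inherits(rdf, "radial_distribution"))
  window <- match.arg(window)
  q <- as.numeric(q)
  if (length(q) < 1 || any(!is.finite(q)) || any(q <= 0))
    stop("`q` must be a non-empty grid of positive wavenumbers")
  r <- rdf$r_centers
  R <- max(.rdf_edges(rdf))
  w <- if (window == "lorch") {
    x <- pi * r / R
    sin(x) / x
  } else rep(1, length(r))
  h <- (rdf$g - 1) * w * r^2 * rdf$bin_width
  S <- vapply(q, function(qk) {
    x <- qk * r
    1 + 4 * pi * density * sum(h * sin(x) / x)
  }, numeric(1))
  structure(list(q = q, S = S, density = density,
                 q_min_reliable = 2 * pi / R, window = window),
            class = "structure_factor")
}

#' @export
print.structure_factor <- function(x, ...) {
  cat(sprintf("<structure_factor> %d q points in [%.3g, %.3g] nm^-1, rho = %.4g nm^-3, reliable above %.3g nm^-1 (window: %s)\n",
              length(x$q), min(x$q), max(x$q), x$density, x$q_min_reliable,
              x$window))
  invisible(x)
}

#' Structure factor by the direct Debye pair sum
#'
#' Evaluates `S(q) = 1 + (2/N) sum_{i<j} sin(q r_ij)/(q r_ij)` on one or
#' several configurations, averaging over frames.  This route uses nothing
#' but raw pair distances, so it serves as an independent oracle for
#' [structure_factor()].  With a finite `r_max` the sum is truncated at
#' that separation and the analytic ideal-gas contribution of the
#' truncated volume, `4 pi rho (sin(qR) - qR cos(qR)) / q^3`, is
#' subtracted so the estimator still tends to 1 for an ideal gas.
#'
#' @param ps a [particle_set()] or a list of them (frames).
#' @param q wavenumber grid (nm^-1).
#' @param min_image use minimum-image pair distances (for fully periodic
#'   boxes).
#' @param r_max pair-distance cutoff in nm (`Inf` = full sum).
#' @return A `structure_factor`; the per-frame curves are kept in
#'   `$S_frames` (a matrix, q by frames) for error estimation.
#' @export
structure_factor_direct <- function(ps, q = default_q_grid(),
                                    min_image = FALSE, r_max = Inf) {
  frames <- if (inherits(ps, "particle_set")) list(ps) else ps
  stopifnot(length(frames) >= 1, inherits(frames[[1]], "particle_set"))
  q <- as.numeric(q)
  if (any(q <= 0)) stop("`q` must be positive")
  box <- frames[[1]]$box
  sf <- vapply(frames, function(f) {
    if (n_particles(f) < 2) stop("the Debye sum needs at least 2 particles")
    cpp_debye_sum(f$coordinates, q, min_image, f$box$extents,
                  if (is.finite(r_max)) r_max else -1)
  }, numeric(length(q)))
  sf <- matrix(sf, nrow = length(q))
  rho <- mean(vapply(frames, number_density, numeric(1)))
  S <- rowMeans(sf)
  if (is.finite(r_max)) {
    ideal <- 4 * pi * rho * (sin(q * r_max) - q * r_max * cos(q * r_max)) / q^3
    S <- S - ideal
    sf <- sf - ideal
  }
  out <- structure(list(q = q, S = S, density = rho,
                        q_min_reliable = if (is.finite(r_max))
                          2 * pi / r_max else 2 * pi / min(box$extents),
                        window = "debye"),
                   class = "structure_factor")
  out$S_frames <- sf
  out
}

#' Zero-angle structure factor
#'
#' Two routes: (A) the compressibility relation `S(0) = 1 + rho * G_inf`
#' from a Kirkwood-Buff integral, and (B) linear extrapolation of S(q)
#' against q^2 over the first reliable octave
#' `q in [q_min_reliable, 2 q_min_reliable]`.  S(0) is never read off the
#' curve below `q_min_reliable`.
#'
#' @param sf a `structure_factor` (route B).
#' @param G_inf Kirkwood-Buff integral in nm^3 (route A).
#' @param density number density in nm^-3 (route A; defaults to `sf$density`).
#' @return S(0), a single number.
#' @export
s_zero <- function(sf = NULL, G_inf = NULL, density = NULL) {
  if (!is.null(G_inf)) {
    if (is.null(density)) {
      if (is.null(sf)) stop("route A needs `density`")
      density <- sf$density
    }
    return(1 + density * G_inf)
  }
  stopifnot(inherits(sf, "structure_factor"))
  q0 <- sf$q_min_reliable
  sel <- sf$q >= q0 & sf$q <= 2 * q0
  if (sum(sel) < 3)
    stop("fewer than 3 reliable low-q points for the q^2 extrapolation")
  fit <- lm(sf$S[sel] ~ I(sf$q[sel]^2))
  unname(coef(fit)[1])
}

#' Second virial coefficient from the concentration dependence of S(0)
#'
#' In the dilute limit `S(0) = 1 - 2 B22 rho`, so a straight line through
#' `(rho, S0)` points with intercept pinned at 1 yields B22 = -slope / 2.
#'
#' @param density number densities in nm^-3 (>= 2 distinct values).
#' @param s0 matching S(0) values.
#' @param sigma optional known per-point standard deviations of S(0); when
#'   given, the fit is weighted by `1/sigma^2` and the slope error comes
#'   from exact error propagation rather than from the residuals (with
#'   only a handful of concentrations, residual-based errors are
#'   t-distributed with very few degrees of freedom and undercover badly).
#' @param weights optional fit weights (ignored when `sigma` is given).
#' @param fix_intercept pin the intercept at 1 (default) or fit it.
#' @return A list with `b22` (nm^3), `stderr`, `slope` and `intercept`.
#' @export
b22_from_s0_slope <- function(density, s0, sigma = NULL, weights = NULL,
                              fix_intercept = TRUE) {
  density <- as.numeric(density); s0 <- as.numeric(s0)
  n <- length(density)
  if (n < 2 || length(s0) != n)
    stop("need at least two (density, S0) points")
  if (length(unique(density)) < 2)
    stop("densities are identical; the slope fit is singular")
  if (!is.null(sigma)) weights <- 1 / sigma^2
  if (is.null(weights)) weights <- rep(1, n)
  if (fix_intercept) {
    m <- sum(weights * density * (s0 - 1)) / sum(weights * density^2)
    if (!is.null(sigma)) {
      se_m <- sqrt(1 / sum(density^2 / sigma^2))
    } else {
      resid <- s0 - 1 - m * density
      dof <- n - 1L
      se_m <- if (dof > 0)
        sqrt(sum(weights * resid^2) / dof / sum(weights * density^2))
      else NA_real_
    }
    intercept <- 1
  } else {
    fit <- lm(s0 ~ density, weights = weights)
    m <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    se_m <- summary(fit)$coefficients[2, 2]
  }
  list(b22 = -m / 2, stderr = se_m / 2, slope = m, intercept = intercept)
}
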