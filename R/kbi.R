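#' Kirkwood-Buff integral by direct RDF integration
#'
#' Running integral `G(r) = 4 pi int_0^r (g(s) - 1) s^2 ds`.  By default
#' each histogram bin contributes its exact shell integral
#' `(g_k - 1) * 4 pi (e_{k+1}^3 - e_k^3) / 3` (piecewise-constant g), which
#' integrates step-like g exactly and agrees with the trapezoidal rule to
#' O(bin_width^2) for smooth g; `method = "trapezoid"` applies the
#' trapezoidal rule on bin centers instead.
#'
#' Direct integration amplifies the r^2-weighted noise of the measured
#' g(r) at large r; prefer [kbi_subbox()] plus [kbi_extrapolate()] on
#' noisy data.
#'
#' @param rdf a `radial_distribution`.
#' @param cutoff upper integration limit in nm (default: the RDF range).
#' @param method `"histogram"` (default) or `"trapezoid"`.
#' @return An object of class `cumulative_kbi` with fields `r` (bin
#'   edges), `G_of_r` (nm^3, `G(0) = 0`), `G_inf` (value at the cutoff)
#'   and `cutoff`.
#' @export
kbi_direct <- function(rdf, cutoff = NULL,
                       method = c("histogram", "trapezoid")) {
  stopifnot(inherits(rdf, "radial_distribution"))
  method <- match.arg(method)
  edges <- .rdf_edges(rdf)
  if (is.null(cutoff)) cutoff <- max(edges)
  if (cutoff > max(edges) + 1e-9)
    stop("`cutoff` exceeds the RDF grid")
  if (method == "histogram") {
    contrib <- (rdf$g - 1) * 4 * pi / 3 * diff(edges^3)
    G <- c(0, cumsum(contrib))
    r <- edges
  } else {
    f <- 4 * pi * (rdf$g - 1) * rdf$r_centers^2
    r <- c(0, rdf$r_centers)
    f <- c(0, f)
    G <- c(0, cumsum(diff(r) * (head(f, -1) + tail(f, -1)) / 2))
  }
  # interpolate the running integral at the cutoff (exact in r^3 for the
  # histogram rule, linear in r for the trapezoid rule)
  k <- findInterval(cutoff, r, rightmost.closed = TRUE)
  if (k >= length(r)) {
    G_inf <- G[length(G)]
  } else if (method == "histogram") {
    G_inf <- G[k] + (rdf$g[k] - 1) * 4 * pi / 3 * (cutoff^3 - r[k]^3)
  } else {
    G_inf <- G[k] + (G[k + 1] - G[k]) * (cutoff - r[k]) / (r[k + 1] - r[k])
  }
  structure(list(r = r, G_of_r = G, G_inf = G_inf, cutoff = cutoff,
                 method = method),
            class = "cumulative_kbi")
}

#' @export
print.cumulative_kbi <- function(x, ...) {
  cat(sprintf("<cumulative_kbi> G_inf = %.6g nm^3 at cutoff %.3g nm (%s rule)\n",
              x$G_inf, x$cutoff, x$method))
  invisible(x)
}

#' Sub-box (small-subvolume) density-fluctuation scan
#'
#' Slides parallelepiped sub-boxes with a square base of side L and the
#' full slab height H across the lateral extent at a fixed stride, pools
#' the particle counts over all window positions (and over frames when a
#' list is given), and evaluates the grand-canonical fluctuation estimator
#' `G_eff(L) = V_sub * (var(N) - mean(N)) / mean(N)^2` with the population
#' variance of the pooled counts.  Window membership is half-open on both
#' lateral axes.  When the box is laterally periodic the windows wrap
#' around, making the scan exactly invariant under translations by a
#' multiple of the stride.
#'
#' @param ps a [particle_set()] or a list of them (frames on a common box).
#' @param L sub-box base sides in nm (default: 6 nm to half the smaller
#'   lateral extent, in 2 nm steps).
#' @param stride window step in nm (default 3; decreasing it smooths the
#'   scan without changing its trend).
#' @return An object of class `subbox_scan` with fields `L`, `stride`,
#'   `H`, `G_eff` (nm^3 per L), `SV` (surface-to-volume ratio
#'   `2/H + 4/L`, nm^-1), `n_subboxes`, `n_frames` and per-frame count
#'   moments (`frame_moments`) for bootstrap error estimation.
#' @export
kbi_subbox <- function(ps, L = NULL, stride = 3) {
  frames <- if (inherits(ps, "particle_set")) list(ps) else ps
  stopifnot(length(frames) >= 1, inherits(frames[[1]], "particle_set"))
  box <- frames[[1]]$box
  if (!is.finite(stride) || stride <= 0) stop("`stride` must be positive")
  if (is.null(L)) {
    Lmax <- min(box$extents[1:2]) / 2
    if (Lmax < 6) stop("box too small for the default L grid")
    L <- seq(6, Lmax, by = 2)
  }
  L <- as.numeric(L)
  if (length(L) == 0) stop("`L` must not be empty")
  if (any(L <= 0) || any(L > min(box$extents[1:2]) + 1e-9))
    stop("every L must be positive and no larger than the lateral extents")
  L <- sort(L)
  H <- box$extents[3]
  wrap <- box$periodic[1] && box$periodic[2]
  nf <- length(frames)
  moments <- array(0, dim = c(length(L), nf, 3))
  for (j in seq_len(nf)) {
    f <- frames[[j]]
    x <- f$coordinates[, 1] - box$origin[1]
    y <- f$coordinates[, 2] - box$origin[2]
    for (i in seq_along(L)) {
      moments[i, j, ] <- cpp_subbox_moments(x, y, box$extents[1],
                                            box$extents[2], L[i], stride,
                                            wrap)
    }
  }
  pooled <- apply(moments, c(1, 3), sum)
  G <- .subbox_g(pooled, L, H)
  structure(list(L = L, stride = stride, H = H, G_eff = G,
                 SV = 2 / H + 4 / L, n_subboxes = pooled[, 1],
                 n_frames = nf, frame_moments = moments, box = box),
            class = "subbox_scan")
}

# G_eff from pooled (n, sum N, sum N^2) moments; population variance
.subbox_g <- function(pooled, L, H) {
  n <- pooled[, 1]
  m <- pooled[, 2] / n
  v <- pooled[, 3] / n - m^2
  ifelse(m > 0, L^2 * H * (v - m) / m^2, NA_real_)
}

#' @export
print.subbox_scan <- function(x, ...) {
  cat(sprintf("<subbox_scan> %d sub-box sizes, L in [%.3g, %.3g] nm, stride %.3g nm, H = %.3g nm, %d frame(s)\n",
              length(x$L), min(x$L), max(x$L), x$stride, x$H, x$n_frames))
  invisible(x)
}

#' Extrapolate a sub-box scan to the thermodynamic limit
#'
#' In a finite sample the effective sub-box Kirkwood-Buff integral varies
#' linearly with the window's surface-to-volume ratio,
#' `G_eff(S/V) = G_inf + (S/V) * G'`, so the thermodynamic-limit value is
#' the intercept of an ordinary least-squares line through the scan,
#' restricted to the linear regime `L <= L_max` (50 nm by default).  The
#' fit is unweighted: overlapping windows correlate the per-L errors and
#' would make weighted errors overconfident.  When several frames are
#' available the intercept's standard error is additionally estimated by
#' bootstrap over frames, which is the error reported in `stderr`.
#'
#' @param scan a `subbox_scan`.
#' @param L_max largest sub-box side included in the fit (nm).
#' @param n_boot bootstrap replicates over frames (0 disables).
#' @param seed optional RNG seed for the bootstrap.
#' @return An object of class `kbi_estimate` with `G_inf` (nm^3),
#'   `stderr`, `method = "subbox"` and `fit` diagnostics (intercept,
#'   slope `G'`, R^2, L range used, OLS and bootstrap errors).
#' @export
kbi_extrapolate <- function(scan, L_max = 50, n_boot = 200, seed = NULL) {
  stopifnot(inherits(scan, "subbox_scan"))
  sel <- scan$L <= L_max + 1e-9 & is.finite(scan$G_eff)
  if (sum(sel) < 3)
    stop("fewer than 3 usable sub-box sizes below L_max")
  sv <- scan$SV[sel]
  g <- scan$G_eff[sel]
  fit <- lm(g ~ sv)
  sm <- summary(fit)
  G_inf <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  se_ols <- sm$coefficients[1, 2]
  se_boot <- NA_real_
  if (scan$n_frames > 1 && n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    Ls <- scan$L[sel]
    mom <- scan$frame_moments[sel, , , drop = FALSE]
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(scan$n_frames, replace = TRUE)
      pooled <- apply(mom[, idx, , drop = FALSE], c(1, 3), sum)
      gb <- .subbox_g(pooled, Ls, scan$H)
      ok <- is.finite(gb)
      if (sum(ok) < 3) return(NA_real_)
      unname(coef(lm(gb[ok] ~ sv[ok]))[1])
    }, numeric(1))
    se_boot <- sd(boots, na.rm = TRUE)
  }
  structure(list(G_inf = G_inf,
                 stderr = if (is.finite(se_boot)) se_boot else se_ols,
                 method = "subbox",
                 fit = list(intercept = G_inf, slope = slope,
                            r_squared = sm$r.squared,
                            L_range = range(scan$L[sel]),
                            stderr_ols = se_ols, stderr_boot = se_boot,
                            n_points = sum(sel))),
            class = "kbi_estimate")
}

#' @export
print.kbi_estimate <- function(x, ...) {
  cat(sprintf("<kbi_estimate> G_inf = %.6g +/- %.3g nm^3 (%s)\n",
              x$G_inf, x$stderr, x$method))
  if (!is.null(x$fit))
    cat(sprintf("  fit: slope G' = %.6g nm^2, R^2 = %.4f, L in [%.3g, %.3g] nm\n",
                x$fit$slope, x$fit$r_squared, x$fit$L_range[1],
                x$fit$L_range[2]))
  invisible(x)
}

# Per-bin contributions to int (exp(-U) - 1) r^2 dr on the histogram grid
# of a potential curve.  Bins below the first valid bin -- and interior
# masked bins, which were masked precisely because g fell below the floor
# -- are treated as hard repulsion (exp(-U) = 0, Mayer function -1).
.mayer_profile <- function(curve, cutoff) {
  stopifnot(inherits(curve, "potential_curve"))
  dr <- curve$r[2] - curve$r[1]
  edges <- c(curve$r - dr / 2, tail(curve$r, 1) + dr / 2)
  if (edges[1] < 0) edges[1] <- 0
  if (cutoff > max(edges) + 1e-9)
    stop("`cutoff` exceeds the potential grid")
  f <- ifelse(curve$valid, exp(-curve$value) - 1, -1)
  hi <- pmin(edges[-1], cutoff)
  lo <- pmin(edges[-length(edges)], cutoff)
  f * (hi^3 - lo^3) / 3
}

#' Second virial coefficient from a pair potential
#'
#' `B22 = -2 pi int_0^cutoff (exp(-U(r)) - 1) r^2 dr` with U in kB*T
#' units, each histogram bin integrated exactly.  Distances below the
#' first valid bin are treated as hard repulsion.
#'
#' @param U a [potential_curve()] (typically kind `"PIP"`).
#' @param cutoff upper integration limit in nm (default: the grid range).
#' @return B22 in nm^3.
#' @export
b22_from_potential <- function(U, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- max(U$r) + (U$r[2] - U$r[1]) / 2
  -2 * pi * sum(.mayer_profile(U, cutoff))
}

#' Kirkwood-Buff integral from a potential of mean force
#'
#' `G_inf = 4 pi int_0^cutoff (exp(-W(r)) - 1) r^2 dr`; the same Mayer
#' quadrature as [b22_from_potential()] with a `+4 pi` kernel, so that for
#' any curve `kbi_from_pmf(U) = -2 * b22_from_potential(U)` -- the exact
#' dilute-limit identity relating the two quantities.
#'
#' @param W a [potential_curve()].
#' @inheritParams b22_from_potential
#' @return G_inf in nm^3.
#' @export
kbi_from_pmf <- function(W, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- max(W$r) + (W$r[2] - W$r[1]) / 2
  4 * pi * sum(.mayer_profile(W, cutoff))
}

#' Convert B22 from nm^3 to the mL mol / g^2 convention
#'
#' `B22' = B22 * N_A / MW^2`, with the nm^3 -> mL conversion folded in.
#'
#' @param b22_nm3 B22 in nm^3 per molecule pair.
#' @param molecular_weight in g/mol.
#' @return B22 in mL mol / g^2.
#' @export
b22_to_mol_ml_g2 <- function(b22_nm3, molecular_weight) {
  b22_nm3 * AVOGADRO * 1e-21 / molecular_weight^2
}
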