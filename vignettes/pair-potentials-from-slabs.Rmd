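---
title: "Pair interaction potentials and Kirkwood-Buff integrals from particle coordinates in thin slabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair interaction potentials and Kirkwood-Buff integrals from particle coordinates in thin slabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopip)
```

## The model

Cryo-electron tomography of a vitrified protein solution yields, after
segmentation, the 3D centroid coordinates of every macromolecule in a thin
slab (typically ~800 x 800 x 100 nm³).  Those coordinates are a direct
sample of the equilibrium configurational distribution, so standard
liquid-state statistical mechanics applies:

* the radial distribution function $g(r)$ is the ratio of the observed
  pair density at separation $r$ to the ideal-gas expectation;
* the reversible work theorem inverts it to the potential of mean force,
  $W(r, c) = -k_B T \ln g(r, c)$;
* at low concentration the many-body correction $\Delta w(r, c)$ vanishes
  and $W$ converges to the concentration-independent pair interaction
  potential $U(r)$;
* the Kirkwood-Buff integral
  $G = 4\pi \int_0^\infty (g(r) - 1)\, r^2 \mathrm{d}r$ and the second
  virial coefficient
  $B_{22} = -2\pi \int_0^\infty (e^{-U(r)/k_B T} - 1)\, r^2 \mathrm{d}r$
  summarise the net interaction; in the dilute limit they obey
  $G = -2 B_{22}$ exactly;
* the zero-angle structure factor ties the same quantity to scattering:
  $S(0) = 1 + \rho G \approx 1 - 2 B_{22} \rho$.

Everything in the package works in nanometres, $k_B T$ energy units and
number densities in nm⁻³, with half-open interval membership $[lo, hi)$ on
every axis so that tilings and sub-box scans never double-count.

## Why the slab needs special treatment

The analysed volume is thin: the 30 nm range over which $g(r)$ carries
information is a third of the slab height.  Ignoring that would bias
every bin.  `compute_rdf()` therefore normalises each particle's pair
counts by the volume of the spherical shell *actually available inside
the box*.  Interior shells use the analytic $(4/3)\pi(r_{out}^3 -
r_{in}^3)$; shells cut by a single pair of walls use the closed-form
spherical-cap expression; the general corner case integrates exact
disk-rectangle slice areas with panelled Gauss-Legendre quadrature
(panels split at tangency/corner heights, so the integrand is analytic
within each panel; accuracy is far inside the 0.5% contract).  The test
suite verifies the generic case against rejection-sampling Monte Carlo
and, more stringently, checks that a Poisson gas returns $g \equiv 1$
within counting error in *every* bin, including wall-dominated ones.

Two preprocessing steps precede the statistics, mirroring how tomogram
coordinate arrays are prepared:

* **Tilt correction** (`estimate_tilt()`, `apply_tilt_correction()`): a
  least-squares plane $z = a + bx + cy$ through all centroids, angles
  $\arctan b$, $\arctan c$, followed by a rigid rotation about the
  centroid.  A plane through the slab's density is the minimal model; no
  robust reweighting is applied by default.  Because the slab has finite
  thickness the raw fitted slope is attenuated by
  $(1 - s^2/\mathrm{var}(x))$ where $s$ is the residual spread; the
  estimator divides this factor back out (skipped for near-isotropic
  clouds, which are instead flagged `slab_like = FALSE`).  The remaining
  angle noise is $\approx 1/(\text{aspect ratio} \cdot \sqrt{N})$
  radians, so a 0.1-degree recovery check is a 3-sigma test only for
  $N \gtrsim 4 \times 10^4$ at aspect ratio 8 -- the suite sizes its
  fixtures accordingly.
* **Central-slab cropping** (`crop_central_slab()`): surface layers
  enriched by air-water-interface adsorption are excluded by keeping the
  widest run of height bins whose density lies within 20% of the median
  bin density, then shrinking by one extra bin per side as a margin
  against partially contaminated edge bins.  The rule is a package
  decision: the source workflow highlights a used height range but
  prints no explicit rule.

## Estimating the Kirkwood-Buff integral

Direct integration of $4\pi (g-1) r^2$ (`kbi_direct()`) is exact but
noise-hungry: the $r^2$ weight amplifies the statistical error of the
outer bins, which is why replicate direct integrals scatter widely (a
property the suite asserts).  The default quadrature integrates each
histogram bin's shell exactly (piecewise-constant $g$), which reproduces
step-function closed forms to machine precision and matches the
trapezoidal rule to $O(\Delta^2)$ for smooth curves; the trapezoid is
available as `method = "trapezoid"`.

The robust route is the sub-box (small-subvolume) method
(`kbi_subbox()` + `kbi_extrapolate()`): sliding parallelepipeds of
square base $L$ and full slab height $H$ across the volume, the count
fluctuations give an effective
$G_{\mathrm{eff}} = V_{sub}(\mathrm{var}(N) - \bar N)/\bar N^2$, and the
thermodynamic-limit value is the intercept of $G_{\mathrm{eff}}$ against
the surface-to-volume ratio $S/V = 2/H + 4/L$, fitted over the linear
regime $L \le 50$ nm.  Design choices, all recorded in the report:

* counts are pooled across window positions and frames before the
  variance is taken (the estimator is an ensemble statement; pooling is
  the lower-variance choice for few frames);
* the population variance is used -- overlapping windows are not
  independent, sample-size corrections are ill-defined, and the residual
  bias is absorbed by the $S/V$ extrapolation;
* the stride defaults to 3 nm; halving it smooths the scan without
  changing its trend (asserted as a property test);
* the extrapolation is ordinary least squares without weights, because
  overlapping windows correlate the per-$L$ errors; the reported error is
  a bootstrap over frames when replicates exist, which is honest where
  the OLS formula is overconfident.

## Structure factors

The primary route transforms the boundary-corrected RDF,
$S(q) = 1 + 4\pi\rho \int_0^R (g - 1)\, w(r)\, \mathrm{sinc}(qr)\, r^2
\mathrm{d}r$, with a Lorch window $w(r) = \mathrm{sinc}(\pi r / R)$
damping the hard cutoff at $R$ (30 nm by default) that would otherwise
ring at low $q$.  The window is configurable and recorded in the output.
Values below $q_{min} = 2\pi/R$ are reported but flagged unreliable;
$S(0)$ is obtained either from $1 + \rho G$ or by extrapolating $S$
against $q^2$ over the first reliable octave, never read off the curve.
The independent oracle is the Debye pair sum
(`structure_factor_direct()`), which uses nothing but raw pair
distances; with a finite cutoff the analytic ideal-gas term of the
truncated volume is subtracted so the two routes are directly
comparable.

With several concentrations, `b22_from_s0_slope()` fits
$S(0) = 1 - 2 B_{22} \rho$ with the intercept pinned at 1.  When the
per-point uncertainty of $S(0)$ is known it should be passed as `sigma`:
with only three concentrations a residual-based standard error has two
degrees of freedom and a nominal 2-SE interval covers only ~82%, whereas
the propagated known-sigma error restores the expected ~95% coverage
(verified by simulation in the suite).

## The synthetic-data world

`sample_poisson()` and `run_mc()` generate the ground-truth worlds every
stage is validated against.  The Monte Carlo engine does single-particle
Metropolis displacement sampling in fully periodic orthorhombic boxes
under the minimum-image convention, with the step auto-tuned toward
30-50% acceptance during equilibration and frozen afterwards (in very
dilute gases acceptance saturates near 1 regardless of step -- the tuner
simply widens the step, which is harmless).  Incremental energies are
checked against full recomputation every $10^3$ sweeps (drift bound
$10^{-9} k_B T$ asserted), trajectories are bit-exact per seed, and a
two-particle square-well system is checked against Boltzmann state
weights.

The reference validation fluid mimics a charge-stabilised globular
protein: hard core $\sigma = 7$ nm with Yukawa repulsion
$U(r) = \varepsilon (\sigma/r) e^{-\kappa(r-\sigma)}$,
$\varepsilon = 2\,k_B T$ at contact, $\kappa = 0.5$ nm⁻¹, at
$\rho\sigma^3 = 0.005$ in a periodic 2290 x 2290 x 100 nm³ slab
(N = 7644, i.e. a realistic particle count per unit slab area at a
realistic working density).  The lateral size is chosen so the sub-box
estimator has useful precision (its noise scales as
$\rho^{-1}\sqrt{2/n_{windows}}$) while the canonical-ensemble bias of a
closed box, $\approx -V_{sub}/N$, stays below 1% of the signal thanks to
the thin geometry.  What a green test on this world does **not**
establish: segmentation errors, missing-wedge anisotropy, polydispersity
and orientation-dependent interactions are all outside the generator;
only `inject_artifacts()`'s tilt and surface-enrichment nuisances are
emulated.

Two residuals in the validation are physical, not numerical: at
$\rho\sigma^3 = 0.005$ the measured $W$ still contains a genuine
$O(\rho)$ many-body term, so $B_{22}$ recovered from the PMF sits a few
percent below the infinite-dilution truth, and both KBI estimators
measure $G(\rho)$ rather than $G(0) = -2B_{22}$.  The acceptance checks
compare against the dilute-limit truth within 3 standard errors, which
accommodates this known offset at the stated density.

## Numerical choices and degenerate inputs

* $g$ bins with $g \le 10^{-3}$ are masked invalid for the logarithm,
  never clamped; masks propagate to every downstream fit.  In the Mayer
  quadratures, masked bins (below the first valid bin or interior holes)
  are treated as hard repulsion, $e^{-U} = 0$ -- they were masked
  precisely because $g$ collapsed there.
* Replicate RDFs are averaged with weights equal to each replicate's
  *expected* pair count at $g = 1$ (density x available shell volume).
  Weighting by observed counts -- the obvious inverse-variance proxy --
  self-weights the noise and inflates $g$ by $\approx 1/\text{count}$
  per bin (the ratio estimator bias $E[\sum c^2]/E[\sum c]^2$), a small
  per-bin offset that the $r^2$-weighted integrals amplify into large
  fractions of $B_{22}$.  The expected-count weight carries the same
  information but is independent of the noise.
* Empty bins give $g = 0$; a zero-particle crop, a singular slope fit,
  mismatched grids and cutoffs beyond the tabulated range all raise
  errors rather than returning silent defaults.
* Configs are JSON (no YAML parser is assumed); all numeric tables are
  written with 17 significant digits so they round-trip bit-exactly.

## A worked null example

```{r, eval = FALSE}
box <- box_geometry(c(800, 800, 100))
frames <- sample_poisson(box, n = 5000, n_frames = 20,
                         ensemble = "grand", seed = 7)
rdf <- compute_rdf_frames(frames)
est <- kbi_extrapolate(kbi_subbox(frames), L_max = 50, seed = 5)
structure_factor(rdf)
```

For an ideal gas every route must return its null: $g \equiv 1$ within
counting error, $W \equiv 0$, $G$ consistent with zero, $S(q) \equiv 1$.
The acceptance suite runs exactly this world at fixed seeds.

## Known limitations

* The method yields an angular-averaged potential; orientation-resolved
  correlations are out of scope by design.
* Sub-box errors rely on frame bootstrap; with a single frame only the
  (overconfident) OLS error is available.
* The tilt model is a single plane; curved or doubly-kinked slabs are
  not modelled.
* The MC generator simulates fully periodic boxes; slab walls are
  emulated by cropping, not by physical boundaries, so wall-induced
  layering is deliberately absent.
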