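# tomopip

Pair interaction potentials and Kirkwood-Buff integrals from particle
coordinates in thin slabs.

## What problem this solves, and for whom

Cryo-electron tomography can image a vitrified protein solution and, after
segmentation, deliver the 3D centroid coordinates of every macromolecule in
a slab of roughly 800 x 800 x 100 nm³.  Those coordinates are an
equilibrium sample of the solution's configurational statistics, so they
contain the protein-protein interaction thermodynamics directly — no
scattering model, no closure relation.  `tomopip` is for structural
biologists and soft-matter scientists who have such coordinate sets (or
want to validate methods on synthetic ones) and need the standard
liquid-state observables extracted from them correctly in a *finite, thin,
possibly tilted* volume.

## The statistics at the core

With g(r) the radial distribution function computed from the coordinates:

- potential of mean force (reversible work theorem):
  `W(r) = -kB T ln g(r)`; at low concentration `W -> U(r)`, the pair
  interaction potential;
- Kirkwood-Buff integral: `G = 4 pi INT (g(r) - 1) r^2 dr`, also
  estimated from sub-box count fluctuations
  `G_eff = V_sub (var N - mean N) / (mean N)^2` extrapolated linearly in
  the surface-to-volume ratio `S/V = 2/H + 4/L` to its intercept;
- second virial coefficient:
  `B22 = -2 pi INT (exp(-U/kBT) - 1) r^2 dr`, with the dilute-limit
  identity `G = -2 B22`;
- structure factor `S(q) = 1 + 4 pi rho INT (g-1) sinc(qr) r^2 dr` and
  the compressibility relation `S(0) = 1 + rho G ~ 1 - 2 B22 rho`.

The finite-slab correction — normalising every pair count by the exact
volume of the spherical shell clipped to the box — is what makes g(r)
unbiased out to separations comparable to the slab height.  A Metropolis
Monte Carlo generator of fluids with known pair potentials provides ground
truth for every stage.

## Worked example

Recover a known Yukawa (charge-stabilised soft sphere) potential from
simulated coordinates, end to end:

```r
library(tomopip)

pot <- potential_spec("yukawa", sigma = 7, epsilon = 2, kappa = 0.5)
box <- box_geometry(c(2290, 2290, 100), periodic = TRUE)  # thin periodic slab
mc  <- run_mc(pot, box, n_particles = 7644, n_sweeps_equil = 300,
              n_frames = 50, sample_every = 10, seed = 42)

rdf <- compute_rdf_frames(mc$frames)      # boundary-corrected g(r)
pmf <- pmf_from_rdf(rdf)                  # W(r) = -ln g in kB*T
b22_true <- b22_from_potential(potential_to_curve(pot), 30)
b22_rec  <- b22_from_potential(pmf, 30)

est <- kbi_extrapolate(kbi_subbox(mc$frames, L = seq(6, 50, 4)),
                       L_max = 50, seed = 7)
c(b22_true = b22_true, b22_recovered = b22_rec,
  G_subbox = est$G_inf, G_stderr = est$stderr)
```

```
     b22_true b22_recovered      G_subbox      G_stderr
    1869.0633     1762.6610    -3465.5415      131.4871
```

Reading: the true second virial coefficient of this potential is
1869 nm³; the value recovered purely from the simulated coordinates is
1763 nm³ (-5.7%, the residual being the genuine finite-concentration
many-body term at rho sigma³ = 0.005, not an estimator error), and the
sub-box Kirkwood-Buff integral -3466 ± 131 nm³ brackets the dilute-limit
identity G = -2 B22 = -3738 nm³ within three standard errors.  For an
ideal-gas null world every route returns its null (g = 1, W = 0, G = 0,
S(q) = 1) within counting error — that suite runs in `tests/`.

A scriptable front end mirrors the same pipeline on coordinate files:

```sh
Rscript inst/scripts/tomopip-cli.R simulate --config sim.json --out-dir sim/
Rscript inst/scripts/tomopip-cli.R analyze  --config cfg.json --out-dir out/
```

with JSON configs (box extents, temperature, molecular weight, per-stage
overrides) and TSV/JSON reports whose tables round-trip bit-exactly.

## Layout

- `R/`, `src/` — implementation (geometry quadrature, pair counting,
  sub-box scans and the MC engine are compiled).
- `tests/testthat/` — unit, property and acceptance suites; all fixtures
  are generated in code at fixed seeds.
- `vignettes/pair-potentials-from-slabs.Rmd` — the methods notes: model
  assumptions, parameter defaults and why, numerical choices, what the
  synthetic worlds do and do not establish.
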