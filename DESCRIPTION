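Package: tomopip
Title: Pair Interaction Potentials and Kirkwood-Buff Integrals from
    Particle Coordinates in Tomographic Slabs
Version: 0.1.0
Authors@R:
    person("tomopip", "developers", email = "tomopip@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanics pipeline for thin-slab particle
    coordinate data such as protein centroids extracted from cryo-electron
    tomograms. Computes boundary-corrected radial distribution functions in
    finite axis-aligned boxes, converts them to potentials of mean force
    and effective pair interaction potentials, evaluates isotropic
    structure factors, and estimates Kirkwood-Buff integrals by direct
    integration, by the sub-box (small-subvolume) density-fluctuation
    method with surface-to-volume extrapolation, and from potentials via
    Mayer-function quadrature, together with second virial coefficients.
    Includes preprocessing for slab tilt and surface-enrichment artefacts,
    a Metropolis Monte Carlo generator of synthetic fluids with known pair
    potentials for ground-truth validation, and a scriptable analysis
    front end producing TSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
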