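Package: vesselflow
Title: Bottom-Up Modeling of Flow Through 3D Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts node-link vessel graphs from 3D fluorescence image
    stacks of perfused microvascular networks (smoothing, adaptive
    thresholding, level-set refinement, homotopic thinning, distance-based
    radius estimation), rebuilds a labeled computational domain with vessel
    lumen, a uniform-thickness endothelial shell and a porous interstitium,
    and solves steady coupled free/porous (Stokes-Brinkman with optional
    Forchheimer and convective terms) flow on a staggered grid under
    pressure boundary conditions. Post-processing yields wall shear
    stresses, per-vessel velocities, transmural leakage, streamlines and a
    multivariate regression of wall shear stress on hemodynamic predictors.
    Companion procedures estimate endothelial diffusive permeability from
    dextran timelapse stacks, convert it to hydraulic permeability, and
    measure perfusion speeds by bead tracking. A synthetic-data module
    generates ground-truthed tubular networks, permeability timelapses and
    bead movies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
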