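---
title: "Bottom-up modeling of flow through 3D microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up modeling of flow through 3D microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselflow)
```

Self-assembled microvascular networks in microfluidic devices are imaged as
3D confocal stacks of a perfused fluorescent tracer. vesselflow turns such a
stack into a computational flow model in four stages: segmentation,
node-link graph extraction, bottom-up reconstruction of a labeled domain
(vessel lumen, endothelial monolayer, interstitial matrix), and a steady
coupled free/porous flow solution from which wall shear stress (WSS),
per-vessel velocities and transmural leakage are derived. This vignette
explains the model, the numerical choices behind each stage, and what the
synthetic benchmarks do and do not demonstrate.

## The physical model

Three compartments make up the domain:

* **Lumen** -- the open vessel interior. Steady incompressible flow obeys
  conservation of mass $\nabla \cdot \vec v = 0$ and the stationary
  Navier-Stokes momentum balance. At the device scale (velocities of order
  100 um/s, diameters 20-40 um) the Reynolds number is of order $10^{-3}$,
  so the convective term is negligible and the default solution mode drops
  it (see *Solver* below).
* **Endothelium** -- a porous shell of uniform thickness `t_endo` around
  every vessel. Flow follows the Brinkman equation: a viscous term
  $\frac{\mu}{\varepsilon_p}\nabla^2 \vec v$ plus the Darcy drag
  $-\frac{\mu}{\kappa}\vec v$, optionally with the Forchheimer correction
  $-\frac{\rho\,\varepsilon_p C_f}{\sqrt\kappa}\,|\vec v|\,\vec v$ where
  $C_f = 1.75/\sqrt{150\,\varepsilon_p^3}$.
* **Interstitium** -- the fibrin matrix between vessels, also a Brinkman
  medium with its own permeability.

Because the same momentum structure holds in all compartments (the lumen is
the limit $\varepsilon_p = 1$, zero drag), the package discretizes one
unified equation over the whole labeled domain; velocity and stress
continuity at the lumen/endothelium and endothelium/interstitium interfaces
are then implicit, which is standard Brinkman practice and avoids explicit
interface conditions entirely.

### Default parameters

| quantity | default | unit | meaning |
|---|---|---|---|
| `rho` | 1000 | kg/m^3 | culture-medium density |
| `mu` | 1.002e-3 | Pa s | medium viscosity |
| `mu_endo` | 3e-3 | Pa s | effective viscosity inside the monolayer (whole-blood-like) |
| `eps_p` | 0.265 | -- | porosity of both fibrin and endothelium |
| `kappa_inter` | 1.2e-7 | m^2 | fibrin Darcy permeability (configurable; see *Known limitations*) |
| `kappa_endo` | 5.66e-13 | m^2 | from the control diffusive permeability via the conversion below |
| `t_endo` | 5 | um | endothelial shell thickness (not reported by imaging; a monolayer-scale choice) |
| control pressures | 3.15 / 1.75 | Pa | vessel / interstitial inlet |
| treated (IL-1b) pressures | 0.35 / 0.075 | Pa | vessel / interstitial inlet |
| outlets | 0 | Pa | all outlet faces |

The endothelial hydraulic permeability is derived from the diffusive
permeability of the monolayer by
$\kappa = P_D\,\mu\,L/\varepsilon_p$ with $L = 1$ mm (the chamber depth
between parent channels). The printed form of this conversion is
typographically ambiguous (the fraction structure is not recoverable from
the typeset text, and its units are irregular: $P_D$ is a velocity, so
$P_D \mu L / \varepsilon_p$ has units Pa s m^2/s rather than m^2); the
reading above is implemented literally, recorded in the result's `units`
attribute, and treated as a configurable input rather than a derived truth.
The same caution applies to the fibrin value 1.2e-7 m^2, which is far more
permeable than typical fibrin-gel measurements; both numbers are plain
configuration defaults.

Similarly, the diffusive-permeability estimator implements
$P_D = \frac{r}{2}\,\frac{1}{I_{vessel}}\,\frac{dI_{gel}}{dt}$, the
standard cylindrical volume-to-surface form of the early-time mass balance;
the alternative $2r$ reading of the same ambiguous typeset formula is
available via `fit_diffusive_permeability(..., formula = "2r")`.

## Stage 1: segmentation

`read_stack()` reads multi-page TIFFs (voxel spacing from metadata, a JSON
sidecar, or an explicit override -- never a silent default),
`resample_isotropic()` makes voxels cubic while preserving physical extent
to within one voxel, and `gaussian_smooth()` smooths with a physical-unit
sigma. `binarize()` supports a global threshold (the route used for data of
known uniform contrast, including the synthetic benchmarks, where half the
vessel/background contrast is the unbiased edge locator) and local-mean
adaptive thresholding with a configurable window and offset (for real
acquisitions with uneven illumination; thresholds end up in the mask's
`provenance` attribute because real data need per-image tuning).
`refine_levelset()` optionally evolves the boundary under the
distance-regularized level-set formulation toward intensity edges; it is off
by default and mainly useful when the initial threshold was conservative.
`clean_mask()` fills enclosed cavities (6-connectivity) and removes
components below 500 voxels (26-connectivity, strict `<`), the
complementary-connectivity pair that keeps foreground and background
topology consistent.

## Stage 2: skeleton and graph

`skeletonize()` thins the mask to a one-voxel-wide curve skeleton by
sequential deletion of *simple points* (deletions that provably preserve
digital topology, checked by the two-condition neighborhood
characterization), organized in six directional subiterations and ordered
outside-in by the distance transform so the erosion front stays parallel to
the vessel surface. Two safeguards matter in practice and are worth knowing
about:

* a voxel already one voxel wide along the peel direction is protected in
  that direction's pass -- without this, a perfectly symmetric even-width
  structure is consumed end-to-end within a single subiteration. This
  failure mode is real: the widely used Lee-style thinning deletes a
  symmetric 2x2 bar and even a symmetric digital cylinder *entirely*;
* when the directional passes stall, a cleanup phase removes remaining
  simple non-endpoint voxels in distance order, dissolving diagonal knots
  that the directional protection would otherwise freeze.

Terminal side chains shorter than the vessel radius at their base are
pruned: they are thinning artifacts that live entirely inside the parent
vessel. `skeleton_to_graph()` then clusters junction voxels
(26-connectivity) into branch nodes at their centroids, traces degree-2
chains into links, and consolidates *sub-radius decorations*: tiny
self-loops, short parallel edges, short terminal stubs, and branch-branch
links shorter than 1.5 local radii (two junction clusters within one vessel
diameter are one anatomical bifurcation; contracted links are routed through
their own polyline so no geometry is lost). This consolidation is more
aggressive than keeping every raw voxel-graph edge, and it is what makes
node counts comparable with ground truth: a digital curve unavoidably
carries locally-non-simple duplicate voxels that would otherwise read as
spurious bifurcations. Anything at or above the local-radius scale is left
untouched.

`measure_links()` computes path length, endpoint distance and tortuosity
(their ratio; degenerate closed links are flagged with an infinite
sentinel). `subdivide_tortuous()` replaces links with tortuosity strictly
above 1.15 by five children cut at equal arc-length fractions -- total path
length is conserved exactly, children are re-measured but never re-split.

### Radius estimation

`estimate_radii()` reads the Euclidean distance transform of the mask at
each centerline point. Three corrections address known biases of this
simple estimator:

* **medial hill climb** (`recenter`): digital skeletons ride up to a few
  voxels off-axis; each reading is taken at the cross-sectional
  distance-transform maximum reachable within a few unit steps
  perpendicular to the local tangent;
* **blur compensation** (`blur_sigma`): the half-level surface of a
  Gaussian-blurred cylinder of radius $r$ sits about $\sigma^2/2r$ inside
  the true surface; when the acquisition blur is known this shrinkage is
  added back;
* **end exclusion**: the per-link aggregate skips points within one local
  radius of either link end, where the distance transform reads the end cap
  or the junction blob rather than this link's cross-section.

Even so, the minimum-distance convention clips by up to half a voxel
diagonal on perfectly lattice-aligned tubes whose axis falls between voxel
centers (every centerline voxel is then 0.7 voxels off-axis and no
neighboring voxel is better). `method = "perimeter"` provides the
alternative estimator that averages distances from each centerline point to
its associated mask-perimeter voxels; it does not clip on aligned tubes and
is the choice when sub-voxel accuracy on near-axis-aligned vessels matters.
Per-point radii are retained (3-point median smoothed) for tapered
reconstruction.

## Stage 3: bottom-up reconstruction

`build_label_field()` is the implicit-geometry equivalent of Boolean solid
modeling: the lumen is the union of capsules -- a cylinder per centerline
segment with spheres at segment ends, which removes the seams where
segments meet at angles -- the endothelium is the same union grown by
`t_endo` minus the lumen, and the rest of the block is interstitium.
Working on a voxel label field rather than CAD surfaces is deliberate:
self-intersecting network geometry, a known failure mode of direct surface
export, cannot break a voxel union, and the label field is exactly what the
solver consumes. Link ends within one radius of a tagged block face are
extended through the face, so vessels open into their boundary conditions
with no endothelial cap. For graphs that come from extraction, spheres
sized by the measured junction radius are added at branch nodes. Voxel
centers sit at $(i+0.5)\,h$; all coordinates are physical micrometers.
Setting a region's `kappa` to 0 declares it solid (no-slip), which is how
impermeable-wall benchmarks are built.

`extract_surface()` iso-surfaces a label region at 0.5 occupancy using
marching tetrahedra (the translation-invariant six-tetrahedron cube split,
which is watertight across cube faces by construction and needs no case
tables); the occupancy is lightly smoothed first, which removes the voxel
staircase area bias (a raw staircase overestimates a sphere's area by tens
of percent; the smoothed iso-surface is within a fraction of a percent).
`register_rigid()` is iterative-closest-point alignment with Kabsch/SVD
updates, and `cloud_to_mesh_deviation()` computes exact point-to-triangle
distances (grid-accelerated) with `fraction_within` summaries -- together
they reproduce the cloud-to-mesh validation protocol used to compare
reconstructed and segmented surfaces.

## Stage 4: the flow solver

`assemble_problem()` discretizes the unified equations on a MAC staggered
grid (pressures at cell centers, face-normal velocities on faces -- the
classical cure for pressure checkerboarding): one momentum row per unknown
face with the viscous Laplacian at effective viscosity
$\mu_{region}/\varepsilon_p$, Darcy drag averaged across region interfaces
as resistivities (arithmetic mean of $\mu/\kappa$, i.e. harmonic averaging
of permeability, the series-resistance rule for flow normal to an
interface), and the pressure gradient; one continuity row per fluid cell.
Tagged boundary faces carry their pressure in the ghost cell half a voxel
outside the domain (the standard cell-centered convention; the
boundary-condition placement error is first order in the voxel size, which
is why oracle comparisons use reasonably fine grids). Untagged block
boundaries are no-slip walls by default -- the chamber is a physical wall --
with `slip_walls = TRUE` turning them into symmetry planes for
representative-volume setups such as an effectively infinite porous slab.
Face tags can address a label per block face or a single link's lumen
(`link_<id>`), which distinguishes several vessels piercing the same face.

`solve_flow()` solves the resulting symmetric saddle-point system by an
augmented-Lagrangian Uzawa iteration: the velocity block, augmented with a
grad-div term weighted by the local momentum scale (robust across
permeability jumps of ten decades), is factorized once with a supernodal
sparse Cholesky; a handful of multiplier updates then drive the discrete
divergence to the $10^{-10}$ relative level, so total boundary flux
telescopes to numerical zero. The ordering is deterministic, so repeated
solves are bit-identical. The default `stokes_brinkman_linear` mode drops
the convective and Forchheimer terms, which are numerically negligible at
$Re \sim 10^{-3}$; `picard_full` honors the printed equations by lagging
$|\vec v|$ in the Forchheimer drag and the advecting velocity in the
convective term, and agrees with the linear mode to $10^{-12}$ at creeping
flow -- exactly as it should.

### Post-processing

`wall_shear_stress()` evaluates the full viscous traction
$\mu(\nabla\vec v + \nabla\vec v^T)\hat n$ at wall-adjacent lumen cells and
reports the magnitude of its tangential part. Two details keep the estimate
honest on voxelized walls: the surface normal comes from the smooth capsule
distance field, not from axis-aligned face normals (a staircase wall
otherwise biases the mean by a factor $\pi/4$); and the one-sided gradient
is the derivative, *evaluated at the true wall position from the distance
field*, of the quadratic through the discrete no-slip point and the two
nearest cell values -- exact for a parabolic profile, removing the
half-voxel cell-center bias. On the tube benchmark this lands within about
1% of the closed form where naive one-sided differences are 10-20% off.

`link_statistics()` assigns each lumen voxel to its generating link (the
capsule field records the owner) and reports per link: mean axial velocity
(cell mean of $\vec v\cdot\hat t$ along the local centerline tangent),
volumetric inflow/outflow through junction and boundary cross-sections, and
transmural leakage through the lumen-endothelium interface. Because each
cell is discretely divergence-free, inflow - outflow - leakage closes to
the solver tolerance by construction -- the reported `closure` column makes
this auditable. `streamlines()` traces RK4 paths through the trilinearly
interpolated staggered field. `wss_regression()` is ordinary least squares
of per-link WSS on axial velocity, wall outflow and radius, with
per-predictor F tests and variance inflation factors.

### The cytokine comparison and the finite-reservoir protocol

`two_channel_phantom()` builds the device-scale fixture: two parent
channels bridged by a square grid of network vessels in a quasi-planar
chamber. `solve_scenarios()` runs the control and IL-1b-treated parameter
sets (treated = tenfold endothelial diffusive permeability) on identical
geometry. Two comparisons are physically distinct and both are provided:

* at **fixed pressures**, higher wall permeability strictly increases
  transmural leakage and total outlet discharge -- the grid-model
  comparison at a common driving pressure. Note that mean lumen WSS *rises*
  in this regime, because the same head now drives more flow;
* at the **per-scenario pressures** (3.15/1.75 Pa control, 0.35/0.075 Pa
  treated), mean lumen WSS and distal intraluminal velocity strictly
  decrease -- the device comparison, where the treated device's lower
  residual pressure reflects its faster equilibration.

The link between the two regimes is the lumped finite-reservoir model
(`reservoir_pressure()`): the media wells are communicating columns whose
head difference decays as $\Delta p(t) = \Delta p_0\,
e^{-2G\rho g t/A}$ with $G$ the device conductance. The well area $A$ is
anchored so that the control device's residual head at the 5-second
observation time equals its stated inlet pressure; the treated device, with
roughly 2.5-fold higher conductance, has then decayed much further, and
beads advected through the correspondingly scaled fields are slower -- the
package reproduces this as a strict direction, not a magnitude claim, since
the lumped model ignores channel compliance and entrance losses.

## Permeability and bead velocimetry

`fit_diffusive_permeability()` fits the early-time line to the mean gel
intensity (first-frame background subtracted, vessel-intensity drift above
10% warned about) and applies the cylindrical mass balance. Recovery on
generated timelapses is exact to rounding without noise and within a
percent at 5% frame noise, because the gel mean averages thousands of
pixels -- the 15% acceptance margin is generous.

`detect_spots()` is difference-of-Gaussians band-pass detection at the bead
scale with local maxima and an iterated windowed centroid (the iteration
removes the window-asymmetry bias, taking center errors from half a pixel
to milli-pixels). `link_tracks()` performs greedy mutual-nearest
frame-to-frame assignment with a hard step gate, and
`filter_and_summarize()` applies the net-displacement filter before
reporting per-track mean speeds (path length over duration). The published
gates (150 um step, 125 um displacement, 3 frames, 10 um spots) are the
defaults; like the original acquisitions, whose frame interval differed
threefold between conditions, the step gate should be scaled to the
expected per-frame displacement -- a gate twenty times the displacement
makes identity swaps between crossing beads legal and inflates speeds.

## What the synthetic benchmarks show -- and what they do not

`random_vessel_graph()` grows bifurcating trees spanning inlet to outlet
face (radii 5-20 um, descending toward the leaves; collision-checked so
vessels touch only at junctions), `rasterize_graph()` renders them as
blurred (2 um) noisy (5% contrast) stacks with exact ground truth, and the
other generators produce permeability timelapses and bead movies with known
truth. Everything is deterministic given a seed, and seeds never leak into
the caller's RNG stream.

These fixtures exercise the imaged-device regime (vessel diameters tens of
micrometers, velocities of order 100 um/s), but they are deliberately
idealized: circular cross-sections (real self-assembled vessels are
eccentric), additive Gaussian noise (no PSF anisotropy or spectral
bleed-through), and tree topology without anastomotic loops. Passing the
round-trip benchmarks therefore demonstrates the internal consistency and
numerical accuracy of the pipeline, not segmentation performance on real
confocal data, where contrast varies and thresholds need per-image tuning.
Two quantitative caveats from the benchmarks themselves: per-link radius
recovery reaches $R^2 \approx 0.999$ with median errors of a fraction of a
voxel, but junction regions remain the hard part -- a capsule-union model
matches a blurred, thresholded junction blob to about 2 voxels only for
~92% of surface points (the looser published deviation band, one vessel
radius, is met everywhere), and the reconstruction benchmark that isolates
the geometry machinery (rebuilding from the ground-truth graph) passes the
2-voxel band at 100%.

## Problem sizes and numerical settings

The validation suite uses tube oracles at 8-32 cells per diameter (up to
about 10^5 unknowns, solved in seconds to a minute by the supernodal
factorization), one 400 x 260 x 260 um synthetic network at 1 um voxels
(~27M voxels) for the extraction and reconstruction benchmarks, and the
two-channel phantom at 5 um resolution for the scenario comparisons. Uzawa
iterations stop at a divergence of $10^{-10}$ relative to the peak
velocity; ICP stops at an RMS improvement below $10^{-5}$; all tie-breaks
(candidate ordering in thinning, nearest-neighbor ties) are fixed by scan
order, so every stage is deterministic given its configuration.

## Known limitations

* Vessels are perfectly circular and the endothelial thickness uniform;
  eccentric cross-sections and spatially varying monolayer thickness (e.g.
  from lectin stains) are not modeled.
* The fibrin permeability default (1.2e-7 m^2) and the
  diffusive-to-hydraulic conversion are carried as stated inputs despite
  their dimensional irregularities; users with measured values should
  override both.
* Steady state only: pulsatility, fluid-structure interaction and solute
  transport are out of scope; the reservoir decay is a lumped
  approximation, not a transient solve.
* 2D projection tracking is the default for bead movies; dense projected
  crossings are a genuine failure mode of any nearest-neighbor tracker, and
  the tracker here is deliberately the simple deterministic one.
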