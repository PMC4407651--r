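---
title: "Image-based homogenisation of soil hydraulic properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based homogenisation of soil hydraulic properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoflow)
```

## The problem

Roots restructure the soil around them — the rhizosphere — and with it the
soil's ability to hold and conduct water. X-ray computed tomography can
image a soil core at micrometre resolution and, after segmentation into
solid, water and air, the water-filled pore geometry is known explicitly.
`rhizoflow` turns such three-phase voxel volumes (imaged or synthetic) into
hydraulic quantities: the water release characteristic θ(h), the
unsaturated hydraulic conductivity K(h), pore-population metrics, and a
fitted van Genuchten parameterisation — the workflow used to compare bulk
against rhizosphere soil across a drying sequence.

## From Stokes flow to Darcy's law

At the pore scale, water in soil moves slowly enough that inertia is
negligible, so flow in the water domain Ω<sub>w</sub> obeys the Stokes
equations with no-slip on every solid–water and air–water interface (air is
treated as a trapped, rigid phase; if the air were mobile it would
lubricate the water and raise the conductivity, so this choice is
conservative). Homogenisation upscales this to Darcy's law: the average
velocity under a pressure gradient and gravity is

  u = −K (∇p₀ − ρ g ê_z),

and the permeability K is parameterised by a *cell problem* solved once per
representative elementary volume (REV): find a corrector velocity ν_k and
pressure correction π_k with

  ∇²ν_k − ∇π_k = ê_k,  ∇·ν_k = 0 in Ω_w,  ν_k = 0 on the interfaces,

from which K_jk is the cell average of ê_j·ν_k scaled by L_y²/μ, with L_y
the REV edge length and μ the viscosity. The hydraulic conductivity
reported in cm s⁻¹ is ρ g K. Throughout the package ρ = 10³ kg m⁻³,
μ = 10⁻³ kg m⁻¹ s⁻¹ and g = 9.8 m s⁻², which also fixes the head
conversion at 10.2041 cm of water per kPa (`water_constants()`).

Homogenisation assumes a periodic microstructure. A soil image is not
periodic, so the sample is mirror-reflected in x, y and z, which makes it
periodic by construction at the price of an artificial symmetry whose
influence shrinks as the REV grows. Rather than solving on the eightfold
reflected volume, the solver imposes the equivalent mirror-symmetry
boundary conditions on the original sample: zero pressure correction and
zero tangential velocity on the faces normal to the driving direction, and
zero normal velocity with zero normal gradients on the other faces. The
package implements both routes — `solve_cell_problem(boundary =
"symmetric")` on the sample and `boundary = "periodic"` on
`reflect_volume()` of it — and their agreement to solver tolerance is the
central correctness check of the boundary formulation (it is exercised in
the test suite on random geometries). One consequence of the reflection
worth knowing: the mirrored medium's permeability tensor is diagonal by
symmetry, so in symmetric mode the off-diagonal cell averages are exactly
zero and genuine cross-flow terms are only available from the periodic
mode.

### Discretisation and solver

The solver is voxel-native: a staggered (MAC) finite-difference scheme with
velocity unknowns on voxel faces and pressures at voxel centres, no-slip
walls imposed half a voxel inside solid (ghost reflection), which keeps the
scheme second-order on flat walls. No meshing step is involved. The linear
system is solved by conjugate gradients on the pressure Schur complement;
each application performs three scalar Poisson solves (Jacobi-preconditioned
CG), and the outer iteration is preconditioned by an approximate solve of
the pressure-network surrogate D diag(A)⁻¹ Dᵀ inside a flexible-CG
recurrence. The surrogate matters on partially drained geometries, where
water persists as thin films and narrow throats: those long-wavelength
pressure modes otherwise stall the iteration. The default relative
residual tolerance is 10⁻⁸ with an iteration cap; non-convergence is an
error carrying the residual history, never a silently inaccurate number.

Two analytic oracles calibrate the scaling before any soil geometry is
trusted: a plane Poiseuille slab (mean velocity φa²/12 in voxel units,
matched to better than 1% at 16 voxels across) and a square duct against
its Fourier-series solution (0.4% at 32 voxels across). The same oracle
fixes the interpretation of the cell average in the permeability formula:
the average runs over the whole cell (solid included), so a slab occupying
a fraction φ of the cell has K = φa²/(12μ).

Isolated water that does not span the sample is kept in the flow domain
with no-slip enclosure; it self-consistently contributes zero net flow and
is flagged (`flow_domain()$n_isolated`) rather than special-cased.
Per-direction diagonal entries are provably non-negative in this
discretisation; ensemble means minus standard deviations can of course
still be negative at small REV sizes, which is a statement about sample
variability, not about any individual solve.

## REV subsampling

`extract_subsamples()` draws cubic subvolumes at seeded random origins
(3.8 mm side, volume 54.9 mm³, in the reference workflow) and persists the
origins so the same coordinates are reused at every matric potential of a
sample. `dyadic_series()` builds nested concentric cubes with nominal
volumes V₀/2^j for j = 0…8 (54.9 mm³ down to 0.2 mm³). Sides are rounded
to whole voxels and the achieved sides recorded; sub-cubes are centred on
their parent to avoid boundary bias, and the six random cubes may overlap
(origins are logged in the manifest). `convergence_stats()` then reports
the mean and standard deviation of conductivity per level — the REV
convergence diagnostic — with a configurable relative-change flag.

## Synthetic three-phase media

No public imaging data accompany the reference workflow, so the package
generates its own study materials, and these generators are first-class,
tested code. Two architectures are provided.

**Sand-like** (`generate_sand_like()`): random sequential addition of
spherical grains until the target porosity is reached, with the pore space
initially water-filled. A strict hard-sphere RSA jams near 38% solid —
far short of the ~55% solid of a repacked sand — so grain centres are
instead kept at a minimum separation of 0.75 of the radius sum, letting
grains interpenetrate slightly like cemented or angular grains. When
placements keep getting rejected, the sampled radius range shrinks
(polydisperse filling), and a placement that would overshoot the porosity
tolerance is rejected, so achieved porosity lands within ±0.03 of target
(the contract is checked, and failure names the achieved value). Defaults:
64³ voxels at 6 μm, porosity 0.45, grain radii 4–7 voxels. At 6 μm
resolution the pore radii (roughly 6–30 μm) drain across the −5 to −40 kPa
range of the default schedule, which is the behaviour wanted of a sand.

**Clay-like** (`generate_clay_like()`): a dense packing of small
aggregates leaves a network of thin inter-aggregate micropores; a small
number of full-height planar cracks (desiccation-style, normal to x or y
so they meet the air-entry face) are carved as macropores. Three further
steps keep the two pore populations distinct, which is the defining
structural feature being emulated — a large micropore population plus a
few large cracks: inter-aggregate voids wider than ~2.5 voxels are plugged
(an aggregate filling a vug), crack walls get a one-voxel compacted skin
(the cutan analogue) so micropores never open directly into a crack, and
the packing target is corrected over a few attempts so the plugging does
not pull porosity off target. Defaults: 64³ voxels at 0.5 μm, porosity
0.50, aggregate radii 3.5–5.5 voxels, two cracks of 9–13 voxel aperture.
At 0.5 μm the micropores (≤ ~1.25 μm radius) stay below the Young–Laplace
radius of −75 kPa (1.92 μm) and remain water-filled through the whole
schedule, while the cracks (2–3 μm) drain late — so clay-like media retain
strictly more water than matched-porosity sand-like media at −75 kPa, the
qualitative texture contrast of the reference comparison.
`pore_radius_histogram()` verifies bimodality (two local maxima separated
by an empty bin); `count_planar_voids()` counts the cracks.

**Drainage** (`apply_drainage()`): quasi-static morphological invasion on
the drying branch. For a matric potential P the Young–Laplace critical
radius is r_c = 2σ cosγ/|P| (σ = 0.072 N m⁻¹, γ = 0 by default); air
occupies every pore voxel whose local pore radius is at least r_c *and*
that is face-connected (6-connectivity — a physical air pathway needs
shared faces) to the entry face through voxels meeting the same criterion.
Air never retreats (drying branch only). The local pore radius is the
maximal-inscribed-sphere local thickness, computed from an exact Euclidean
distance transform followed by sphere propagation; radii are
centre-to-centre distances, a convention chosen so that the union of
maximal spheres covers the whole pore space (a morphological opening) — a
channel of radius 5 voxels then drains completely at r_c = 3 and not at
all at r_c = 7, the behaviour the capillary-bundle picture requires. Air
enters from the top face by default (drainage to a suction applied below),
configurable. If r_c falls below one voxel the step degenerates to full
drainage of connected pores and a warning says so.

What the generators deliberately do not emulate: film and corner flow,
wetting (imbibition), shrink–swell deformation, gravity within the sample,
and any quantitative rhizosphere structural model — "rhizosphere-like"
variants are exposed only as porosity and crack-parameter presets, not as
asserted biology. Passing tests on these media therefore show the
*pipeline* is correct under controlled geometry, not that any particular
field soil behaves this way.

## Segmentation and noise rules

`segment_threshold()` reproduces reference-calibrated thresholding: cut
points lie halfway between the air and water reference greys and halfway
between the water and soil reference greys (water attenuates less than
mineral soil, and that ordering is enforced). The air reference defaults
to the lowest histogram mode since only water and soil references are
calibrated against physical standards. How partial-volume voxels are
arbitrated is not prescribed by the source workflow; midpoint cuts are
this package's choice. `filter_noise()` applies the resolution rule: in
3D, any connected non-soil object under 2 voxels in some axis or under
8×10⁻⁶ mm³ is relabelled to the majority phase of its face neighbours
(ties resolved toward water — never invent solid); in 2D the per-slice
0.02 mm equivalent-diameter analogue. Object counting uses 26-connectivity
(permissive, as is usual for CT morphology), while flow connectivity is
always 6 (physical). The filter is idempotent and leaves the solid mask
untouched except where it absorbs sub-threshold specks.

## Pore metrics

`compute_metrics()` reports counts, volumes and surface areas of
air-filled and water-filled pores (AFPs/WFPs, each a 26-connected region),
the water-filled porosity, and the fraction of water in the largest WFP.
Surface areas come from a marching-tetrahedra triangulation of the
Gaussian-smoothed (σ = 0.8 voxel) phase mask: voxel-face counting
overestimates smooth surfaces by up to ~50%, whereas the triangulated
estimate is within 3% of 4πr² for a digitised sphere of radius 20 voxels.
Structures thinner than two voxels are below this method's (and the noise
rule's) resolution. The air–water interface is counted in both phases'
totals, with solid-contact and fluid-contact areas also logged separately
so either convention can be recovered. The metric can represent the
thin-film regime in which WFP surface area rises while WFP volume falls;
the test suite asserts this capability on a constructed fixture rather
than claiming it always occurs.

## Water release and van Genuchten fitting

`vg_theta()` and `vg_relative_k()` implement the van Genuchten retention
and relative-conductivity closed forms with m = 1 − 1/n exactly and
θ_r = 0 (taken as negligible). `fit_vg()` estimates (θ_s, α, n) by
Levenberg–Marquardt least squares, multistarted from a log/linear (α, n)
grid so the fit does not depend on a lucky initial guess. When
conductivity data are supplied the fit is joint: water-content residuals
and log₁₀ relative-conductivity residuals, each normalised and weighted so
the two datasets contribute equally in aggregate (conductivity spans
decades, hence the log scale; whether the reference workflow fitted
jointly or sequentially is unstated, and joint fitting with a single
(α, n, θ_s) per soil is this package's choice). K_sat is taken from the
computed conductivity at saturation, not fitted as a shape parameter.
Round-trip recovery of generator parameters is exact to optimiser
tolerance on noiseless data and the median error in n stays under 5% with
θ-noise of 0.01 across replicates.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the generators at 16³–64³
voxels, the analytic oracles at up to 40×40×8 (duct) and 64³ (slab
refinement), reflection equivalence at 32³ vs 64³, and the drainage +
conductivity study at 64³ per texture — sizes chosen so the whole suite
completes in minutes on one core while every claim above is still
exercised at a resolution where the oracles hold. Every stochastic step
takes an explicit seed (`rng_seed`, `seed` arguments); no wall-clock
seeding exists anywhere, and rerunning any configured pipeline reproduces
byte-identical numbers. The `run_pipeline()` orchestration reuses
subsample origins across potentials, aggregates conductivity by dyadic
level, and serialises its configuration next to its outputs.

## Known limitations

- The air phase is rigid: near saturation, mobile connected air would
  raise conductivity; the fixed-interface assumption restricts validity to
  modest pressure gradients on the drying branch.
- Staircase voxel walls limit the accuracy of conductivity on geometries
  with pores only a few voxels wide; the refinement study quantifies the
  first-order trend.
- Water retained below image resolution is invisible: image-derived θ(h)
  underestimates retention in fine-textured media at strongly negative
  potentials, which is also why the synthetic clay uses a finer voxel
  pitch than the synthetic sand.
- Morphological drainage is quasi-static invasion percolation; dynamic
  effects, films and snap-off are not modelled.
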