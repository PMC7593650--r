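---
title: "Methods: subject-specific contact modelling of the mouse knee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subject-specific contact modelling of the mouse knee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which parameters
matter, and what the synthetic test bed does and does not establish about
real specimens.

## The problem

Cartilage contact pressure in the loaded mouse knee cannot be measured
directly; it is estimated by finite element (FE) models built from
micro-CT. The pipeline modelled here reflects the standard workflow: the
intact joint is scanned in its rest position (mineralised tissue bright,
cartilage invisible); the dissected femur and tibia are stained and
scanned separately so their cartilage shells become visible; each bone is
rigidly registered back into the rest pose; the soft meniscus, invisible
in both scans, is filled in between its calcified remnants and the
cartilage; and the assembled geometry is meshed and loaded in compression.
The scientific question the four model variants address is how much
geometric realism the pressure readout needs: homogeneous cartilage of one
thickness, homogeneous with a per-condyle thickness, subject-specific
layers, or subject-specific layers plus meniscus.

## The phantom and what it emulates

`phantom_spec()` defines a parametric stylisation of a murine knee:

* femur: two spherical condyles (lateral radius 0.50 mm, medial 0.42 mm,
  centres 1.05 mm apart) joined by a bridging bar and a short shaft;
* tibia: a plateau slab with *shallow convex crowns* under the condyles;
* cartilage: spherical femoral shells and flat-topped tibial tables,
  0.10 mm thick laterally and 1.5x thicker medially; the lateral layers
  touch at rest while the medial compartment keeps a 4 um clearance;
* calcified menisci: 240 degree torus arcs around each condyle, disjoint
  from both bones in the rest scan;
* two acquisitions: the rest scan (bone + calcified menisci at bone
  intensity) and stained scans of each separated bone (cartilage at
  intermediate intensity), displaced by known rigid transforms, with
  additive Gaussian noise under a fixed seed.

Every choice with a downstream consequence is deliberate:

* **Convex crowns rather than concave dishes.** Offsetting a concave
  plateau produces generic layers that are *more* conforming than
  hand-built anatomical ones, which would invert the expected pressure
  ordering across variants. The murine tibial plateau is in fact flat to
  convex, and a slightly convex bone surface makes the bone-offset generic
  layers less conforming than the subject-specific ones — the
  configuration of interest.
* **Medial thickness ratio and clearance.** With the medial cartilage 1.5x
  thicker and a 4 um rest clearance, the bone-to-bone gap is ~0.10 mm
  wider medially than laterally. A one-thickness generic layer (t = half
  the lateral gap) therefore never closes the medial gap within the 30 um
  protocol — the "no medial contact" behaviour — while the
  subject-specific model regains medial contact almost immediately.
* **Grid de-alignment.** The voxel lattice is offset from the analytic
  solids by 0.37 voxel so that spheres never align degenerately with voxel
  centres; a real scanner lattice never aligns with anatomy either.
* **Voxel spacing.** The default is 25 um (acquisition-resolution scans at
  4.35 um are supported but impractical for routine testing); landmarks
  are exact (noise-free correspondences), so registration errors isolate
  algorithmic behaviour rather than landmark placement skill.

The phantom emulates contrast, noise, separation transforms and tissue
topology. It does not emulate reconstruction artefacts (ring artefacts,
beam hardening), trabecular microarchitecture, intensity calibration, or
anatomically irregular cartilage thickness maps. Consequently, passing
tests demonstrate that the pipeline's operators are correct and the solver
is convergent and force-consistent — not that segmentation choices are
robust to real-scan artefacts.

## Geometry reconstruction

The rest scan is smoothed (Gaussian, sigma = 1 voxel) and thresholded at a
single level (suggested by Otsu's criterion, with the plateau midpoint
taken so well-separated modes give a central level). Connected components
are split by position: the superior-most component is the femur, the
inferior-most the tibia, the rest are calcified menisci. Each stained scan
is registered into the rest frame by the two-step landmark procedure (3
coarse markers, then 15 landmarks; closed-form Kabsch fit each time) and
resampled trilinearly. Cartilage is thresholded from the resampled stained
volume (level from the sub-bone histogram), the original bone masks are
Boolean-subtracted, the mask is smoothed with a 2-voxel radius, and
components not attached to their own bone are dropped.

On the phantom this recovers bone masks with Dice above 0.95 and the
separation transforms to near machine precision; cartilage Dice is lower
(0.80-0.95 depending on voxel size) because threshold-plus-subtraction on
a blurred resampled volume is an imperfect stand-in for the slice-by-slice
manual contouring used on real specimens — a deliberate substitution,
since manual contouring is not implementable, and a controlled one, since
the phantom quantifies its cost.

The rms residual of the rigid fit is reported per coordinate,
`sqrt(SS/(3n))`; with isotropic destination noise sigma its expectation is
`sigma * sqrt(1 - 2/n)`, so a correctly working fit sits near sigma in the
Monte-Carlo test.

## Generic cartilage and the meniscus wrap

Generic layers are constant-distance offset shells of each bone's surface,
confined to the articular corridor (voxels whose summed distance to the
two bones is within 0.25 mm of the compartment's minimal gap). The layer
thickness is `t = g/2` per bone so that the two layers spanning the
minimal gap `g` just touch; in two-thickness mode `t` is set per
compartment. The corridor width matters: too narrow and the layer itself
caps the achievable contact area.

The soft meniscus is a morphological closing (ball radius = half the
maximal bridged gap, default 200 um) of the union of calcified menisci and
cartilage masks, restricted to the neighbourhood of the calcified arcs,
minus every input mask. Two curation steps follow, both with a mechanical
rationale: a morphological opening removes voxel-thin tongues of fill
squeezed between the articulating surfaces (a frictionless thin sheet
pinched on a slope has no stable equilibrium, and the real meniscal wedge
is thick), and a two-voxel in-plane clearance is carved around the femoral
cartilage side walls so the meniscus meets the femur only across the
articulating gap. These replace the manual editing that the commercial
wrap output receives in practice.

## Meshing

Voxels (optionally coarsened by an integer factor; blocks take the
majority label, ties to the softer tissue, emptiness wins only with an
absolute majority) are subdivided into six tetrahedra by the Kuhn
decomposition, which conforms across neighbouring voxels by construction.
One global coarsening factor keeps all tissue interfaces conforming. At
factor 1 the per-tissue mesh volume equals the mask volume exactly.

Bodies: tissues of one bone share nodes (welded bone-cartilage interface);
femur, tibia and meniscus are meshed with duplicated interface nodes so
they remain distinct contacting bodies. The meniscus is bonded back to the
tibial side by multipoint constraints (tie), which mirrors the modelling
intent: perfect bonding below, frictionless contact above. Surface
staircasing is accepted; the mask smoothing upstream and the smooth-normal
contact treatment below mitigate it.

## The solver

Constant-strain tetrahedra with the closed-form isotropic element matrix;
units mm / N / MPa. Constraints (Dirichlet, kinematic translation coupling
to a reference point, ties) are eliminated through a sparse transformation
`u = S q + u0`, and the reduced system is factorised with a supernodal
Cholesky. "Dynamic coupling" of the femoral top surface is implemented as
kinematic *translation* coupling (rotations unconstrained is the main open
interpretation; with a displacement-driven axial protocol and a flat
coupled surface the difference is immaterial at these loads).

Contact is node-to-surface, finite sliding (slave nodes re-projected onto
the deformed master surface every iteration), frictionless, penalty-based.
Numerical choices that proved load-bearing on staircased voxel surfaces:

* **Smooth master normals.** Area-weighted nodal normals interpolated
  barycentrically at the projection point; facet-wise normals flip by up
  to 45 degrees across staircase edges and destabilise the iteration.
* **Regularised pressure-overclosure.** `p = k g^2 / (2 eps)` for
  penetration below `eps` = 1 um, linear above. The contact stiffness then
  grows continuously from zero, which removes marginal-node chattering at
  terrace edges. Default penalty `k = 50 E/h` with `E` the compliant-side
  modulus and `h` the slave-surface edge; peak pressures move by well
  under 5% when `k` is multiplied by 10.
* **Acceleration and damping.** Aitken extrapolation of the sliding fixed
  point while the active set is stable; geometrically decaying
  under-relaxation while it changes repeatedly.
* **Convergence and increments.** An increment converges when the
  penetration field is stationary to 1e-5 mm (0.04% of a desk-scale
  element). Non-converging increments are bisected up to four levels; if a
  deep-loading increment still cycles, the most stationary iterate within
  1e-3 mm is accepted, one final linear solve makes the stored state
  internally consistent, and the step is flagged `relaxed`. Flagged steps
  occur only well beyond the matched-force step in the shipped
  configurations; because of the final consistent solve, summed contact
  forces equal the reference reaction to machine precision at *every*
  stored step, flagged or not.
* **Geometric nonlinearity** is not included: displacements (<= 117 um)
  are small for the bones but not strictly small for cartilage, so
  cartilage strains around 15% are treated linearly. This is a disclosed
  approximation shared with the displacement-scale of the emulated
  workflow.

The sphere-on-rigid-plane benchmark (structured cap mesh, exact spherical
bottom surface) validates the whole stack against the Hertz closed form at
the measured reaction force; at the default refinement the peak pressure
is within ~4% and the contact radius within ~3%.

## Protocol and matched-force comparison

The femur is translated superiorly by 87 um rounded to whole voxels (at
4.35 um spacing this is exactly 20 voxels; at the desk scale 25 um x
coarsening 2 it becomes 100 um), the same displacement is applied to the
reference point to initialise contact, and 30 um of loading follows. The
canonical protocol applies the loading in four steps; the desk-scale study
uses ten increments of 3 um so that the coarse phantom's stiffer
force-displacement curve is sampled finely enough around the 0.3 N target
(chosen a priori from a column-model estimate of the phantom's contact
stiffness). Variants are compared at the loading step whose reaction is
closest to 0.3 N.

Per condyle (split by the sagittal plane through the centroid of the
femoral articular surface; the phantom's intercondylar notch leaves a
node-free band, so any plane in the notch gives the same labels as the
ground truth), the summary reports the mean pressure over contacting
nodes, the contact area as summed tributary areas, 0.2 MPa frequency
histograms, and the peak pressure excluding isolated points — concretely,
contacting nodes with fewer than 3 contacting neighbours within 3x the
median inter-node spacing, this package's definition of the otherwise
unspecified exclusion of isolated local artefacts. Percent differences are
taken against the one-thickness model laterally and the two-thickness
model medially (the simplest variant with medial contact).

## Problem sizes

Defaults were chosen so the whole chain runs on one CPU at desk scale: the
phantom grid is ~95 x 45 x 58 voxels at 25 um; meshes are built at a
coarsening factor of 2 (50 um elements, 50-60k tetrahedra, ~35k degrees of
freedom); the four-variant study solves in roughly 10 minutes and the
Hertz benchmark in seconds. Acquisition-scale settings (4.35 um voxels,
100 um bone / 5 um soft-tissue target edges) are reachable through the
same configuration surface but produce multi-million-element meshes that
belong on a cluster, not in a test suite.

## Known limitations

* Linear elastic, small-strain tissue models: no poroelasticity,
  viscoelasticity, fibre reinforcement, friction or large-deformation
  kinematics; no ligaments and no load control. Displacement control plus
  the kinematic coupling stands in for the stabilising soft tissues.
* Node-to-surface contact approximates a surface-to-surface formulation;
  pressures are nodal, not mortar-consistent.
* Voxel meshes carry staircase surfaces; pressure fields inherit terrace
  granularity at coarse settings, which is why the study's claims are
  orderings and areas, not absolute pressures.
* The phantom's cartilage is geometrically clean; the pipeline's
  threshold-based cartilage segmentation substitutes for manual contouring
  and is only as good as the phantom's controlled contrast.
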