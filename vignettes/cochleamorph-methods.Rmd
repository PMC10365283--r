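---
title: "Quantitative OSL morphometry: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative OSL morphometry: models, phantoms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cochleamorph` quantifies the morphology of the osseous spiral lamina (OSL)
— the thin bony shelf that spirals from the modiolus to the lateral cochlear
wall — from micro-CT volumes. It measures three things: the OSL width
profile from base to apex, the mean and SD of that width inside tonotopic
octave bands, and the volumetric porosity of the OSL's two bony plates
(tympanic and vestibular). Because cadaveric micro-CT scans are rarely
shareable, every stage is validated against a synthetic cochlea phantom
whose ground truth is exact by construction.

## The measurement model

**Reference frame.** All spiral coordinates live in a cylindrical frame
defined by three landmark points: the cochlear centre, the helicotrema
(which fixes the modiolar axis direction), and a point at the basal end of
the spiral (which fixes the angular origin). `build_reference_frame()`
orthonormalises these into `axis_dir` and `zero_dir`.

**Spiral unwrapping.** A segmented OSL mask covers 2–3 turns, so the raw
cylindrical azimuth is ambiguous modulo 360°. The tracer partitions mask
voxels into angular wedges (default 4°), clusters each wedge by radius —
the turns of a spiral are radially separated — and stitches clusters across
adjacent wedges by radial continuity into a single chain running from the
innermost (basal) end outward. Each cluster, and each voxel, receives a
continuous unwrapped angle. Closed rings (an annulus test solid, or a
cochlea imaged over exactly one turn) are detected when the chain returns
to its start. The tracer assumes turns do not overlap radially within a
wedge; masks should be noise-filtered (`remove_small_components()`) first.

**Width.** Within each wedge the inner (modiolar) wall is estimated as the
centroid of the one-voxel-thick innermost edge of the section's voxels, and
the outer (lateral) wall as the outermost edge, both after removing the
in-wedge radial drift of the spiral by linear detrending against azimuth
(at the apex of the default phantom this drift is ~1.3 voxels per wedge and
would otherwise bias the width systematically upward). Both wall radii
receive a half-voxel edge correction, since voxel centres sit half a voxel
inside the physical surface. Width is the Euclidean distance between the
paired wall points of the radial section — the standard mid-modiolar radial
measurement. An alternative reading, distance projected onto the plane
perpendicular to the axis, differs only through the plates' axial offset
within a section and is not separately implemented.

**Contour smoothing.** The per-wedge wall estimates carry grid-alignment
noise of up to ±0.8 voxel. The scalar series (inner/outer radius and axial
position versus unwrapped angle) are smoothed with robust local-quadratic
regression (`loess`, degree 2, symmetric family), taking the widest of
spans {0.35, 0.2, 0.12, 0.08} whose fit stays within 1.5 voxels of the raw
series. Local polynomial fits are used instead of smoothing splines
deliberately: spline boundary conditions let the fit sag at the free ends
of an open spiral, and at the apex — where the OSL is ~0.3 mm wide — a
sag of half a voxel is already a ~10% width error. Closed rings are
wrap-padded before fitting so they have no free endpoints.

**Tonotopy.** Positions along the spiral midline are normalised by arc
length and mapped to characteristic frequency with the Greenwood-form
function `f(x) = A(10^(a x) − k)`. The defaults are Greenwood's human
organ-of-Corti constants (A = 165.4 Hz, a = 2.1, k = 0.88, x measured from
the apex). Published spiral-ganglion maps use the same functional family
with different constants and sometimes measure x from the base; both are
supported (`freq_map_params(..., x_convention = "from_base")`), and the
constants are configuration, not claims. Octave bands double from `f_min`
upward and are half-open in position with boundaries belonging to the
higher-frequency band. Note that full-range partitions end in a small
remainder band (the range is not an integer number of octaves); this band
can be narrower than a voxel, so band statistics there rest on very few
samples.

**Porosity.** For each plate and spiral segment the porosity is
`p = (Vf − Vo)/Vf · 100%`, with `Vo` the segmented (porous) volume and `Vf`
its pore-filled counterpart. The percentage is computed as
`(Vf − Vo)·100/Vf`, which is exact for integer voxel counts. Two filling
backends exist:

* **Voxel closing** (primary): morphological closing with an exact
  Euclidean ball, computed through a squared distance transform, so
  dilation/erosion form an adjunction and closing is idempotent and
  extensive. A closing ball larger than the largest pore radius fills every
  enclosed cavity exactly while leaving flat outer surfaces untouched. The
  closing radius must also stay below half the clearance between adjacent
  spiral turns, or the closing bridges them; the default (3 voxels) is safe
  for the default phantom geometry.
* **Mesh shrink-wrap** (secondary): emulates a graphics-package shrink-wrap
  modifier. The part's voxelization is dilated and hole-filled to build a
  cavity-free enclosure; its surface mesh is decimated to the face budget
  by vertex clustering and then projected onto the part's outer surface by
  iterative steps along the gradient of the Euclidean distance field, with
  Laplacian relaxation between steps, stopping half a voxel outside voxel
  centres (i.e. on the physical surface). No published algorithmic contract
  exists for the original interactive operation, so only enclosure and
  approximation properties are claimed; on the phantom the two backends
  agree within 5 percentage points, the voxel backend being the accurate
  one (it recovers slab truth essentially exactly).

**Plate splitting.** Within each angular section the axial (modiolar-axis)
coordinates of OSL voxels are bimodal — two plates separated by the
nerve-fibre gap. The split surface is the largest axial gap per section,
interpolated across sections where pores obscure it; voxels above it (along
`axis_dir`) are vestibular. If fewer than half the sections show a gap the
mask is a single sheet and a topology error is raised.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a logarithmic-spiral ribbon
`r(θ) = r0·e^(gθ)` with axial pitch, split into two plates around a
soft-tissue gap, with ribbon width falling linearly in normalised arc
length from 1.34 mm (base) to 0.28 mm (apex) — the span reported for the
human OSL. Intensities are background 20, soft tissue 90, bone 180,
inclusion 255, plus Gaussian noise (σ = 10 by default), rounded to
integers; at the default 6σ separation between background and the bone
threshold, misclassification is negligible, which is what lets the
segmentation recipe be tested for ≥99% agreement.

The published literature does not parameterise any specimen's spiral, so
the geometric defaults (r0 = 2 mm, g = 0.105 rad⁻¹, 2.5 turns, pitch
0.3 mm/turn, 60 µm voxels) are conventional, chosen so that (a) adjacent
turns clear each other by more than twice the default closing radius and
(b) the apical ribbon is still ~5 voxels wide. As the spec formula is
`r0·e^(gθ)` with positive growth and the sweep ordered base→apex, the
synthetic spiral widens toward the end labelled apex — a mirror-image of
anatomy that no measurement depends on; base/apex semantics attach to the
width profile and tonotopic axis, not to the radius ordering.

**Pores with exact truth.** Pore spheres must be mutually disjoint and
strictly interior (closed 1-voxel walls), so that true porosity is an
exact voxel count and closing can recover it. Random sequential placement
saturates near 38% volume fraction, far below the 50–65% range reported
for otosclerotic plates. Pore centres therefore sit on dense *integer*
packing lattices, hardcoded per radius r = 1..5 (found by search and
validated exactly: no nonzero lattice vector shorter than 2r exists, hence
discrete balls on distinct sites share no voxel; with integer centres
every ball has the full enumerated count, e.g. 123 voxels at r = 3). The
lattice is randomly shifted and randomly thinned to the target fraction,
so achieved truth equals the target to within one ball quantum. Radii mix
uniformly across the requested range when the target allows; otherwise the
placer falls back to denser single-radius packings, and raises an error
naming the achieved fraction when the target is geometrically unreachable.

Feasibility is bounded by boundary depletion: pores of radius r are
excluded from a shell of roughly r + 2 voxels at every surface. In a thin
curved ribbon this caps achievable porosity well below the bulk packing
limit — hence the phantom's default pore fraction of 30% (radii 1–2
voxels, 1.2 mm plates), while the 50% and 65% regimes are exercised on
thick slab fixtures (`generate_porous_slab()`; 128³ voxels at r = 2 reach
~53% bulk, 96³ at r = 1 reach ~72%). High-porosity arrangements are
necessarily crystalline; the phantom trades realism of pore arrangement
for exactness of truth throughout.

The phantom does **not** emulate scala anatomy, the modiolus, trabecular
(non-spherical, connected) porosity, beam hardening, ring artifacts, or
partial-volume blur. Passing tests therefore demonstrate the correctness
of the measurement chain on geometrically ideal data at known noise, not
robustness to scanner physics.

## Numerical choices and degeneracies

* Distance transforms are exact squared-Euclidean (per-axis lower-envelope
  passes in C++); ball radii may be non-integer (e.g. 1.5 × max pore
  radius).
* Erosion treats the outside of the array as foreground, so closing
  remains extensive for masks touching the array hull; the pore placer
  instead pads with background before eroding, so pores can never open
  onto a slab's hull.
* Component labeling is BFS over 6/18/26-neighbourhoods; the test suite
  cross-checks it against an independent minimum-label-propagation oracle.
* Mask surface meshes emit one quad per exposed voxel face; their
  divergence-theorem volume equals the voxel count exactly, which anchors
  the mesh backend to the voxel backend.
* Watertightness is checked as balanced directed edge multisets, which
  admits the benign non-manifold junctions of vertex-clustered decimation
  while rejecting open boundaries.
* Band assignment at a shared boundary goes to the higher-frequency band;
  the extreme high-frequency band keeps its outer endpoint.
* Degenerate width samples (inner = outer) are kept but flagged through
  the `degenerate` attribute of the profile.
* All randomness (pore placement, lattice shifts, noise) flows through a
  single seed; equal spec + seed reproduces volumes bitwise, and the
  pipeline's `summary.json` is byte-identical across runs.

## Problem sizes

Module tests run on a 100 µm / 2-turn phantom (~2 M voxels, seconds); the
study-conditions checks use the default 60 µm / 2.5-turn phantom (~9 M
voxels, ~30 s to generate) and slab fixtures up to 128³. These sizes were
chosen as the smallest at which the apical ribbon remains ~5 voxels wide
and the 50–65% porosity regime is reachable.

## Known limitations

* The spiral tracer requires radially separated turns and a single
  connected sweep starting at the minimum-radius end; a chain break (e.g.
  a fully interrupted OSL) truncates the angular range rather than
  bridging the gap.
* The apical terminal wedge is partial, so the last one or two width
  samples average over a truncated section.
* The mesh-wrap backend underestimates filled volume on strongly curved
  thin segments (it rounds cut faces and corners); treat it as the
  qualitative counterpart of the quantitative voxel backend.
* Landmarks are inputs, as in the manual workflow this mirrors; there is
  no automatic helicotrema/centre detection.
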