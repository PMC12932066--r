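---
title: "Designing needle-guided prostate biopsy moulds: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing needle-guided prostate biopsy moulds: model, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostamould)
```

## The problem

After radical prostatectomy, the explanted prostate still contains the
MRI-visible lesion that was biopsied in vivo, but fresh (unfixed) tumour
tissue is hard to sample blind: cancer is not visibly distinct from benign
gland. If the MR-US fusion platform's surface segmentations — one prostate
boundary mesh, one mesh per radiologist-drawn region of interest (ROI) —
are available as STL exports, a patient-specific mould can be printed
whose cavity reproduces the gland shape and whose drilled channels aim a
core-biopsy needle at each lesion's centre of mass. The specimen is placed
in the mould in a known pose, the needle is inserted to a fixed depth
through each guide, and the core is taken from the target without
disturbing the downstream pathology workflow.

`prostamould` implements this construction end to end, plus the two things
needed to trust it without clinical data: a seeded synthetic-case
generator with closed-form ground truth, and a targeting simulator that
measures what the clinical study can only observe as a binary outcome
(cancer present in the core or not) as a continuous geometric quantity
(notch-lesion intersection length under placement error).

## Construction procedure

For a case (boundary mesh $B$, ROI meshes $R_1 \dots R_k$, millimetres,
LPS frame), with spec defaults in parentheses:

1. **Offset variants.** The cavity is $B$ dilated outward by
   $\delta \in \{0, 1, 2\}$ mm. The looser variants tolerate slight MRI
   segmentation error: in practice one of the three printed moulds fits the
   explanted gland. Offsetting is exact signed-distance dilation, not
   vertex-normal displacement, so it is robust to sharp features and never
   self-intersects.
2. **Block.** The mould body is the axis-aligned bounding box of the
   *unoffset* boundary expanded by the wall margin (10 mm) — a
   material-optimised rectangular block rather than a literal cube. All
   three variants share this block so the guide plan transfers unchanged.
3. **Cavity subtraction.** Because the cavity lies strictly inside the
   block, the boolean difference is exact: block faces plus the
   orientation-flipped cavity surface.
4. **Insertion opening.** The specimen must get into the cavity. The
   sampling approaches are superior, posterior and the two laterals, which
   leaves the anterior face free; the builder subtracts the prism swept
   from the cavity silhouette (projected along the anterior axis) from the
   cavity mid-plane out through the anterior face. A one-piece open-face
   block was chosen over a two-piece split mould: it prints without
   assembly features and the four sampling faces stay intact.
5. **Guide planning.** Each ROI's volumetric centre of mass is computed by
   the divergence theorem. For each ROI, the `guides_per_roi` (2) approach
   faces with the smallest perpendicular centroid-to-face distance are
   chosen (ties broken in the fixed order superior, posterior,
   left-lateral, right-lateral). Guide axes are the inward face normals
   through the centroid: perpendicular entry is how a hand-held needle is
   actually used, and oblique channels would need oblique towers that
   print poorly.
6. **Length calibration.** With fixed insertion depth $D$ (50 mm) and a
   needle whose specimen notch centres $t$ mm behind the tip, the notch
   centre lands on the centroid exactly when the guide-top entry point is
   $D - t$ from the centroid along the axis. The guide tower height is
   therefore $(D - t) - d_\text{face}$, where $d_\text{face}$ is the
   block-face-to-centroid distance. This is an identity of the
   construction, not an approximation; the test suite asserts it to
   $10^{-6}$ mm on every emitted guide. A target deeper than $D - t$ from
   every allowed face raises a calibration error naming the deficit.
7. **Carving.** Channels (needle outer diameter + 2 x 0.25 mm clearance)
   are subtracted from the guide top down to the target centroid — because
   the centroid lies inside the cavity void, the channel physically ends
   where the cavity begins and never continues into the far wall. Towers
   are annular cylinders (1.5 mm wall) unioned onto the faces.

### Needle models

The published workflow fixes only the insertion depth (5 cm) and names the
devices. The hole sizes and notch geometry are this package's defaults,
all config-exposed: 14 G manual Tru-Cut, OD 2.11 mm, tip-targeted
($t = 0$); 18 G spring-loaded, OD 1.27 mm, fired notch centring 13 mm
behind the tip ($t = 13$); notch length 18 mm for both.

### Layout rules

Channels of different ROIs must not intersect; the collision test uses
only the *material* segment of each channel (guide top to first cavity
crossing), because two guides of the same ROI from different faces meet
only inside the cavity void. When the nearest face would collide (or the
opening would cut a channel's guidance section, below), the planner falls
back deterministically to the next-nearest allowed face; if a ROI cannot
place all its guides, the build fails rather than silently under-sampling.

A channel aimed anterior of the cavity waist legitimately *terminates at
the insertion opening* a few millimetres short of the cavity: the needle
crosses a short open gap straight into the specimen surface. This is a
feature of any open-face mould (the opening rim tapers to a knife edge
where it meets the cavity), so the layout gate only requires the opening
to stay clear of each bore over its proximal guidance section — the tower
plus the first `max(5 mm, 2 diameters)` of wall.

## Geometry engine

No R mesh library covers watertight booleans, signed-distance offsetting
and iso-surfacing, and those operations are the substance of this package,
so the engine is implemented here (C++ kernels under `src/`):

* **Representation.** Indexed triangle meshes; *watertight* means every
  edge is shared by exactly two consistently wound faces. Volumes and
  centroids are divergence-theorem surface integrals.
* **Solids as signed distance fields.** Operations sample solids on a
  node-centred grid (`mesh_resolution_mm`, default 0.7 mm): analytic SDFs
  for boxes and cylinders; for meshes, exact point-triangle distance
  within a narrow band of the surface (clamped outside) with the sign
  everywhere from watertight ray parity. Booleans are pointwise min/max;
  offsetting subtracts the offset from the field.
* **Surface extraction.** Marching tetrahedra on the Kuhn 6-tetrahedron
  cube decomposition, which is face-consistent across cells, so the
  extracted surface is watertight by construction whenever the field is
  positive on the grid boundary (the builder pads grids to guarantee
  this). Vertices are deduplicated by grid-edge key; exact-zero node
  values are nudged outside so no degenerate triangles arise.
* **Robustness.** The grid origin carries a fixed sub-voxel jitter so mesh
  vertices and edges generically avoid grid nodes and ray rows; projected
  edge ties in the parity test are broken by a half-open rule on the
  oriented edge direction, counting each crossing exactly once.
* **Pipeline composition.** `build_mould_variants()` composes one field
  per variant from the primitives (box, offset cavity, opening prism,
  towers, channels) and remeshes once, rather than chaining the staged
  mesh operations, which would resample intermediate surfaces twice. The
  staged operations (`subtract_cavity()`, `cut_insertion_opening()`,
  `carve_guides()`) remain first-class and are tested independently.

The 0.7 mm default resolution keeps every volume the test suite measures
within a fraction of a percent of its closed form (a full three-variant
case builds in seconds); halve it for production prints if sub-0.1 mm
surface fidelity matters.

### STL round trips

STL is unitless; this package fixes millimetres (the convention of
DICOM-derived exports) and defaults to the LPS frame (+x left, +y
posterior, +z superior) — segmentation platforms do not record the frame
in the file, so the tag is carried on every mesh and is configurable.
Binary STL stores float32, so binary round trips are exact only to format
quantisation (about $|x| \cdot 2^{-23}$ per coordinate); ASCII output
prints 17 significant digits and round-trips exactly. Loading merges
facet-duplicated vertices (tolerance $10^{-6}$ mm) and re-winds faces
consistently, but never fills holes: a hole in a boundary segmentation is
a data error, not noise.

## Synthetic cases and what they do (and do not) show

`generate_phantom()` builds ellipsoidal prostates and spherical/ellipsoidal
ROIs, because closed forms give free oracles: every volume, centroid and
chord length the tests assert is computed analytically, never from the
code under test. `default_cohort_phantoms()` emulates the reference
cohort's observed ranges: prostate volumes uniform in 25.5–55.4 ml (mapped
to semi-axes with fixed 1 : 0.9 : 1.1 anisotropy, avoiding degenerate
shapes), one or two lesions per case (second-lesion probability 1/3, as in
the cohort) with volumes uniform in 0.13–2.41 ml, placed uniformly inside
the gland with a 2 mm containment margin and non-overlapping (joint
rejection sampling; a second lesion prefers the hemisphere away from the
first, mirroring the cohort's small secondary lesions). Optional boundary
noise is a smooth seeded radial field (a short sum of plane-wave
sinusoids), not i.i.d. vertex jitter, so perturbed surfaces stay
watertight.

Passing tests on these phantoms show the *geometry* is right: calibration
identity, containment, watertightness, volume agreement with voxel
booleans, hit rates. They do not show robustness to real segmentation
artefacts (stair-stepping, lobed TZ shapes, touching structures), and the
simulator's rigid-specimen assumption is the largest idealisation: a real
gland deforms as it settles into the cavity, which is precisely the error
the 1–2 mm offset variants and the error model are there to absorb, not a
phenomenon the package models.

## Targeting simulator

The needle is modelled as its axis plus the notch interval — a 1D model.
The finite core diameter would only add lateral tolerance (< 0.7 mm), so
ignoring it makes the hit criterion conservative. A *hit* is a strictly
positive notch-ROI intersection length, computed by exact segment-mesh
clipping. With zero placement error, every guide hits by the calibration
identity; `perturbed_hit_rate()` applies seeded rigid jitter (per-axis
Gaussian translation, Gaussian-angle rotation about the cavity centroid,
and optional uniform-in-ball free play standing in for a specimen sitting
loosely in an offset cavity) and reports per-guide Monte-Carlo hit rates.
For a spherical ROI under pure translation error the hit probability has a
one-dimensional closed integral (Rayleigh radial component x Gaussian
axial component), which the acceptance checks integrate numerically and
compare against the simulator at n = 2000 trials.

## Numerical choices

* Vertex merge tolerance $10^{-6}$ mm; validation never repairs holes.
* Grid resolution 0.7 mm (builder), voxel oracle 0.5 mm. The voxel oracle
  keeps the block analytic and counts nodes only against curved
  boundaries, because node counting over large grid-aligned planes incurs
  a coherent half-voxel bias.
* Approach-face ties broken in a fixed order for determinism; all
  randomness flows from explicit integer seeds, and identical configs
  yield byte-identical STLs and manifests.
* Medians are the midpoint of the central order statistics; reported
  cohort medians round half-away-from-zero to the conventional printed
  precision (2 dp PSA and PSA density, 1 dp prostate volume) — banker's
  rounding would misreport a 0.175 median as 0.17.
* The packaged reference table is kept verbatim; its printed per-lesion
  summary statistics contain internal inconsistencies (a stated mean ROI
  volume and prostate-size range that no subset of the table reproduces),
  so only the medians and fractions are recomputed as checks.

## Known limitations

* Rigid specimen; no deformation or swelling model.
* One-piece open-anterior mould only; split or slit (whole-mount) moulds
  are out of scope.
* Guide axes are face-normal; oblique trajectories are not planned.
* No avoidance of urethra or neurovascular structures (no such
  segmentations are in scope).
* The simulator's hit rate is a geometric surrogate: clinical yield
  conflates targeting with tumour biology.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 5))
models <- build_mould_variants(ph, mould_spec())
models[[2]]                                 # the +1 mm variant
rep0 <- perturbed_hit_rate(models[[1]], ph, error_model(seed = 1), n_trials = 1)
rep0$hit_rate                               # 1, 1 - calibration identity
summarize_cohort(load_reference_cohort())
```
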