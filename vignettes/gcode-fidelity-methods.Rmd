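---
title: "Measuring the geometric fidelity of FDM G-code"
author: "slicerQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the geometric fidelity of FDM G-code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicerQC)
```

## The problem

Slicing software converts a surface mesh (STL) into layered toolpaths and
G-code. Whatever geometric error the slicer introduces — perimeter
offsetting, corner handling, layer quantization, omitted partial layers —
is embedded in the G-code and reproduced faithfully by the printer,
independent of the printer's own accuracy. For patient-specific anatomical
models and implants this slicer-induced error is a relevant fraction of the
total process error, yet it is rarely quantified because the G-code is
treated as an opaque intermediate.

slicerQC reconstructs the geometry *encoded in the G-code* and compares it
with the reference STL, with no printing involved. The pipeline is
slicer-independent: it needs only the G-code text (RepRap linear-move
dialect), the reference mesh, and a small step-shaped calibration object
that was co-sliced with the model.

## Pipeline

1. **Parse** (`parseGcode`). G0/G1 moves under G90/G91, M82/M83 and G92
   state are resolved to absolute coordinates. Extrusion segments are moves
   with a positive extrusion delta; an E-axis retraction and its un-retract
   are travels, and extrusion resumes only once the cumulative extrusion
   exceeds its pre-retraction maximum, so prime moves never create phantom
   geometry. Arc moves (G2/G3) are rejected rather than linearized, and
   inch mode is rejected: silent approximation would contaminate exactly
   the quantity we are measuring. Layer height, line width and extrusion
   multiplier are read from slicer header comments, falling back to modal
   analysis of Z steps, then to user defaults (with a warning). The
   extrusion multiplier is carried in the metadata but plays no geometric
   role.

2. **Sample the nozzle centerline (PC1)** (`extractCenterlinePoints`).
   Every segment contributes its endpoints plus intermediate samples at
   most `spacing` apart; the default spacing is half the voxel size so
   that rasterization cannot skip voxels (a Nyquist-style bound). Each
   point carries links to its neighbours in G-code order (broken at
   travels) and a tangent computed by central difference between the
   neighbouring *original* G-code vertices — one-sided at open path ends,
   wrapped on closed contours. No smoothing is applied to tangents or
   normals; noise suppression is left to the voxel shell test.

3. **Voxelize and classify** (`voxelize`, `classifyLabels`). PC1 is
   stamped into a 0.10 mm grid (half-open voxel membership with a 1e-7 mm
   guard so exact-plane coordinates index deterministically) and closed
   morphologically with a cube kernel of radius `w/2` = 0.20 mm so that
   extrusion lines spaced one line width apart fuse into a solid. The
   closed solid's surface is the *centerline envelope*, half a line width
   inside the true surface — which is exactly what the later XY offset
   corrects. We deliberately do not dilate by the material footprint: the
   shell filter must retain the centerline points themselves, and the
   offset correction assumes the shell crust runs through them. The
   exterior is found by a 6-connected flood fill from the grid border
   (complementary connectivity to the 26-connected occupied phase);
   occupied voxels 26-adjacent to the exterior are SHELL, the rest
   INTERIOR; enclosed cavities that survive closing stay EMPTY. A
   watertight iso-surface (`marchingCubesSurface`, a tetrahedral-
   decomposition marching-cubes variant: six tetrahedra per cell, midpoint
   interpolation, orientation fixed against the inside phase) is available
   for QC; the quantitative pipeline never measures on voxel centers.

4. **Shell filter (PC2)** (`shellFilter`). Only points whose voxel is
   SHELL survive; infill and inner perimeters disappear. Links re-thread
   across removed points within the same contiguous path.

5. **XY offset (PC3)** (`xyCorrect`). Each point spawns two candidates at
   ±w/2 along the in-plane normal. If exactly one lies in the infill
   (INTERIOR voxel), the other is the true surface point; if neither does,
   the path is a free-standing single line and both are kept; if both do,
   the point is dropped and counted as an error diagnostic. On the top and
   bottom layers the whole deposition plane is SHELL, so the inner
   perimeter also keeps both candidates there; the chain used for contour
   reconstruction follows the candidate in an EMPTY voxel (the outermost
   filament boundary) and contour building later validates hole contours
   against the label map, dropping rings that have deposited material
   inside them.

6. **Z correction (PC4)** (`zCorrect`). The nozzle Z is the *top* of the
   deposited bead, so every point moves down by one layer height; points
   whose deposition voxel has an EMPTY voxel directly above belong to the
   superior edge and move back up. The voxel lookup uses the point's
   pre-correction centerline position: the corrected position lies half a
   line width outside the crust, where the EMPTY-above test would
   misclassify every wall point as a top edge.

7. **Calibration split and registration** (`splitCalibration`,
   `comPrealign`, `icpRefine`, `applyTransform`). The scene must contain
   exactly two 26-connected components; points are assigned to components
   by nearest occupied voxel (a spatial-index lookup, since corrected
   points sit just outside the crust). The calibration object is
   recognised by its rotation-invariant bounding dimensions — the
   minimum-area enclosing rectangle of the footprint (rotating calipers)
   plus the Z extent, compared sorted at ±0.5 mm — because parts are
   placed rotated on the virtual bed and an axis-aligned box would grow
   with the rotation. Registration is center-of-mass pre-alignment
   (point mean onto volumetric mesh centroid) followed by rigid ICP with
   nearest-point-on-surface correspondences and SVD updates: 50 iterations
   maximum, convergence declared when the RMS residual falls below
   0.02 mm. A corrected toolpath cloud carries quantization scatter above
   that threshold, so in practice all 50 iterations run; treating the
   0.02 mm as a threshold on the *change* of the residual instead stops
   the iteration while several tenths of a degree of an initial bed
   rotation are still unrecovered, which would make the registration
   useless for rotated placements. The step shape's asymmetry pins the
   orientation; no outlier trimming is applied. The recovered transform is
   applied to the model cloud (TPCM).

8. **Metrics** (`surfaceMetrics`, `volumeDifference`). Signed
   point-to-surface distances from every TPCM point to the reference mesh:
   magnitude is the Euclidean distance to the nearest surface point, sign
   comes from the angle-weighted pseudo-normal at the closest feature
   (face normal on faces, adjacent-face average on edges, angle-weighted
   average on vertices), which keeps the sign continuous across edges.
   Reported are the signed mean (MSD), RMS, and signed extrema; the
   unsigned minimum is kept as a diagnostic. Symmetric metrics (Hausdorff)
   are deliberately not computed: the STL is the ground truth, so the
   unidirectional deviation is the interpretable quantity. Nearest-
   triangle ties break by lowest index, and the uniform-grid spatial index
   enumerates every triangle that can attain the minimum, so the indexed
   and the exhaustive route agree exactly.

9. **Layer reconstruction** (`buildLayerContours`, `extrudeLayer`,
   `mergeLayers`, `reconstructMesh`). Closed contours are traced through
   the G-code links within each layer (closure tolerance w/4 = 0.10 mm:
   wide enough to close seam gaps, too narrow to fuse distinct contours),
   snap-rounded to a 1 µm grid, simplified by a 2 µm chord-distance
   collinearity test (just above the snap noise, so straight runs collapse
   to their endpoints even on rotated walls), and nested even-odd (outer
   CCW, holes CW). Each layer extrudes to a prism between k·h and
   (k+1)·h — triangulated caps by deterministic ear clipping, vertical
   side walls, holes as inverted prisms so signed volumes subtract. Slabs
   merge with all-or-nothing interface handling: identical opposing caps
   cancel and the walls fuse; differing caps (staircase treads, first/last
   layers) are both retained as separate closed components. Either way the
   mesh passes the same watertightness check the volume code enforces, and
   the total volume is exactly the sum of slab volumes. Reconstruction
   runs in the slicer frame (exact k·h planes, label map available for
   hole validation) and the mesh is then carried into the reference frame
   by the recovered transform; the volume is invariant under that rigid
   motion.

## The calibration object

Every slicer uses its own build-plate coordinate system, so the sliced
geometry must be registered back to the STL frame without introducing
error. A step-shaped fiducial — two orthogonal blocks, bounding box exactly
10.00 × 6.25 × 8.75 mm (`makeCalibrationObject`) — is co-sliced with the
model near the origin. Its three perpendicular reference faces and the
asymmetric step profile make the rigid registration well-posed.

One real property of this object is worth understanding: 8.75 mm is not a
multiple of the 0.20 mm layer height, so the encoded solid is 8.60 mm tall
(the slicer drops the partial top layer — the same height-error mechanism
that motivates G-code verification in the first place). Registering the
encoded object onto the 8.75 mm reference therefore carries a small
constant bias transform (a tilt of ~0.3° and a fraction of a voxel of
translation, in our fixtures). This bias is a property of the G-code, not
of the registration: it is identical for every placement of the same
scene, so the registration-accuracy harness
(`runRegistrationAccuracy`) reports the *deviation* of the residual
transform across placements, plus the MSD perturbation obtained by
applying the recovered versus the true transform to the same cloud.

## Synthetic fixtures and what they do not show

The package validates itself without commercial slicers through a
deterministic mini-slicer (`miniSlice`): cross-sections at mid-layer
height, two mitered inset perimeters at w/2 and 3w/2, 100% rectilinear
infill at spacing w alternating 0°/90° with a 55% infill–perimeter
overlap, absolute-E extrusion proportional to path length × w × h,
retraction between layers, a deterministic seam at the (rounded)
lexicographically smallest vertex, and header comments carrying h and w.
Fixture conditions follow the study configuration: h = 0.20 mm,
w = 0.40 mm, two perimeters, 100% infill. The final partial layer is
omitted — the simpler of the two conventions real slicers use, and the one
that exercises the height-error mechanism.

Fixture scenes (`composeScene`) put the calibration object at the origin
and the model beside it with 5 mm clearance, then apply a rigid placement
(translations on the 0.10 mm grid, rotations about Z up to ±5°) emulating
the slicer's unknown coordinate system. Because the mini-slicer is
deterministic and the voxel grid origin snaps to the voxel size,
grid-aligned translations yield bit-congruent pipelines — the repeatability
harness (`runRepeatability`) measures exactly 0 deviation across
placements, unlike real slicers, whose residual nondeterminism is one of
the things the full framework exists to measure.

What passing on these fixtures does **not** show: behaviour on organic,
high-curvature anatomy (tangent estimation and corner handling are
exercised only at polygon corners and coarse n-gons), on slicer quirks
(gap fill, thin-wall single-line paths, seam scattering, arc moves), or on
models with internal voids (out of scope: the reconstruction assumes
solid, watertight objects; cross-section *through-holes* are supported,
enclosed cavities are not).

## Numerical choices

* Voxel size 0.10 mm (quantization uncertainty ±0.05 mm per axis);
  the acceptance experiment re-runs two fixture models at 0.05 mm and
  requires the MSD to move by less than 0.005 mm.
* Sampling spacing = voxel/2; closing radius w/2; closure tolerance w/4;
  all configurable through `runConfig` and recorded in every report.
* Half-open voxel membership with a 1e-7 mm guard; seam and sampling
  computations round before comparing so exact translations of a scene
  are bit-congruent.
* Ear clipping picks the lowest-index ear; degenerate remainders fall
  back to a fan, which keeps signed volumes exact even if a traced
  contour is locally self-intersecting after snap-rounding.
* ICP correspondence ties and nearest-triangle ties break by lowest
  index; there is no randomized initialization anywhere in the pipeline.
  The only random numbers in the package are in `samplePlacements`, behind
  one seed.

## Problem sizes

The bundled tests and the acceptance script run fixture scenes of
8–20 mm extent: a 20 × 20 × 2 mm box scene yields ~1500 extrusion
segments, ~190k sampled centerline points at the default 0.05 mm spacing
and a ~7M-voxel label map at 0.10 mm voxels (~600k points and ~50M voxels
at 0.05 mm); a full compare takes about ten seconds at 0.10 mm voxels and
about a minute at 0.05 mm. These sizes were chosen so
the whole verification suite reflects every stage of the method on
realistic toolpath structure while staying desk-scale; the method itself
has no fixture-specific assumptions and runs unchanged on larger G-code.

## Known limitations

* Linear-move dialect only; G2/G3 arcs and firmware retraction (G10/G11)
  are rejected, multi-extruder T commands are out of scope.
* The XY offset assumes a uniform nominal line width; elliptical bead
  shapes and flow-dependent widths are physical-print effects outside the
  G-code-level analysis.
* Heavy occlusion or fragmentation of the calibration object would
  degrade the registration; no mitigation is implemented.
* Adaptive layer heights are not supported; the reconstruction uses the
  single slicer-defined layer height.
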