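---
title: "Methods: quantifying DICOM RTSS round-trip fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DICOM RTSS round-trip fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A DICOM Radiotherapy Structure Set (RTSS) stores each anatomical structure
as a stack of closed planar polygons in patient millimetre coordinates.
Contouring and planning systems, however, usually convert these polygons to
an internal volumetric representation (a binary mask or a surface mesh) the
moment a structure is loaded. When the structure is exported again, the
reverse conversion does not in general restore the original polygon
boundary: vertices move, vertex counts change, and small disconnected
regions can silently disappear. For contour similarity measures (CSMs) used
in auto-contouring validation and clinical monitoring — where an unedited
contour is *expected* to compare as identical to its source — such
software-induced displacements masquerade as edits.

`rtssfidelity` implements the complete assessment pipeline for this
problem: analytic test structures, a simulator of re-export behaviours,
slice-wise vertex-displacement analysis, and a suite of polygon- and
mesh-based similarity measures with voxel-relative tolerances.

## The data model

* `planar_contour` — one closed polygon at a fixed z. The polygon is
  implicitly closed; the closing vertex is never stored twice.
* `rt_structure` — a named list of contours. Several contours may share one
  z (disconnected regions, or holes under the even-odd rule).
* `image_grid` — in-plane spacings `dx`, `dy`, slice spacing `dz`, origin
  (center of voxel (0,0,0), DICOM ImagePositionPatient semantics) and voxel
  counts. The grid supplies the *in-plane voxel size* `min(dx, dy)` that
  normalizes tolerances and displacement histograms. Coordinates in
  contours are always patient millimetres; voxel indices exist only inside
  rasterization.

RTSS files are read and written natively (explicit VR little endian). The
writer's `decimal_places` argument controls the DecimalString precision of
coordinates — the mechanism behind the tiny but measurable differences
between exporting systems. The grid travels in a JSON sidecar
(`<file>.grid.json`) because a bare RTSS carries no pixel-spacing
information.

## Cleaning

Before any distance analysis both members of a pair are cleaned exactly the
same way: consecutive duplicate vertices (cyclically, including a stored
closing point) are removed at `eps = 1e-6` mm, and degenerate contours —
fewer than 3 distinct vertices, or absolute shoelace area below
`area_eps = 1e-6` mm² — are dropped. "Zero volume" is interpreted as zero
in-plane area, since a planar contour only contributes volume through its
area. Cleaning both sides avoids penalising systems that deduplicate during
re-export. Cleaning is idempotent and never moves a surviving vertex.

## Displacement analysis

For every vertex of the original contour, the displacement is the distance
to the *nearest location* on the re-exported contour — the closest point on
the closed polyline, not the nearest vertex — computed strictly in 2D on
the matching slice (slices match within `dz / 10`). Summaries are the mean
and maximum over vertices, plus a cumulative curve of distances divided by
the in-plane voxel size.

Original slices with no counterpart in the re-export are a topology signal,
not a distance: their vertices are excluded from the mean/max but remain in
the cumulative-curve denominator, so the curve tops out below 1 when slices
vanished. Topology change is flagged when per-slice contour counts differ,
when slices exist on one side only, or when the directional maximum
boundary distance is large in one direction but not the other (default
threshold 2 voxels) — the signature of a small disconnected region being
removed.

## The measure suite

Polygon pathway (computed directly on the stacks):

* **nAPL** — the fraction of the reference perimeter lying farther than the
  tolerance from the test contour; 0 = within tolerance everywhere, 1 =
  outside everywhere. Each reference edge is subdivided into sub-segments
  no longer than `tol / 4` (floored at 0.05 mm) and classified by its
  midpoint distance. A 1e-9 mm slack absorbs floating-point ties, so the
  identity comparison is exactly 0 even at tolerance 0.
* **vDSC** — `2 V(A∩B) / (V(A) + V(B))` with per-slice areas by exact
  even-odd clipping. Intersection areas use a trapezoidal slab
  decomposition (y-breaks at every vertex and every A–B edge crossing);
  within a slab no edges cross, so the even-odd interior of each set is an
  ordered sequence of trapezoids and intersection reduces to interval
  overlap. This is exact for simple, non-self-crossing contours and —
  unlike classic clipping algorithms — robust for identical polygons and
  shared edges. Holes subtract by nesting parity; slice volume is
  area × dz, so dz cancels in the ratio.
* **2DHD / 95%2DHD / 50%2DHD / 2DMSD** — both boundaries are resampled at
  ≤ 0.1 mm arc length per matched slice; directional nearest-boundary
  distances are pooled over both directions and all slices; the aggregates
  are max, 95th percentile, median and mean of the pooled sample. Pooling
  (rather than per-slice maxima) keeps percentiles well-defined when slices
  carry few samples; the max is identical either way.

Mesh pathway (sDSC, 3DMSD): the structure is rasterized at grid resolution
(even-odd rule at voxel centers, centers exactly on an edge count as
outside), a signed Euclidean distance field is computed (exact two-pass
transform, negative inside), and the zero iso-surface is extracted with
linear interpolation. Surface distances are evaluated at face centroids
with area weighting against the other mesh's triangles (point-to-triangle,
not point-to-vertex).

## Design choices made where the design was open

* **Marching tetrahedra rather than classic marching cubes.** Each cell is
  split into 6 tetrahedra sharing a main diagonal; each tetrahedron
  produces 1–2 triangles with vertices linearly interpolated along its
  edges. This gives the same sub-voxel placement as marching cubes at
  iso-level 0 but is watertight by construction — the classic cube case
  table has ambiguous configurations that can leave holes, and the package
  asserts watertightness on every extracted mesh.
* **Slice extrusion.** A structure contoured every `dz_s` mm occupies
  `z ± dz_s / 2` around each contoured plane when rasterized, so a stack of
  21 slices spaced 2.5 mm yields a 52.5 mm-thick volume. End-slice handling
  differs between commercial systems; this convention is fixed and
  documented rather than configurable.
* **Grid phase.** `grid_for_structures()` offsets in-plane voxel centers by
  half a voxel from the structure bounding-box center, so polygon faces
  drawn on whole-millimetre positions fall on voxel-boundary midlines — the
  arrangement seen when contours follow a CT grid. Axial voxel centers are
  aligned with the contour planes. With this phase, a mask round trip of an
  axis-aligned face reconstructs it exactly; with the opposite phase every
  flat face would shift half a voxel, which is the worst case rather than
  the typical one.
* **nAPL normalization.** The added path length is normalized by the
  reference's total perimeter, bounding it to [0, 1] with the endpoint
  meanings above.
* **Directional measures and slice sentinels.** Distances from samples on
  unmatched slices are infinite sentinels: reported, excluded from finite
  aggregates (with a warning), and routed into the topology flag instead of
  the mean.

## The synthetic world

The generator emulates two dataset families:

* Six analytic pairs: sparse corner-only cuboids (A, B), densely sampled
  cuboids (C, D; vertices every 1 mm along the perimeter), and a sparse
  (E) and dense (F) octahedron whose diamond cross-sections shrink linearly
  toward the apices. Object dimensions are not published for the original
  datasets, so the package fixes a realistic default once: 50 mm cubes and
  50 mm half-diagonal octahedra, dz = 2.5 mm, 1 × 1 mm in-plane voxels.
  Each test member is the reference translated by 5 mm along x, giving
  closed-form expectations for every measure (e.g. vDSC
  `2·45·50·50 / (2·50³) = 0.9`, 2DHD = 5 mm).
* A multi-region fixture: a large primary cuboid plus a small satellite
  (default 2 mm side, 4 mm² area) separated by a 30 mm edge-to-edge gap on
  shared slices — the input for small-region-removal and topology tests.

The re-export simulator provides seven deterministic modes
(`truncate_precision`, `resample_path`, `mask_roundtrip_2d`,
`mask_roundtrip_3d`, `drop_small_regions`, `subsample_vertices`,
`densify_vertices`); a simulated "system" is an ordered list of modes.
These reproduce the four empirically observed behaviour classes: negligible
displacement (precision truncation at ≥ 6 decimals, < 0.01 voxel), minor
vertex movement (fine path resampling at 0.25 mm, < 0.1 voxel — the worst
corner cut of uniform resampling at spacing `h` across a right angle is
`h / (2√2) ≈ 0.09` voxel on a 1 mm grid), mask-like displacement (2D mask
round trip, mostly < 0.2 voxel on densely sampled shapes), and heavy-tailed
behaviour (3D mask round trip with one binary closing, emulating volumetric
smoothing).

What the synthetic world does *not* emulate: anatomical shape complexity,
real CT resolutions and noise, vendor-specific resampling heuristics, and
the exact reference/test relationship of the original published pairs
(translation is a labelled stand-in). A green test therefore establishes
the correctness and calibration of the *measures and pipeline*, not the
behaviour of any particular commercial system.

## Numerical notes

* Point-on-boundary ties: rasterization counts a voxel center exactly on an
  edge as outside (deterministic); nAPL and sDSC classifications carry a
  1e-9 mm slack so identity comparisons are exact. 45° edges that pass
  exactly through voxel centers (the sparse octahedron at default
  alignment) sit on this knife edge: a 1e-15 mm coordinate perturbation can
  flip individual boundary voxels of the *mask*, which is visible in
  mesh-pathway measures but bounded by one voxel; polygon-pathway measures
  are unaffected.
* The slab intersection area assumes contours do not self-intersect; it is
  exact (up to float arithmetic) including shared edges and identical
  inputs.
* `distances_2d` discretization error is bounded by the 0.1 mm sampling
  step; nAPL sub-segment error by `tol / 4`. Both are configurable.
* Degenerate apex slices of octahedra (area below `area_eps`) are omitted
  at generation time, mirroring the degenerate-contour rule.

## Limitations

* Only explicit-VR little-endian RTSS files are read; only `CLOSED_PLANAR`
  contours are supported (point and open contours are rejected with a clear
  error).
* No registration or frame-of-reference transformation: structures are
  compared in the coordinates they carry.
* The 2D percentile measures are defined on the pooled bidirectional
  sample; published implementations that aggregate per slice may differ in
  the 95%/50% variants (the maximum is identical).
* Statistical comparison across systems (beyond descriptive tables) is out
  of scope.
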