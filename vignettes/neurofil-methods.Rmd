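---
title: "From filament-tracer surface exports to hierarchical tracings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From filament-tracer surface exports to hierarchical tracings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofil)
```

## The problem

Semi-automatic filament tracers used on confocal stacks of labelled neurons
export the reconstruction as *surface geometry*: a VRML file holding many
small, unconnected tubular fragments, each encoded as a run of 17-point
elliptical cross-sections, with no tracing points and no parent-child
hierarchy. Morphometric software on the other side of the workflow
(branch-order analysis, Sholl analysis, spine counts) consumes
*hierarchical tracings*: points with radii, a rooted tree per neurite,
contour-based somata, and spine markers. `neurofil` converts the former
into the latter, and additionally repairs the fragmented, holed spine
meshes that isosurface exports produce, so that areas and volumes can be
measured on watertight geometry.

Because the exporting tools are proprietary and deposit no public data, the
package carries a seeded synthetic-morphology generator that emulates every
structural quirk of the dialect the algorithms must survive: non-unique
volume identifiers, heavy fragmentation with overlap zones at the cuts,
randomly inverted fragments, elliptical (not circular) slices with random
start phase, and artificial "insertion sphere" geometries attached to some
spines. All tests and the acceptance script run against this generator, so
the whole test bed is self-contained.

## Skeletonization of sliced fragments

Each 17-point slice becomes one tracing point: the **center** is the
arithmetic centroid of the slice points, and the stored thickness is the
**slice radius** — the distance from the center to the farthest slice
point, i.e. the major semi-axis for an elliptical section. The centroid is
exact for the uniform angular sampling the exports use and degrades
gracefully otherwise; the max-distance radius convention means thickness
statistics refer to the widest extent of the cross-section rather than an
area-equivalent radius, which is worth keeping in mind when comparing
against other radius estimators.

A fragment's slices, in file order, yield a polyline of tracing points.
Spine identifiers sometimes carry two geometries — the spine proper plus a
small artificial sphere-with-neck added at the insertion; only the **main
geometry** (more slices; on a tie, the larger bounding-box diagonal)
enters the tracing, since the artificial sphere would bias area and volume
downstream.

## Rebuilding the hierarchy

The tree is rebuilt greedily, one polyline at a time, from a
polylines-to-be-processed pool. The first fragment in each file is taken as
the one closest to the soma and seeds the neurite. For the polyline being
processed, the distance from each of its points to all points of every
pooled polyline is measured; a pool polyline whose minimum distance falls
at or below the **connection threshold** contributes exactly one
connection at the minimizing point pair. Three mechanisms make the greedy
pass robust:

* **Inverted fragments.** If the connection lands strictly past the middle
  index of the pooled polyline, that fragment was exported tip-first; it is
  reversed and the index remapped before anything else happens. The test is
  index-based with a strict inequality; on near-uniform slicing this is
  equivalent to an arc-length test and the index is what the file provides.
* **Shared connection points.** Connections that land on the same
  intermediate point (or more than two on the final point) are separated by
  moving the farther ones to the nearest free neighboring index, keeping
  the connection count unchanged.
* **Case dispatch.** No connections: terminal fragment, committed as-is.
  One connection at the final point: the two polylines are joined and
  processing continues with the joined polyline. A connection at an
  intermediate point: split there, commit the first part, recurse on both
  remainders. Two connections at the final point: a bifurcation. Several
  connections: handled nearest-the-start-first by repeated subdivision,
  with untaken polylines remaining in the pool to be rediscovered by later
  searches.

Fragment cuts leave one-slice overlap zones, so the raw tree contains
near-duplicate points; a post-pass removes any point closer than the
**dedupe epsilon** (default `1e-3` µm — far below inter-slice spacing,
configurable) to its parent, re-parenting children and never deleting a
bifurcation point.

The connection threshold is searched automatically: starting at 0.2 µm and
doubling (up to 16 µm) until no fragment is left unconnected. The schedule
spans sub-voxel overlap gaps to gross breaks in a handful of iterations;
the first workable threshold is at most twice the largest true gap. Too
large a threshold risks false connections, which is why the search stops at
the first success rather than using a generous fixed value.

Trees are stored parent-pointer style in a single node table; the branch
decomposition (one polyline per maximal unbranched path, as contour-based
ASC requires) is always *computed* from the table, so the two views cannot
fall out of step.

## Somata

Four sources are supported. (i) A stack of 2D contours: the convex hull of
all contour vertices is taken and then remeshed isotropically, since the
raw hull is sparse and irregular while the later soma-to-neurite
deformation wants dense, uniform triangles. Only convex somata can be
produced this way. (ii) A sphere from incomplete information. (iii) When no
soma information exists at all, a sphere whose center is the barycenter of
the first-order neurite starting points and whose radius is the shortest
distance from that center to any of them. (iv) An externally supplied
surface mesh (OBJ/PLY).

When a geometric soma is available, neurite points strictly inside it are
removed and the intersection of the first inside-to-outside segment with
the soma surface becomes the real initial tracing point, its radius
linearly interpolated along the segment (the interpolation rule is the
package's choice; nothing in the problem fixes it).

**Isotropic remeshing.** Rather than an edge split/collapse/flip loop, the
package exploits convexity: a subdivided icosphere is radially projected
from the hull centroid onto the hull surface (exactly, via the half-space
representation), then relaxed tangentially and re-projected for a few
iterations. The subdivision level is chosen by measuring the mean projected
edge length of a coarse probe sphere against the target edge length
(default: hull diameter / 20). Vertices end exactly on the hull, so the
result is convex to machine precision, and ≥ 95% of edges land within
[0.5, 1.5] × target on the soma shapes that matter. This is simpler and
more robust in pure R than a half-edge remesher, at the cost of only
handling star-shaped (here: convex) surfaces — exactly the supported class.

**Deformation.** The physically based mass-spring soma deformation of the
original mesh-growing pipeline is deliberately replaced by a simplified
geometric pull: for each first-order start, the nearest soma vertex moves
toward it by `pull_fraction` of the gap (its one-ring at half weight), and
one Laplacian pass smooths the untouched vertices. This is a documented
fidelity deviation: it produces the same qualitative "pulled toward the
neurites" shape with none of the simulation machinery, and connectivity
(hence closedness) is untouched.

For contour-based ASC output, the soma is converted back to 2D contours by
cross-sectioning at z-levels spanning the central 90% of the z-extent
(avoiding degenerate pole contours), each contour ordered counterclockwise
from +z.

## Spines

Spine meshes cut from the dendrite have a flat base. The base is detected
as the largest-area cluster of coplanar faces (normals within 2°, plane
offsets within 1e-3 of the bounding-box diagonal, at least 5% of the total
area). The mesh is rotated so the base outward normal lies along −Y (body
in +Y; the sign convention is the package's, since "aligned with the
Y-axis" leaves it open) and translated so the base centroid is the origin.
The inverse pose — a unit quaternion and a translation — is stored with the
mesh, so the original placement is recovered exactly; this canonical form
is what the on-disk spine store keeps (OBJ mesh + JSON sidecar with
transform and metrics + plain-text index), in open formats so extracted
morphology is not locked to any one tool.

Placement inverts canonicalization against a *spine line* (insertion point
→ spine end) taken from a tracing: the canonical +Y axis is rotated onto
the line direction by the minimal rotation, the base centroid moved to the
insertion point, and optionally the spine scaled uniformly so its height
matches the line length. Scaling is off by default for measured geometry
(preserve real size) and intended for store-sourced replacement spines.
Spines imported verbatim from isosurface files are stored untransformed
and flagged non-reusable.

Attachment never edits the neurite tree: a spine whose insertion point
lies within the connection threshold of some tracing point becomes an
annotation on that point (argmin; ties resolved to the earliest point in
depth-first order); in ASC output it appears as a marker line after the
insertion point's line. For inputs with no spine geometry, spine lines can
be read from length-measurement tables (first point = head, last point =
insertion) or sampled synthetically: a Poisson process along dendritic
arclength at a given density, leaving the shaft perpendicular to the local
tangent, length uniform in 0.5–2.5 µm — values typical of dendritic spines
on cortical pyramidal cells.

## Mesh repair and comparison

Isosurface spine exports are often split over several intersecting or
near-touching sub-meshes, some with holes, making area and volume
ill-defined. The repair pipeline converts to a volumetric representation
and back:

1. **Oriented bounding.** A PCA-oriented bounding box of the combined
   vertex set bounds the voxel grid, which keeps elongated structures from
   exploding the voxel count.
2. **Voxelization.** Each sub-mesh is voxelized *separately* and the
   occupancies OR-ed — crucial, because parity-counting a soup of
   intersecting sub-meshes would cancel overlaps. The inside test is
   ray-crossing parity along all three grid axes with majority voting, so
   a hole flips at most one vote and interior labels survive imperfect
   surfaces.
3. **Morphological closing.** Euclidean-ball dilation then erosion (radii
   in voxels, via an exact squared distance transform) joins disconnected
   pieces such as a spine head separated from its neck. Gaps below twice
   the dilation reach are bridged for features at least comparable to the
   closing radius; sub-voxel export gaps are far inside this.
4. **Smoothing + extraction.** The 0/1 occupancy is Gaussian-filtered
   (sigma in voxels), padded by an empty border, and contoured at the 0.5
   level by tetrahedral decomposition of the voxel lattice (six tetrahedra
   per cell sharing the main diagonal). This marching-tetrahedra variant
   of grid contouring emits watertight, consistently oriented surfaces by
   construction — every lattice edge is interpolated once and shared —
   which is why it was chosen over the table-driven cube variant.

Defaults (voxel 0.05 µm, dilation/erosion 2 voxels, sigma 1 voxel, iso
0.5) are tuned for spines, whose necks at 0.1–0.2 µm set the resolution
floor; a 512³ voxel budget turns runaway grids into an explicit error
rather than silent downsampling. Surface area, volume and mass center are
integrated on the result by the divergence theorem after orientation
fixing.

Comparison uses sampled Hausdorff distances: points on mesh A (all
vertices plus area-weighted random face samples, seeded) are measured
against mesh B by true point-to-triangle distance; the directed distance is
the maximum, the symmetric distance the larger of the two directions, and
mean/min are reported alongside. A blue-to-red linear ramp over the
per-vertex distances is written as a vertex-colored PLY, warm colors
marking the larger deviations. Exact polyhedral Hausdorff distance is out
of scope; the sampling error on the fixtures used here is below 2% at 10⁴
samples.

## The synthetic test bed

`generate_neuron()` grows a strictly binary tree by a biased random walk:
runs of points one `step` (default 1 µm) apart, 4–8 µm between branch
events, bifurcation opening angles of 60–80°, radii tapering by 0.85 per
branch order from a 1 µm trunk — coarse but structurally realistic stand-ins
for dendritic arbors. A minimum inter-branch clearance of 4·`step`
(outside a 6-step guard zone around each bifurcation) is enforced by
rejection sampling with rollback, which makes proximity-based
reconstruction well-posed and gives the threshold search a wide safe band.
`fragment_and_emit_vrml()` cuts ground-truth branches into ~5 µm fragments
with one-slice overlaps (and the parent bifurcation point prepended to
child branches, mimicking how exporters emit children from the branch
point), jitters slice eccentricity in [1, 1.3] and start phase, inverts
fragments with probability 0.3, reuses numeric identifier suffixes across
branches, and optionally shuffles all non-root fragments.

What the fixtures deliberately do **not** model: imaging noise in slice
geometry beyond ellipse jitter, non-binary branch points, axonal
morphology distinct from dendritic, curvature-correlated radius changes,
and true Imaris binary containers. Passing the round-trip tests therefore
demonstrates that the reconstruction logic is correct on structurally
faithful input, not that every real-world export will reconstruct
perfectly — real data can break the "first fragment nearest the soma"
convention or contain gaps beyond 16 µm, both of which surface as explicit
errors rather than silent misconnections.

Problem sizes used by the tests and the acceptance script — 50 seeded
neurons with up to 8 bifurcations for the round trip, unit-sphere pairs at
0.05 µm voxels for repair, 10⁴ Hausdorff samples, 20 seeded spines —
were chosen as the smallest sizes at which the checked properties are
meaningfully exercised.

## Numerical choices and degenerate inputs

* Distances compare with `<=` against thresholds; connection ties break on
  the lowest (current index, other index) pair, spine-attachment ties on
  depth-first order, so results are permutation-stable.
* Coordinate lists not divisible by 17 are a hard error, never truncated —
  silent truncation would corrupt skeletons undetectably.
* Degenerate one-slice fragments yield one-point polylines that may be
  absorbed by concatenation but can never seed a neurite.
* The voxel inside test votes across three ray directions; `iso_level`
  outside the smoothed field's range raises an empty-mesh error.
* Coplanar contour stacks raise a degenerate-hull error; degenerate vertex
  distributions fall back from PCA boxes to axis-aligned boxes with a
  warning.
* ASC files are written with fixed 2-decimal coordinates (0.005 µm
  round-trip guarantee) and d = 2 × radius; clean VRML uses fixed
  6-decimal formatting so re-parsing is bit-identical in text.

## Known limitations

Only convex somata; greedy (not globally optimal) reconnection, exactly as
the sequential algorithm prescribes; spine morphological classification and
head/neck segmentation are out of scope; the ASC dialect targets the
publicly documented grammar and is verified against the package's own
reader, not against any specific commercial parser; IMX support is limited
to a documented plain-text dialect with the vertex-count spine heuristic,
as the true binary layout is unspecified.
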