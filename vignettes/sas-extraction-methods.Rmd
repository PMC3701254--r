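---
title: "Extracting and quantifying synaptic apposition surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and quantifying synaptic apposition surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasmorph)
```

## The problem

Chemical synapses are quantified in volume electron microscopy (FIB/SEM) by
segmenting the electron-dense synaptic junction — the fused active zone (AZ)
and postsynaptic density (PSD) — as a single flattened 3D blob. Because the
AZ and PSD sit face to face across a thin, uniform cleft and have nearly equal
areas, both can be represented by one internal surface lying mid-way through
the blob and following its curvature: the *synaptic apposition surface*
(SAS). Its area is the functionally interesting size measure (it tracks
vesicle release probability on the presynaptic side and receptor number on
the postsynaptic side); its perimeter, curvature and perforations describe
junction shape. `sasmorph` extracts this surface from a binary segmentation
and quantifies it.

A good SAS must (i) lie entirely inside the segmentation, equidistant from
its two faces, (ii) reproduce the segmentation's curvature, and (iii)
reproduce its external perimeter and any perforations. Pure skeletonization,
thinning or Voronoi approaches struggle with the shape variability of real
junctions (tortuous sheets, one or several holes); the method used here is a
hybrid of a distance transform and a deformable planar template.

## The procedure

Given a binary mask with anisotropic voxel spacing (e.g. 3.7 × 3.7 × 20 nm —
all geometry is done in physical nm, never in index space):

1. **Oriented bounding box.** Principal axes of the foreground voxel
   centers; the normal `n` of the largest face gives the junction's flat
   direction. We use the PCA box (covariance eigenvectors plus projected
   extents, inflated by one voxel pitch) rather than the true minimum-volume
   box: it is deterministic, stable, and adequate for flattened blobs.
   Axis signs are fixed deterministically so repeated runs are identical.
2. **Signed distance map.** Exact Euclidean distance between voxel centers,
   positive inside and negative outside, computed separably with the
   physical spacing. `max(DM)` is the depth of the most interior point.
3. **Gaussian smoothing.** The staircase of the voxelization would make any
   internal surface crooked, so the distance map is smoothed with
   `sigma = c_s * max(DM)`. The coefficient is bounded by
   `probit(0.75) = 0.674489`: stronger smoothing can drive the interior of a
   sphere-like object negative, erasing it. The default `c_s = 0.67` is the
   strongest smoothing below that bound. The kernel is truncated at `4 sigma`
   per axis (in voxel units `sigma / spacing`), renormalized to unit sum,
   with edge-reflect boundary handling.
4. **Seed.** The unweighted centroid of all voxels within half the smallest
   spacing of `max(DM)` — the tolerance absorbs discretization ties.
5. **Planar template.** A structured vertex grid spanning the largest OBB
   face, inflated 10% so it overhangs the junction everywhere, passing
   through the seed with normal `n`. The grid pitch is the smallest in-plane
   voxel spacing, which realizes "one vertex per voxel cut by a plane
   parallel to the largest face" without ambiguity.
6. **Deformation.** Each vertex moves along the *fixed* normal by the
   locally sampled normal projection of the distance-map gradient:
   `p(t+1) = p(t) + (grad d . n) n`. The gradient field is static — computed
   once from the smoothed map by central differences — and sampled at vertex
   positions by tricubic (Catmull–Rom) interpolation, which reproduces grid
   values exactly at voxel centers. Because tricubic interpolation is linear
   in the array values, sampling the precomputed scalar field `grad d . n`
   equals projecting the sampled gradient components; we exploit this for
   speed. Out-of-bounds vertices receive zero displacement and are clipped
   later. Vertices only ever move perpendicular to the initial plane, so the
   structured grid cannot fold laterally.
7. **Convergence.** After each iteration the mean Euclidean vertex error
   against each of the last `s = 10` recorded states is computed; iteration
   stops when the minimum drops below `epsilon = c |n| = 0.001` nm (`n` is a
   unit vector; the paper-style expression `c |n|` is dimensionally unclear
   and we adopt the unit-normal reading). Recording several states matters:
   near the medial ridge the update can settle into a small periodic
   oscillation rather than a fixed point, and a two-state cycle still counts
   as converged. A safety cap `max_iters = 500` bounds runtime; phantom runs
   converge in 1–250 iterations.
8. **Clipping.** A vertex is inside iff its tricubically interpolated *raw*
   (unsmoothed) signed distance is >= 0; facets with any outside vertex are
   removed whole. The smoothed map drives seeding and deformation, but
   clipping against the raw map enforces the literal containment criterion
   and keeps perforation geometry unblurred — facets over holes sample
   negative distance and disappear, leaving interior boundary loops. Facet
   removal (rather than re-triangulating the zero crossing) keeps the
   boundary error below one grid pitch, well under the validation
   tolerances.

## Morphometry

On the clipped SAS: area (sum of triangle areas), perimeter (sum of
boundary-edge lengths, *including* hole loops — they are part of the SAS
contour), and the area ratio

`AR(SAS) = 1 − Area(projected SAS) / Area(SAS)`,

which is 0 for a perfectly flat surface and grows with curvature (0.5 for a
hemisphere). The projected area is the union footprint on the largest OBB
face: each projected triangle's area is accumulated per raster cell with
exact triangle-to-cell clipping and per-cell coverage capped at the cell
area. For fold-free surfaces — every mesh this pipeline produces, since
vertices displace only along the fixed normal — this equals the exact
projected area, so a flat SAS yields AR = 0 exactly; a binary cell-coverage
rasterization would instead add a percent-level boundary bias. The sum of
per-facet projections is *not* used because it double-counts folded
surfaces.

Per-vertex curvatures use standard discrete estimators: Gaussian curvature
`K` by angle defect over the barycentric vertex area, mean curvature `H`
from the cotangent Laplace–Beltrami operator signed by the facet-orientation
normal, and principal curvatures `k1,2 = H -/+ sqrt(max(H^2 − K, 0))`, which
guarantees `k1 <= k2` and `H^2 >= K`. Discrete operators are undefined on
the boundary, so boundary vertices are excluded from the summaries. Summary
statistics use the population standard deviation (denominator `n`); the
sometimes-seen `n^2` denominator shrinks with sample size and is treated as
a typesetting artifact.

Segmentation-level features: voxel-count volume, OBB extents, binary
principal moments (eigenvalues of the voxel-center covariance), principal
axes, Feret's diameter (diameter of the exact minimum enclosing sphere of
the voxel centers, Welzl's algorithm with a deterministic order), and the
equivalent ellipsoid with semiaxes `sqrt(5 lambda_i)` — the uniform solid
ellipsoid relation, which recovers the true semiaxes of a homogeneously
filled ellipsoid; the normalization is otherwise unspecified and this choice
is documented here.

## Phantom validation

Real tissue segmentations have no ground truth, so correctness is
established on voxelized analytic solids — slabs, spheres, spherical shell
sectors, perforated sheets and CSG combinations — with closed-form
mid-surface area, curvature and topology. Voxelization is by center
sampling (a voxel is foreground iff its center is inside the solid),
matching the binary output of threshold-based segmentation tools; the
lattice is staggered by half a pitch so that voxel centers never sit exactly
on an analytic face, where the inside test would otherwise flip a whole
boundary layer. Dimensions are at the scale of real junctions (hundreds of
nm). What the phantoms do *not* emulate: gray-level noise, membrane texture,
segmentation errors, or fused multi-junction blobs — passing the suite shows
the geometry engine is right, not that any particular segmentation is.

Choices worth recording:

* The flat slab (740 × 370 × 60 nm) is voxelized at the instrument spacing
  (3.7, 3.7, 20) nm so anisotropy bugs surface. Curved phantoms (sphere,
  shell sector) are voxelized near-isotropically at 4 nm: a 40 nm shell
  sampled at 20 nm sections is only two sections thick and the staircase
  would dominate the curvature signal.
* On the shell sector, curvature and radial-residual checks are evaluated
  over the cap proper — interior vertices whose in-plane radius is at most
  `(R − t/2) sin(theta)`. Beyond that radius the vertical chord leaves the
  full shell thickness and the medial surface legitimately tracks the
  sector's conical cut rim, whose oppositely signed curvature would cancel
  the cap's in a whole-mesh mean. The clipped mesh itself keeps the rim
  skirt: containment, not curvature, is the criterion there.
* `selftest()` runs the full suite (slab, three shell openings, sphere, 1-
  and 3-hole sheets) in roughly ten seconds and checks mid-plane recovery,
  area, AR values and ordering, cap curvature, hole-loop counts and
  convergence everywhere.
* The full-sphere phantom is the smoothing worst case: with
  `sigma = 0.67 max(DM)` the smoothed center value is barely positive (the
  bound exists precisely because a sphere's interior dies first). With the
  reflect boundary and the 2-voxel crop used here it stays positive and the
  sphere pipeline runs at defaults, recovering the equatorial disc; we
  assert only that the center value decreases monotonically in `c_s`, since
  the exact sign-flip point depends on kernel truncation and boundary
  handling.

## Numerical and degenerate-input policy

* Distance transform: exact squared-distance lower-envelope algorithm per
  axis with physical spacing; no chamfer approximation.
* Tricubic sampling clamps edge neighborhoods (replication) and returns 0
  with an out-of-bounds flag outside the array; clipping treats
  out-of-bounds as outside.
* Masks must not touch the array border (the distance map needs background
  on all sides); `extract_labels()` and the phantom generator crop with a
  2-voxel pad. Empty masks, empty clip results and over-smoothed maps (no
  positive voxels) are errors that name their pipeline stage.
* Masks with fewer than 4 non-coplanar voxels fall back to an axis-aligned
  box; seed ties average; eigenvector signs are fixed by convention. The
  whole pipeline is deterministic — identical inputs give bitwise-identical
  meshes and tables.
* Units are always nm (areas nm², curvatures 1/nm); there is no unit
  auto-detection.

## Limitations

* The SAS of a strongly folded junction whose sheet is not a graph over the
  OBB face (e.g. a surface folding back over itself along `n`) cannot be
  represented by a deformed height-field template; such shapes did not occur
  in the validation suite and are rare in practice, but the limitation is
  structural.
* Whole-facet clipping quantizes the SAS boundary at the template pitch;
  perimeters are accurate to about one pitch per boundary run.
* The equivalent-ellipsoid normalization and the inclusion of hole loops in
  the perimeter are conventions (documented above), not universal
  definitions.
* Feret's diameter uses voxel centers, not corners: values are up to one
  diagonal voxel pitch below the corner-to-corner figure.
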