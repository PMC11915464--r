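---
title: "Anatomical head-cap design: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical head-cap design: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the numerics behind `capforge`: what
is being modeled, which algorithmic choices were genuinely open, how the
defaults were chosen, and what the synthetic phantoms do and do not prove
about real heads.

## The 10-20 construction on a triangulated scalp

The 10-20 system and its denser 10-10/10-5 refinements define scalp
positions as fixed fractions of geodesic arc length along reference curves
between four cranial fiducials: nasion (Nz), inion (Iz) and the left/right
preauricular points (LPA/RPA). On a triangulated closed scalp surface the
reference curves are realized as plane/mesh cross-sections: the plane
through three points cuts the closed mesh in a closed polyline whose
vertices are edge-crossing points, and arc length is measured along that
polyline.

The vertex Cz is not a fiducial; it is *defined* as the point that bisects
both the sagittal (Nz to Iz over the top) and the coronal (LPA to RPA over
the top) curves. Starting from a user-supplied guess Cz0, `refine_cz()`
alternates two updates — cut the coronal plane through LPA, RPA and the
current Cz and move Cz to the arc midpoint, then the same with the sagittal
plane through Nz and Iz — until successive estimates move less than a
tolerance (default `1e-6` mesh units, i.e. micrometers when meshes are in
mm). On convex, head-like surfaces each full cycle cancels one component of
the displacement, so convergence takes only a few cycles; the sphere phantom
converges in two.

Two numerical details matter:

* **Iteration floor.** After the user tolerance is met, the iteration
  continues until the step size reaches a machine floor (`1e-13` of the
  bounding-box diagonal) or stagnates. This costs a handful of extra
  cross-sections and makes the converged Cz — and therefore every landmark —
  invariant under rigid motions and uniform scaling to ~1e-12 relative,
  rather than only to the stopping tolerance. The reported iteration count
  is still the number of cycles needed to meet the user tolerance.
* **On-plane vertices.** Signed distances smaller than `1e-12` of the
  bounding-box diagonal are nudged to the positive side before classifying
  edges, so a plane passing exactly through a mesh vertex cannot produce a
  degenerate crossing pattern.

Curve distance is measured along the crossing polyline itself, not along a
smoothed spline; with typical scalp meshes (edge length well under 1% of
head circumference) the polyline shortfall is quadratic in edge length and
far below placement accuracy. The mesh-refinement convergence test in the
suite confirms the quadratic behavior on nested icospheres.

## The montage recipe

The construction order is: sagittal row (Fpz, AFz, Fz, FCz, Cz, CPz, Pz,
POz, Oz at 10%..90% of the Nz-Cz-Iz arc), coronal row (T7, C5, C3, C1, Cz,
C2, C4, C6, T8 on the LPA-Cz-RPA arc), the 10% horizontal ring through
Fpz-T7-Oz (and its mirror through T8), and then intermediate rows, each a
cross-section through three already-placed anchors (e.g. F7-Fz-F8)
subdivided evenly (eighths for the full rows, quarters for the sparse AF/PO
rows). Labels placed earlier are never overwritten; since 10-20, 10-10 and
10-5 use the same anchors and curves, nested systems share bitwise-identical
positions, which the suite asserts.

The intermediate-row subdivision deserves a note: the standard 10-10 rows
contain nine labels (e.g. F7, F5, F3, F1, Fz, F2, F4, F6, F8), i.e. eight
equal intervals across the full arc with the middle anchor at one half, and
that is what `montage_recipe()` encodes. The 10-5 system doubles every
subdivision; half-step positions take their standard compound names where
those are established (AFp7, FTT7, CCPz, ...) and an `h` suffix on the
laterally adjacent label otherwise (C1h, F5h, ...). This dialect is
configurable: `compute_landmarks()` accepts a custom recipe with the same
structure, so an alternative 10-5 label grid can be swapped in without
touching the geometry code. The modern T7/T8/P7/P8 names are primary; the
older T3/T4/T5/T6 appear in the literature as synonyms for the same
positions.

## Cap construction

The cap is built on a deliberately coarse lattice while landmarks are
computed on the *original* fine surface and only then snapped to the coarse
body by nearest-point projection. This ordering means landmark accuracy is
independent of how aggressive the coarsening is; only the snap distance
(reported per label) grows with coarseness.

* **Coarsening** is shortest-edge-first collapse to edge midpoints with a
  manifold link-condition and a normal-flip guard. At `keep_ratio = 0.05`
  on the density-5 sphere the sampled Hausdorff distance to the input is
  ~1.2% of the radius.
* **Grommets** are cylinders centered at each landmark and aligned with the
  outward surface normal, interpolated barycentrically from angle-weighted
  vertex normals (the suite checks interpolated normals against the analytic
  sphere normal to within 2 degrees; face normals alone would err by the
  full edge angle). The default cutter depth, 8x the wire thickness,
  guarantees full penetration after strut extrusion.
* **Hole cutting** re-triangulates the surface exactly along each cutter
  wall: the neighborhood of the outline is first refined by conforming
  marked-edge bisection until triangles are finer than the grommet radius,
  then edges crossing the cylinder's signed-distance zero level are split at
  the interpolated crossing and the interior disk is deleted. Every cutter
  contributes exactly one new boundary loop whose centroid lands within half
  a radius of the landmark.
* **Margins** are cut the same way against box/half-space fields in the
  canonical head frame (origin at the preauricular midpoint, x toward RPA,
  y toward Nz, z toward the vertex): a face box centered on Nz with width
  one third of the head width, a neck plane at one third of the head height,
  and optional ear relief bands. Because the cut lines are re-triangulated
  rather than faces simply deleted, the rims are clean polylines.
* **Wireframe extrusion** replaces every remaining edge by a capsule
  (cylinder with spherical caps) of diameter `wire_thickness` — doubled on
  edges within the margin band, which protects the printed rim from tearing
  — and re-surfaces the capsule union from its exact signed-distance field
  with marching tetrahedra at a voxel pitch of `wire_thickness/4`. Marching
  tetrahedra on a conforming tetrahedral decomposition produces a closed,
  manifold, self-intersection-free surface by construction, which is why
  the pipeline does not need a general mesh Boolean engine for this step.

Two cleanup passes run on every marching-tetrahedra output: a weld at
`1e-6` of the bounding-box diagonal (crossing points generated on nearly
coincident grid edges otherwise survive as micron-scale slivers), and a
pinch resolver that cancels zero-volume duplicate-face flaps and collapses
the rare tiny non-manifold edges where two sheets of the level set touch
within tolerance.

The wireframe minimum-edge guard (wire thickness must not exceed half the
shortest lattice edge) is evaluated against the *pre-cut* lattice pitch,
carried through the cutting stages as an attribute: grommet rings and their
refined transition edges are intentionally finer than the wire and are meant
to fuse into solid collars around each hole.

## Printability and repair

`diagnose()` defines printable as: no non-manifold edges, no boundary
edges, no zero-area faces (area below `1e-14` of the squared bounding-box
diagonal), no zero-length edges, no duplicate vertices (exact duplicates by
default — a tolerance can be passed, but marching output legitimately
contains distinct vertices much closer than a print nozzle), no
self-intersecting face pairs, no orientation-inconsistent faces, and
positive enclosed volume. `repair()` welds, drops degenerate faces, fills
boundary loops of at most 12 edges with a centroid fan (larger loops are
design features — grommets, the face opening — and abort the repair rather
than being sealed silently), reorients all faces consistently outward, and
re-diagnoses; it is idempotent. `remesh_solidify()` handles arbitrary strut
soups by generalized-winding occupancy along voxel columns plus a
narrow-band distance field, so self-intersecting inputs come out as one
watertight solid.

## Surface extraction

Volumes are thresholded (grayscale scalar, a label union, or all nonzero),
reduced to the largest 6-connected component, and interior cavities are
filled so only the outer scalp boundary remains. The binary occupancy is
smoothed by two separable (1,2,1)/4 passes and iso-surfaced at 0.5 in
physical millimeter coordinates; Taubin lambda/mu smoothing (0.5/-0.53,
five passes) removes the residual voxel texture without shrinking.
Triangle density is controlled by the stated criterion — the maximum
circumscribed-circle radius — via midpoint subdivision, which halves the
circumradius per round. The internals of atlas-grade meshing pipelines
(feature-sensitive epsilon-sampling) are approximated by this combination,
not replicated; on the 20-voxel ball fixture the extracted surface is
genus 0 with volume within 1% and area within 0.3% of the closed forms.

## Metrology

The circumference convention is the 10% ring through Fpz-T7-Oz — the
standard cap-sizing ring — so users can compare directly with tape
measurements; when ring landmarks are absent the Nz-LPA-Iz loop is used
with a note. Radial projection uses the preauricular midpoint as center,
the conventional head center. The end-to-end validation mirrors how a
printed cap would be measured against a printed head: recover each grommet
hole's centroid from the cap, project it radially onto the head surface,
and measure its geodesic distance from Iz (sagittal row) or RPA (coronal
row) along the reference curves; `landmark_error_stats()` then reports the
coefficient of determination of measured-vs-reference distances and the
mean and standard deviation of absolute errors. Projecting holes *onto the
head* (rather than landmarks outward onto the cap) is equivalent up to the
radial map and avoids casting rays at a mostly-open lattice.

## What the phantoms do and do not show

The sphere and ellipsoid phantoms have exactly known fiducials and, for the
sphere, closed-form landmark positions; the ellipsoid is checked against an
independent oracle that samples exact plane-quadric intersection ellipses
(plane cuts of quadrics are ellipses, computed by mapping to the unit
sphere and back) at 1e5 points per curve. Passing these checks shows the
geometry code is correct on smooth convex surfaces with noise-free
fiducials. Real scalps add concavities around the ears and nasion bridge,
fiducial-click uncertainty of several millimeters, and segmentation noise;
none of these affect the arc-length arithmetic but all of them add
anatomical variance that the phantom tests deliberately exclude. The
phantom results are therefore a lower bound on achievable accuracy, not a
prediction of on-subject performance.

Default study conditions used across the tests and the acceptance script:
head radius 100 mm (icosphere density 5, 20480 faces — edge length ~3.8 mm,
comparable to a 1 mm-voxel scalp extraction after coarsening), Cz0 displaced
20-30 degrees toward the nasion, `keep_ratio` 0.05, grommet radius 4 mm,
wire thickness 2.5 mm, voxel pitch `wire/4`. These mirror the printed-cap
regime the method targets; the voxel-ball fixture uses radius 20 voxels at
1 mm in a 64-cube grid, small enough that the whole suite runs in a few
minutes on one CPU while keeping every triangle-level tolerance meaningful.

## Known limitations

* Cross-sections assume a closed, single-component scalp mesh; open scans
  must be repaired first (`repair()` fills only small holes by design).
* The exact 10-5 half-step label dialect is not universally standardized;
  swap in a custom recipe if your lab uses different names.
* Margin boxes are axis-aligned in the canonical frame; strongly asymmetric
  heads may need the exposed fractions adjusted.
* The wireframe solid is voxel-accurate to ~half the re-tessellation pitch
  (0.3 mm at defaults) — well under printer tolerance, but not an exact
  constructive-solid-geometry boundary.
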