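# capforge

Anatomically derived, 3D-printable head caps for EEG/fNIRS neuroimaging.

Consistent optode/electrode placement is a major source of variability in
functional neuroimaging. `capforge` turns a subject- or atlas-derived head
surface into a printable wireframe cap whose grommet holes sit exactly at the
anatomically computed 10-20/10-10/10-5 cranial landmarks, so every donning of
the cap reproduces the same scalp positions.

The pipeline:

1. **Surface** — load a closed scalp mesh (STL/OFF/OBJ/JMesh) or extract one
   from a NIfTI volume by iso-surfacing with a user-controlled triangle
   density (maximum circumscribed-circle radius).
2. **Landmarks** — from five fiducials (nasion Nz, inion Iz, left/right
   preauricular LPA/RPA, and an initial vertex guess Cz0), find the true
   vertex Cz by iterative bisection: the coronal plane through LPA–Cz–RPA and
   the sagittal plane through Nz–Cz–Iz are cut against the mesh, Cz moves to
   the arc midpoint of each cut in turn, until successive estimates move less
   than 10⁻⁶ mesh units. Reference rows are then subdivided at the montage
   arc-length fractions (10-20 at 20%, 10-10 at 10%, 10-5 at 5%), and the
   remaining rows are placed on cross-sections through already-placed anchors.
3. **Cap** — coarsen the head surface by edge collapse (`keep_ratio`, e.g.
   keep 5% of edges), snap landmarks back onto the coarse body, stamp a
   normal-aligned cylindrical cutter through the surface at every landmark,
   open the face and neck margins, and extrude every remaining edge into a
   round strut of the chosen wire thickness. The strut union is re-tessellated
   through a signed-distance voxelization into a single watertight solid.
4. **Verify** — `diagnose()` counts non-manifold edges, boundary edges,
   degenerate faces, duplicate vertices, self-intersections and orientation
   defects; a cap is printable only when all are zero and the volume is
   positive. `validate_cap_landmarks()` recovers the grommet-hole centroids,
   radially projects them onto the head, and compares their geodesic
   distances along the sagittal (from Iz) and coronal (from RPA) reference
   curves with the landmark ground truth.

Sphere and ellipsoid phantoms with analytically known landmarks are built in
(`make_sphere()`, `make_ellipsoid()`, `make_voxel_ball()`), so the whole
pipeline is testable against closed-form geometry.

## Worked example

```r
library(capforge)

ph  <- make_sphere(100, density = 5)                # R = 100 mm head phantom
lmk <- compute_landmarks(ph$mesh, ph$fiducials, "10-10")
lmk
#> <landmark_set> 10-10, 61 labels (Cz converged in 2 iterations)

round(lmk$positions["Cz", ], 6)
#>  x  y  z
#>  0  0 100                                          # the true vertex

circumference(ph$mesh, lmk)                         # 10% ring (Fpz-T7-Oz)
#> [1] 597.4714                                      # 2*pi*100*cos(18 deg) = 597.6

body    <- coarsen(ph$mesh, keep_ratio = 0.05)
reg     <- register_landmarks(lmk, body)
cutters <- place_grommets(body, reg, grommet_spec(radius = 4))
cap     <- cut_grommet_holes(body, cutters) |>
  cut_margins(ph$fiducials, cap_params()) |>
  thicken_margin(10)
solid   <- wireframe(cap, wire_thickness = 2.5)

is_printable(diagnose(solid))
#> [1] TRUE

validate_cap_landmarks(ph$mesh, reg, cap)
#> <validation_report> 17 pairs, R^2 = 1.00000, error 0.124 +/- 0.088 mm
```

The validation report means: across the 17 sagittal/coronal-row landmarks,
the grommet holes cut into the cap reproduce the ground-truth geodesic
landmark distances to about a tenth of a millimeter on a 100 mm-radius head.

A command-line front end with the same stages lives at
`inst/cli/capforge.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","capforge.R",package="capforge"))') \
    phantom --kind sphere --radius 100 --out head.stl
```

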