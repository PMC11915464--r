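test_that("dual meshes swap faces and vertices", {
  tet <- tetra_mesh()
  dt <- dual_mesh(tet)
  expect_s3_class(dt, "polymesh")
  expect_equal(nrow(dt$vertices), 4)            # one per input face
  expect_equal(length(dt$faces), 4)             # one per input vertex
  expect_true(all(vapply(dt$faces, length, 1L) == 3L))  # tetrahedron self-dual
  ico <- capforge:::icosahedron()
  di <- dual_mesh(ico)
  expect_equal(nrow(di$vertices), 20)
  expect_equal(length(di$faces), 12)
  expect_true(all(vapply(di$faces, length, 1L) == 5L))  # dodecahedron
  open_mesh <- trimesh(tet$vertices, tet$faces[-1, ])
  expect_error(dual_mesh(open_mesh), "closed")
})

test_that("coarsening respects keep_ratio and stays close to the surface", {
  ph <- sphere100()
  expect_identical(coarsen(ph$mesh, 1), ph$mesh)
  body <- cap_build()$body
  e0 <- nrow(mesh_edges(ph$mesh))
  expect_lte(nrow(mesh_edges(body)), ceiling(0.05 * e0))
  expect_true(mesh_is_closed(body))
  expect_lt(attr(body, "hausdorff"), 0.02 * 100)
  expect_error(coarsen(ph$mesh, 0), "keep_ratio")
})

test_that("landmark registration snaps onto the target surface", {
  b <- cap_build()
  # landmarks from the fine mesh land within 2% of R on the coarse body
  expect_lt(max(b$registered$snap_dist), 0.02 * 100)
  # registration is idempotent
  again <- register_landmarks(b$registered, b$body)
  expect_lt(max(again$snap_dist), 1e-9)
  # an off-surface point along the normal projects straight back
  lm1 <- b$registered
  n <- capforge:::surface_normal_at(b$body, lm1$positions[1, ])
  lm1$positions[1, ] <- lm1$positions[1, ] + 1 * n
  back <- register_landmarks(lm1, b$body)
  expect_lt(abs(back$snap_dist[1] - 1), 0.05)
  expect_lt(sqrt(sum((back$positions[1, ] - b$registered$positions[1, ])^2)),
            0.05)
})

test_that("grommet cutters align with outward surface normals", {
  b <- cap_build()
  P <- b$registered$positions
  axes <- t(vapply(b$cutters, function(ct) attr(ct, "axis"), numeric(3)))
  true_n <- P / sqrt(rowSums(P^2))           # analytic sphere normals
  ang <- acos(pmin(1, rowSums(axes * true_n)))
  expect_lt(max(ang) * 180 / pi, 2)
  expect_equal(length(b$cutters), nrow(P))
  for (ct in b$cutters[1:3]) {
    expect_true(mesh_is_closed(ct))
    expect_gt(mesh_volume(ct), 0)
  }
  expect_equal(attr(b$cutters[[1]], "radius"), 4)
})

test_that("hole cutting adds one boundary loop per cutter near its landmark", {
  b <- cap_build()
  expect_equal(length(mesh_boundary_loops(b$holed)),
               length(b$cutters))             # closed sphere gains N loops
  loops <- mesh_boundary_loops(b$holed)
  cents <- t(vapply(loops, function(lp)
    colMeans(b$holed$vertices[lp, , drop = FALSE]), numeric(3)))
  d <- vapply(seq_len(nrow(cents)), function(i)
    min(sqrt(rowSums((b$registered$positions -
                      matrix(cents[i, ], nrow(b$registered$positions), 3,
                             byrow = TRUE))^2))), numeric(1))
  expect_lt(max(d), 4 / 2)                    # within radius/2 of a landmark
  # empty cutter list is the identity
  expect_identical(cut_grommet_holes(b$body, list()), b$body)
})

test_that("a 10-20 montage cuts exactly 21 grommet holes", {
  ph <- sphere_small()
  lmk <- compute_landmarks(ph$mesh, ph$fiducials, "10-20")
  expect_equal(nrow(lmk$positions), 21)
  body <- coarsen(ph$mesh, 0.05)
  reg <- register_landmarks(lmk, body)
  cutters <- place_grommets(body, reg, grommet_spec(radius = 4))
  holed <- cut_grommet_holes(body, cutters)
  expect_equal(length(mesh_boundary_loops(holed)), 21)
})

test_that("margin cuts open the face and neck while keeping the vertex", {
  b <- cap_build()
  ph <- b$phantom
  frame <- canonical_frame(ph$fiducials)
  local <- frame$to_frame(b$cap$vertices)
  pre <- frame$to_frame(b$holed$vertices)        # extent of the cut input
  zmin <- min(pre[, 3]); height <- diff(range(pre[, 3]))
  # neck rule: outside the face box everything sits above the neck plane
  expect_gte(min(local[, 3]), zmin + height / 3 - 1e-6)
  # Nz itself is inside the face opening
  d_nz <- mesh_nearest_point(rbind(ph$fiducials$nz), b$cap)$dist
  expect_gt(d_nz, 5)
  # all landmarks except the lowest (10%) ring survive the default cuts
  ring <- c(capforge:::ring_left_1010$label,
            capforge:::mirror_label(capforge:::ring_left_1010$label), "Fpz", "Oz")
  keep <- setdiff(rownames(b$registered$positions), ring)
  d <- mesh_nearest_point(b$registered$positions[keep, ], b$cap)$dist
  expect_lt(max(d), 4)                        # at most a grommet radius away
  # pathological cut fractions are rejected
  expect_error(cut_margins(b$holed, ph$fiducials,
                           cap_params(neck_height_fraction = 0.95)),
               "vertex|60%")
})

test_that("margin thickening tags exactly the edges near exterior rims", {
  b <- cap_build()
  cap0 <- thicken_margin(b$cap, 0)
  expect_false(any(attr(cap0, "margin_tags")))
  cap10 <- thicken_margin(b$cap, 10)
  tags <- attr(cap10, "margin_tags")
  expect_gt(sum(tags), 0)
  # brute-force check on a subsample of edges
  loops <- mesh_boundary_loops(b$cap)
  len <- vapply(loops, function(lp) {
    p <- b$cap$vertices[lp, , drop = FALSE]
    q <- b$cap$vertices[c(lp[-1], lp[1]), , drop = FALSE]
    sum(sqrt(rowSums((p - q)^2)))
  }, numeric(1))
  margin_pts <- do.call(rbind, lapply(loops[len >= 60], function(lp)
    b$cap$vertices[lp, , drop = FALSE]))
  edges <- mesh_edges(b$cap)
  idx <- seq(1, nrow(edges), by = 23)
  for (i in idx) {
    d <- min(sqrt(rowSums((margin_pts -
            matrix(b$cap$vertices[edges[i, 1], ], nrow(margin_pts), 3,
                   byrow = TRUE))^2)),
             sqrt(rowSums((margin_pts -
            matrix(b$cap$vertices[edges[i, 2], ], nrow(margin_pts), 3,
                   byrow = TRUE))^2)))
    # vertex-to-polyline distance is bounded by vertex-to-vertex distance;
    # only assert the unambiguous cases
    if (d <= 10) expect_true(tags[i])
  }
  expect_error(thicken_margin(sphere_small()$mesh, 10), "closed")
})

test_that("wireframe struts have the right volume and stay inside the bbox", {
  # single 10 mm edge, 2 mm thickness: solid close to l * t^2 (round section)
  seg <- trimesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 0, 0.001)),
                 rbind(c(1, 2, 3)))
  solid <- capforge:::solidify_capsules(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)),
                                        1, 0.25)
  expect_true(mesh_is_closed(solid))
  vol <- mesh_volume(solid)
  expect_lt(abs(vol - 10 * 2^2) / (10 * 2^2), 0.25)
  bb <- mesh_bbox(solid)
  expect_gte(min(bb[1, ] - (c(0, 0, 0) - 2)), -0.6)
  expect_lte(max(bb[2, ] - (c(10, 0, 0) + 2)), 0.6)
})

test_that("wireframe guards reject over-thick wires", {
  b <- cap_build()
  expect_error(wireframe(b$cap, wire_thickness = 6, pitch = 1.5),
               "keep_ratio|range")
})
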