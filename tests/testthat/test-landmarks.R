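test_that("cross-sections of the unit sphere recover great circles", {
  m <- unit_sphere()$mesh
  cs <- cross_section(m, c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_true(cs$closed)
  expect_lt(abs(cs$length - 2 * pi) / (2 * pi), 0.005)
  expect_error(cross_section(m, c(0, 0, 2.5), c(1, 0, 2), c(0, 1, 2)),
               "not intersect")
  expect_error(cross_section(m, c(1, 0, 0), c(0.5, 0, 0), c(-1, 0, 0)),
               "collinear")
})

test_that("multi-loop sections pick the loop nearest the anchors", {
  # two stacked spheres; the z = 0.9 plane cuts both
  s1 <- make_sphere(1, density = 3)$mesh
  s2 <- mesh_transform(make_sphere(1, density = 3)$mesh,
                       translation = c(0, 0, 1.8))
  both <- trimesh(rbind(s1$vertices, s2$vertices),
                  rbind(s1$faces, s2$faces + nrow(s1$vertices)))
  r <- sqrt(1 - 0.9^2)
  cs_low <- cross_section(both, c(r, 0, 0.9), c(0, r, 0.9), c(-r, 0, 0.9))
  expect_lt(max(abs(sqrt(rowSums(cs_low$points[, 1:2]^2)) - r)), 0.05)
  expect_lt(max(abs(cs_low$points[, 3] - 0.9)), 0.05)
  hi <- 1.8 - 0.9
  cs_hi <- cross_section(both, c(r, 0, hi + 0.002), c(0, r, hi), c(-r, 0, hi))
  expect_gt(min(cs_hi$points[, 3]), 0.5)
})

test_that("arcs partition loops and respect the via point", {
  m <- unit_sphere()$mesh
  eq <- cross_section(m, c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  a <- c(1, 0, 0); b <- c(-1, 0, 0)
  arc1 <- arc_on_loop(eq, a, b, via = c(0, 1, 0))
  arc2 <- arc_on_loop(eq, a, b, via = c(0, -1, 0))
  expect_lt(abs(arc1$length - pi) / pi, 0.005)
  expect_equal(arc1$length + arc2$length, eq$length, tolerance = 1e-9)
  expect_error(arc_on_loop(eq, a, a, via = c(0, 1, 0)), "coincide")
  expect_error(arc_on_loop(eq, a, b, via = c(0, 0, 4)), "from the loop")
})

test_that("point_at_fraction matches an independent cumulative scan", {
  # endpoints
  arc <- surface_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(point_at_fraction(arc, 0), c(0, 0, 0))
  expect_equal(point_at_fraction(arc, 1), c(1, 1, 0))
  expect_error(point_at_fraction(arc, 1.2), "\\[0, 1\\]")
  # symmetry on a semicircle
  th <- seq(0, pi, length.out = 401)
  semi <- surface_curve(cbind(cos(th), sin(th), 0))
  expect_equal(point_at_fraction(semi, 0.5), c(0, 1, 0), tolerance = 1e-4)
  # brute-force linear scan oracle on a fixed irregular polyline
  set.seed(42)
  pts <- cbind(cumsum(runif(100)), cumsum(rnorm(100)), cumsum(rnorm(100)))
  crv <- surface_curve(pts)
  t <- 0.3
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  target <- t * sum(seg)
  i <- max(which(cum <= target))
  u <- (target - cum[i]) / seg[i]
  oracle <- pts[i, ] + u * (pts[i + 1, ] - pts[i, ])
  expect_equal(point_at_fraction(crv, t), oracle, tolerance = 1e-12)
})

test_that("Cz refinement converges to the pole and bisects both arcs", {
  ph <- sphere100()   # Cz0 displaced 20 degrees
  rc <- refine_cz(ph$mesh, ph$fiducials)
  expect_lt(rc$iterations, 50)
  expect_lt(sqrt(sum((rc$cz - c(0, 0, 100))^2)), 1e-3 * 100)
  # bisection residuals, sagittal and coronal
  for (arc in list(rc$sagittal_arc, rc$coronal_arc)) {
    pr <- capforge:::curve_project(arc, rc$cz)
    expect_lt(abs(pr$s - arc$length / 2) / arc$length, 1e-4)
  }
  # a 30-degree initial displacement also converges
  ph30 <- make_sphere(100, density = 4, cz0_offset_deg = 30)
  rc30 <- refine_cz(ph30$mesh, ph30$fiducials)
  expect_lt(rc30$iterations, 50)
  expect_lt(sqrt(sum((rc30$cz - c(0, 0, 100))^2)), 1e-3 * 100)
})

test_that("10-10 sagittal and coronal rows match closed-form positions", {
  ph <- sphere100()
  lmk <- landmarks100()
  al <- ph$analytic_landmarks
  rows <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz",
            "T7", "C5", "C3", "C1", "C2", "C4", "C6", "T8")
  err <- sqrt(rowSums((lmk$positions[rows, ] - al[rows, ])^2))
  expect_lt(max(err), 0.5)
  # the validated label set: sagittal row plus C5..C6 between T7/T8
  expect_true(all(c("C5", "C3", "C1", "C2", "C4", "C6") %in%
                  rownames(lmk$positions)))
})

test_that("montage systems nest with identical shared positions", {
  ph <- sphere_small()
  l20 <- compute_landmarks(ph$mesh, ph$fiducials, "10-20")
  l10 <- compute_landmarks(ph$mesh, ph$fiducials, "10-10")
  l05 <- compute_landmarks(ph$mesh, ph$fiducials, "10-5")
  expect_true(all(rownames(l20$positions) %in% rownames(l10$positions)))
  expect_true(all(rownames(l10$positions) %in% rownames(l05$positions)))
  expect_gt(nrow(l05$positions), nrow(l10$positions))
  expect_equal(l20$positions,
               l10$positions[rownames(l20$positions), ], tolerance = 1e-12)
  expect_equal(l10$positions,
               l05$positions[rownames(l10$positions), ], tolerance = 1e-12)
})

test_that("landmark positions lie on the mesh surface", {
  lmk <- landmarks100()
  d <- mesh_nearest_point(lmk$positions, sphere100()$mesh)$dist
  expect_lt(max(d), 1e-6 * 100)
})

test_that("mirroring the head mirrors the landmarks with L/R labels swapped", {
  ph <- sphere_small()
  l <- compute_landmarks(ph$mesh, ph$fiducials, "10-10")
  M <- diag(c(1, -1, 1))                     # swap left/right
  mmesh <- mesh_transform(ph$mesh, M)
  mfid <- fiducials(nz = ph$fiducials$nz, iz = ph$fiducials$iz,
                    lpa = M %*% ph$fiducials$rpa, rpa = M %*% ph$fiducials$lpa,
                    cz0 = M %*% ph$fiducials$cz0)
  lm <- compute_landmarks(mmesh, mfid, "10-10")
  swapped <- capforge:::mirror_label(rownames(l$positions))
  mirrored <- l$positions %*% M
  rownames(mirrored) <- swapped
  err <- sqrt(rowSums((lm$positions[swapped, ] - mirrored[swapped, ])^2))
  expect_lt(max(err), 1e-6 * 100)
})

test_that("landmark meshes are label-preserving manifold triangulations", {
  lmk <- landmarks100()
  lmesh <- landmark_mesh(lmk)
  expect_equal(nrow(lmesh$vertices), nrow(lmk$positions))
  expect_equal(attr(lmesh, "labels"), rownames(lmk$positions))
  # every landmark used by at least one triangle
  expect_equal(sort(unique(as.vector(lmesh$faces))),
               seq_len(nrow(lmk$positions)))
  # edge-manifold with a single boundary loop (the cap rim)
  counts <- capforge:::edge_incidence_counts(lmesh)
  expect_true(all(counts <= 2))
  expect_equal(length(mesh_boundary_loops(lmesh)), 1)
  few <- lmk; few$positions <- lmk$positions[1:3, ]
  expect_error(landmark_mesh(few), "at least 4")
})
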