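test_that("sphere circumference matches the 10% ring closed form", {
  ph <- sphere100()
  lmk <- landmarks100()
  circ <- circumference(ph$mesh, lmk)
  ref <- 2 * pi * 100 * cos(0.1 * pi)
  expect_lt(abs(circ - ref) / ref, 0.005)
  # linear under scaling
  big <- mesh_transform(ph$mesh, diag(3) * 1.1)
  lmk_big <- lmk
  lmk_big$positions <- lmk$positions * 1.1
  lmk_big$fiducials <- capforge:::transform_fiducials(ph$fiducials, diag(3) * 1.1)
  expect_equal(circumference(big, lmk_big) / circ, 1.1, tolerance = 1e-9)
  # collinear anchors have no defining plane
  degenerate <- lmk
  degenerate$positions["T7", ] <- (degenerate$positions["Fpz", ] +
                                   degenerate$positions["Oz", ]) / 2
  expect_error(circumference(ph$mesh, degenerate), "collinear")
})

test_that("scale_to_circumference hits the target and commutes", {
  ph <- sphere100()
  lmk <- landmarks100()
  cur <- circumference(ph$mesh, lmk)
  same <- scale_to_circumference(ph$mesh, lmk, cur)
  expect_equal(attr(same, "scale"), 1, tolerance = 1e-12)
  scaled <- scale_to_circumference(ph$mesh, lmk, 620)
  r_expect <- 620 / (2 * pi * cos(0.1 * pi))
  r_got <- mean(sqrt(rowSums(scaled$vertices^2)))
  expect_lt(abs(r_got - r_expect) / r_expect, 0.005)
  # recomputing landmarks on the scaled head commutes with scaling
  s <- attr(scaled, "scale")
  fid_s <- capforge:::transform_fiducials(ph$fiducials, diag(3) * s)
  lmk_s <- compute_landmarks(scaled, fid_s, "10-10")
  expect_equal(lmk_s$positions, lmk$positions * s, tolerance = 1e-6 * 100)
  expect_lt(abs(circumference(scaled, lmk_s) - 620) / 620, 0.001)
})

test_that("geodesic row distances follow the montage fractions", {
  ph <- sphere100()
  lmk <- landmarks100()
  sag <- geodesic_landmark_distances(ph$mesh, lmk, "sagittal")
  # Oz sits 10% of the half-circumference from Iz
  expect_equal(unname(sag["Oz"]), 0.1 * pi * 100, tolerance = 0.5)
  # Cz bisects the arc exactly
  expect_equal(unname(sag["Cz"]), 0.5 * pi * 100, tolerance = 0.5)
  # distances increase monotonically along the row away from the origin
  row <- c("Oz", "POz", "Pz", "CPz", "Cz", "FCz", "Fz", "AFz", "Fpz")
  expect_true(all(diff(sag[row]) > 0))
  cor <- geodesic_landmark_distances(ph$mesh, lmk, "coronal")
  expect_equal(unname(cor["Cz"]), 0.5 * pi * 100, tolerance = 0.5)
  expect_error(geodesic_landmark_distances(ph$mesh, lmk, "sagittal",
                                           origin_label = "T7"),
               "from the curve")
})

test_that("radial projection maps between concentric surfaces exactly", {
  inner <- make_sphere(100, density = 4)$mesh
  outer <- make_sphere(103, density = 4)$mesh
  pts <- inner$vertices[c(1, 17, 333, 1201), ]
  proj <- radial_project(pts, c(0, 0, 0), outer)
  expect_equal(proj, pts * 1.03, tolerance = 1e-6 * 100)
  # projecting a surface point onto its own mesh is (nearly) the identity
  self_proj <- radial_project(pts, c(0, 0, 0), inner)
  expect_lt(max(abs(self_proj - pts)), 1e-6 * 100)
  # misses are reported with labels
  labeled <- rbind(up = c(0, 0, 1))
  halfspace <- trimesh(rbind(c(-1, -1, -5), c(1, 0, -5), c(0, 1, -5)),
                       rbind(c(1, 2, 3)))
  expect_error(radial_project(labeled, c(0, 0, 0), halfspace), "up")
})

test_that("radial projection agrees with brute-force ray marching", {
  pe <- ellipsoid_std()
  pts <- rbind(c(30, 20, 50), c(-10, 40, 30), c(5, -25, 60))
  proj <- radial_project(pts, c(0, 0, 0), pe$mesh)
  for (i in seq_len(nrow(pts))) {
    dir <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    # march until the implicit ellipsoid function changes sign, then bisect
    fun <- function(t) sum(((t * dir) / c(100, 80, 90))^2) - 1
    t_hi <- 10
    while (fun(t_hi) < 0) t_hi <- t_hi * 2
    t_star <- stats::uniroot(fun, c(1e-6, t_hi), tol = 1e-12)$root
    expect_lt(sqrt(sum((proj[i, ] - t_star * dir)^2)), 0.05)
  }
})

test_that("landmark error statistics match hand-computed values", {
  ref <- c(a = 10, b = 20, c = 30, d = 40, e = 50)
  # identical distances: perfect fit
  st <- landmark_error_stats(ref, ref)
  expect_equal(st$r_squared, 1)
  expect_equal(st$mean_error, 0)
  expect_equal(st$sd_error, 0)
  # constant offset: mean = offset, sd = 0, correlation still perfect
  st2 <- landmark_error_stats(ref, ref + 1)
  expect_equal(st2$mean_error, 1)
  expect_equal(st2$sd_error, 0)
  expect_equal(st2$r_squared, 1)
  # hand-checkable 5-pair table
  mea <- c(a = 11, b = 19, c = 31, d = 39, e = 51)
  st3 <- landmark_error_stats(ref, mea)
  expect_equal(st3$mean_error, 1)
  expect_equal(st3$sd_error, 0)
  fit <- stats::lm(mea ~ ref)
  expect_equal(st3$r_squared, summary(fit)$r.squared)
  expect_error(landmark_error_stats(ref[1:2], mea[1:2]), "at least 3")
})
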