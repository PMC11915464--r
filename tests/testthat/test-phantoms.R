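test_that("icosphere phantoms are closed, accurate and carry exact fiducials", {
  ph <- unit_sphere()
  expect_true(mesh_is_closed(ph$mesh))
  expect_equal(mesh_euler(ph$mesh), 2)
  # area converges to 4*pi (inscribed polyhedron, slightly below)
  expect_lt(abs(mesh_area(ph$mesh) - 4 * pi) / (4 * pi), 0.002)
  expect_equal(ph$analytic_landmarks["Cz", ], c(0, 0, 1), tolerance = 1e-12)
  ph100 <- sphere100()
  expect_equal(unname(ph100$analytic_landmarks["Fpz", ]),
               100 * c(cos(0.1 * pi), 0, sin(0.1 * pi)), tolerance = 1e-12)
  # all fiducials lie on the sphere
  for (p in unclass(ph100$fiducials))
    expect_equal(sqrt(sum(p^2)), 100, tolerance = 1e-9)
})

test_that("phantom guards reject bad parameters", {
  expect_error(make_sphere(-1), "positive")
  expect_error(make_sphere(1, density = 9), "guard")
  expect_error(make_ellipsoid(1, 0, 1), "positive")
})

test_that("unit-axis ellipsoid degenerates to the unit sphere contract", {
  pe <- make_ellipsoid(1, 1, 1, density = 3)
  ps <- make_sphere(1, density = 3)
  expect_equal(pe$mesh$vertices, ps$mesh$vertices, tolerance = 1e-12)
  expect_equal(unclass(pe$fiducials), unclass(ps$fiducials), tolerance = 1e-12)
})

test_that("ellipsoid sagittal section length matches elliptic quadrature", {
  pe <- ellipsoid_std()
  cs <- cross_section(pe$mesh, pe$fiducials$nz, pe$fiducials$iz, c(0, 0, 90))
  # perimeter of the x-z ellipse with semi-axes (100, 90) by quadrature
  th <- seq(0, 2 * pi, length.out = 200001)
  per <- sum(sqrt((100 * diff(cos(th)))^2 + (90 * diff(sin(th)))^2))
  expect_lt(abs(cs$length - per) / per, 0.002)
})

test_that("ellipsoid mesh is mirror-symmetric in the sagittal plane", {
  pe <- make_ellipsoid(100, 80, 90, density = 3)
  mir <- mesh_transform(pe$mesh, diag(c(1, -1, 1)))
  d <- mesh_nearest_point(mir$vertices, pe$mesh)$dist
  expect_lt(max(d), 1e-9 * 100)
})

test_that("voxel balls have the right volume and reject boundary contact", {
  vol <- make_voxel_ball(20, grid = c(64, 64, 64))
  count <- sum(vol$array)
  expect_lt(abs(count - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.01)
  expect_error(make_voxel_ball(40, grid = c(64, 64, 64)), "boundary")
  # empty ball produces an all-background volume
  expect_equal(sum(make_voxel_ball(0)$array), 0)
  # two disjoint balls occupy two components
  two <- make_voxel_ball(c(10, 6), grid = c(64, 64, 64),
                         centers = rbind(c(20, 32, 32), c(50, 32, 32)))
  lab <- capforge:::cpp_label_components(as.logical(two$array != 0), dim(two$array), 6L)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
})

test_that("the dense-sampling oracle reproduces closed-form sphere landmarks", {
  ph <- sphere_small()
  o <- oracle_landmarks(ph, "10-10", n_dense = 2e4)
  shared <- intersect(rownames(o), rownames(ph$analytic_landmarks))
  err <- sqrt(rowSums((o[shared, ] - ph$analytic_landmarks[shared, ])^2))
  expect_lt(max(err), 1e-3 * 100)
})

test_that("oracle landmarks converge under sampling refinement", {
  pe <- make_ellipsoid(100, 80, 90, density = 3)
  o1 <- oracle_landmarks(pe, "10-10", n_dense = 1e4)
  o2 <- oracle_landmarks(pe, "10-10", n_dense = 1e5)
  shared <- intersect(rownames(o1), rownames(o2))
  expect_lt(max(sqrt(rowSums((o1[shared, ] - o2[shared, ])^2))), 1e-4 * 100)
})

test_that("oracle montage systems nest: 10-20 inside 10-10", {
  ph <- sphere_small()
  o20 <- oracle_landmarks(ph, "10-20", n_dense = 1e4)
  o10 <- oracle_landmarks(ph, "10-10", n_dense = 1e4)
  expect_true(all(rownames(o20) %in% rownames(o10)))
  expect_equal(o20, o10[rownames(o20), ], tolerance = 1e-12)
  expect_error(oracle_landmarks(ph, "10-10", n_dense = 100), ">= 1e4")
})
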