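test_that("a voxel ball extracts to a closed genus-0 sphere of the right size", {
  vol <- make_voxel_ball(20, grid = c(64, 64, 64), voxel_size = 1)
  mesh <- extract_head_surface(vol, extraction_params(max_circumradius = 2))
  expect_true(mesh_is_closed(mesh))
  expect_equal(mesh_euler(mesh), 2)
  ref_v <- 4 / 3 * pi * 20^3
  ref_a <- 4 * pi * 20^2
  expect_lt(abs(mesh_volume(mesh) - ref_v) / ref_v, 0.05)
  expect_lt(abs(mesh_area(mesh) - ref_a) / ref_a, 0.03)
  expect_lte(max(mesh_circumradii(mesh)), 2)
})

test_that("the circumradius bound triggers subdivision when tightened", {
  vol <- make_voxel_ball(10, grid = c(32, 32, 32), voxel_size = 1)
  coarse <- extract_head_surface(vol, extraction_params(max_circumradius = 2))
  fine <- extract_head_surface(vol, extraction_params(max_circumradius = 0.4))
  expect_lte(max(mesh_circumradii(fine)), 0.4)
  expect_gt(nrow(fine$faces), nrow(coarse$faces))
  expect_true(mesh_is_closed(fine))
})

test_that("only the largest component survives; cavities are filled", {
  two <- make_voxel_ball(c(12, 6), grid = c(64, 64, 64),
                         centers = rbind(c(22, 32, 32), c(50, 32, 32)))
  mesh <- extract_head_surface(two, extraction_params())
  # surface belongs to the r=12 ball at x ~ 21 (voxel 22, origin at 0)
  expect_lt(abs(mean(mesh$vertices[, 1]) - 21), 1)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3),
            0.05)
  # hollow ball: interior cavity is ignored (outer surface only)
  vol <- make_voxel_ball(15, grid = c(48, 48, 48))
  hole <- make_voxel_ball(7, grid = c(48, 48, 48))
  hollow <- volume_image(vol$array - hole$array, vol$voxel_size)
  hm <- extract_head_surface(hollow, extraction_params())
  expect_equal(mesh_euler(hm), 2)
  expect_lt(abs(mesh_volume(hm) - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3),
            0.05)
})

test_that("anisotropic voxel sizes give an isotropic surface in mm", {
  # a ball that is spherical in mm (radius 10) sampled on 1 x 1 x 2 mm voxels
  grid <- c(40, 40, 24)
  vs <- c(1, 1, 2)
  ctr <- (grid + 1) / 2 * vs
  mm <- function(ax) (seq_len(grid[ax]) - 1) * vs[ax]
  d2 <- outer(outer((mm(1) - ctr[1])^2, (mm(2) - ctr[2])^2, "+"),
              (mm(3) - ctr[3])^2, "+")
  vol <- volume_image(array(as.numeric(d2 <= 100), grid), voxel_size = vs)
  mesh <- extract_head_surface(vol, extraction_params())
  ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
  expect_equal(unname(ext[3] / ext[1]), 1, tolerance = 0.06)
})

test_that("degenerate volumes are rejected with clear errors", {
  empty <- make_voxel_ball(0, grid = c(16, 16, 16))
  expect_error(extract_head_surface(empty, extraction_params()), "empty")
  touching <- volume_image(array(1, c(8, 8, 8)))
  expect_error(extract_head_surface(touching, extraction_params()), "pad")
})

test_that("label maps select the requested label union", {
  vol <- make_voxel_ball(10, grid = c(40, 40, 40))
  lab <- vol$array * 3L                       # label value 3
  lab[15:25, 15:25, 15:25][lab[15:25, 15:25, 15:25] > 0] <- 5L
  lv <- volume_image(lab, c(1, 1, 1))
  m_all <- extract_head_surface(lv, extraction_params())
  m_sel <- extract_head_surface(lv, extraction_params(threshold = c(3L, 5L)))
  expect_equal(mesh_volume(m_sel), mesh_volume(m_all), tolerance = 1e-6)
})
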