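test_that("clean closed meshes diagnose as printable", {
  ph <- sphere_small()
  rep <- diagnose(ph$mesh)
  for (nm in setdiff(names(rep), "volume")) expect_equal(rep[[nm]], 0)
  expect_equal(rep$volume, 4 / 3 * pi * 100^3, tolerance = 0.01)
  expect_true(is_printable(rep))
})

test_that("constructed defects are counted", {
  # two identical stacked triangles: duplicate vertices + coplanar overlap
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- trimesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  rep <- diagnose(m)
  expect_equal(rep$duplicate_vertices, 3)
  expect_gt(rep$self_intersections, 0)
  # zero-area face
  z <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(diagnose(z)$zero_area_faces, 1)
  # cube with one (quad) face removed: 4 boundary edges remain
  cm <- cube_mesh()
  open_cube <- trimesh(cm$vertices, cm$faces[-c(1, 2), ])
  expect_equal(diagnose(open_cube, check_self_intersections = FALSE)$boundary_edges, 4)
  # flipped face shows up as an orientation defect
  flip <- cm$faces
  flip[1, ] <- flip[1, c(1, 3, 2)]
  expect_gt(diagnose(trimesh(cm$vertices, flip))$inverted_faces, 0)
})

test_that("weld merges within tolerance and is idempotent", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-7, 0, 0))
  m <- trimesh(v, rbind(c(1, 2, 3), c(4, 1, 2)))
  w0 <- weld(m, tolerance = 0)
  expect_equal(nrow(w0$vertices), 4)          # bitwise distinct: no merge
  w <- weld(m, tolerance = 1e-6)
  expect_equal(nrow(w$vertices), 3)
  expect_equal(nrow(w$faces), 1)              # second face degenerated away
  w2 <- weld(w, tolerance = 1e-6)
  expect_equal(w2$vertices, w$vertices)
  expect_equal(w2$faces, w$faces)
  expect_error(weld(m, tolerance = 2, feature_size = 1.25), "refused")
})

test_that("STL per-facet vertices weld down to the OFF twin's count", {
  m <- sphere_small()$mesh
  p1 <- tempfile(fileext = ".stl"); p2 <- tempfile(fileext = ".off")
  write_mesh(m, p1); write_mesh(m, p2)
  s <- weld(read_mesh(p1), tolerance = 1e-6)
  o <- read_mesh(p2)
  expect_equal(nrow(s$vertices), nrow(o$vertices))
  unlink(c(p1, p2))
})

test_that("repair restores watertightness and is idempotent", {
  ph <- sphere_small()
  clean <- repair(ph$mesh)
  expect_equal(nrow(clean$faces), nrow(ph$mesh$faces))
  expect_equal(mesh_volume(clean), mesh_volume(ph$mesh), tolerance = 1e-9)
  # three adjacent deleted faces -> hole filled, volume nearly unchanged
  f <- ph$mesh$faces
  v1 <- f[1, 1]
  adjacent <- which(rowSums(matrix(f %in% f[1, ], ncol = 3)) >= 2)[1:3]
  holed <- trimesh(ph$mesh$vertices, f[-adjacent, ])
  fixed <- repair(holed)
  expect_true(is_printable(diagnose(fixed)))
  expect_lt(abs(mesh_volume(fixed) - mesh_volume(ph$mesh)) /
            mesh_volume(ph$mesh), 0.001)
  # inside-out sphere is reoriented to positive volume
  inverted <- trimesh(ph$mesh$vertices, f[, c(1, 3, 2)])
  expect_lt(mesh_volume(inverted), 0)
  expect_gt(mesh_volume(repair(inverted)), 0)
  # idempotence on all repaired fixtures
  for (m in list(clean, fixed)) {
    again <- repair(m)
    expect_equal(again$vertices, m$vertices)
    expect_equal(nrow(again$faces), nrow(m$faces))
  }
  # large design openings abort rather than being sealed
  cap <- cap_build()$cap
  expect_error(repair(cap), "design openings")
})

test_that("remesh_solidify fuses crossing struts into one watertight solid", {
  c1 <- capforge:::cylinder_mesh(c(0, 0, 0), c(1, 0, 0), 1.25, 20, 32)
  c2 <- capforge:::cylinder_mesh(c(0, 0, 0), c(0, 1, 0), 1.25, 20, 32)
  soup <- trimesh(rbind(c1$vertices, c2$vertices),
                  rbind(c1$faces, c2$faces + nrow(c1$vertices)),
                  validate = FALSE)
  expect_gt(diagnose(soup)$self_intersections, 0)   # the input really crosses
  rs <- remesh_solidify(soup, 0.3)
  expect_true(is_printable(diagnose(rs)))
  # single connected component
  e <- mesh_edges(rs)
  parent <- seq_len(nrow(rs$vertices))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(e))) {
    a <- find(e[i, 1]); b <- find(e[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  expect_equal(length(unique(vapply(seq_along(parent), find, 1L))), 1L)
})

test_that("remesh_solidify reproduces a cylinder's volume within 10%", {
  cyl <- capforge:::cylinder_mesh(c(0, 0, 0), c(0, 0, 1), 2, 20, 48)
  rs <- remesh_solidify(cyl, 0.4)
  expect_true(is_printable(diagnose(rs)))
  expect_lt(abs(mesh_volume(rs) - pi * 4 * 20) / (pi * 4 * 20), 0.1)
  expect_error(remesh_solidify(cyl, 5), "coarse")
})
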