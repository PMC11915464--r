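test_that("all four mesh formats round-trip a tetrahedron", {
  m <- tetra_mesh()
  for (fmt in c("stl", "off", "obj", "jmesh")) {
    path <- tempfile(fileext = paste0(".", if (fmt == "jmesh") "jmsh" else fmt))
    write_mesh(m, path, format = fmt)
    back <- read_mesh(path, format = fmt)
    expect_same_geometry(m, back)
    expect_equal(abs(mesh_volume(back)), abs(mesh_volume(m)), tolerance = 1e-6)
    unlink(path)
  }
})

test_that("round trips preserve topology and geometry to 1e-6 relative", {
  m <- sphere_small()$mesh
  for (fmt in c("stl", "off", "obj", "jmesh")) {
    path <- tempfile(fileext = ".dat")
    write_mesh(m, path, format = fmt)
    back <- read_mesh(path, format = fmt)
    expect_equal(nrow(back$faces), nrow(m$faces))
    expect_equal(nrow(back$vertices), nrow(m$vertices))
    expect_true(mesh_is_closed(back))
    expect_lt(abs(mesh_volume(back) - mesh_volume(m)) / mesh_volume(m), 1e-6)
    unlink(path)
  }
})

test_that("ASCII and binary STL agree; zero normals are recomputed", {
  m <- tetra_mesh()
  pb <- tempfile(fileext = ".stl"); pa <- tempfile(fileext = ".stl")
  write_mesh(m, pb, binary = TRUE)
  write_mesh(m, pa, binary = FALSE)
  expect_same_geometry(read_mesh(pb), read_mesh(pa))
  # hand-write a binary STL with an all-zero normal: accepted on read
  con <- file(pb, "wb")
  writeBin(charToRaw(sprintf("%-80s", "zero-normal fixture")), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0)), con, size = 4,
           endian = "little")
  writeBin(as.raw(c(0, 0)), con)
  close(con)
  one <- read_mesh(pb)
  expect_equal(nrow(one$faces), 1)
  n <- mesh_face_normals(one)
  expect_equal(sqrt(sum(n^2)), 1, tolerance = 1e-6)
  unlink(c(pa, pb))
})

test_that("a cube writes 12 binary STL facets and empty meshes are refused", {
  path <- tempfile(fileext = ".stl")
  write_mesh(cube_mesh(), path)
  con <- file(path, "rb")
  invisible(readBin(con, "raw", 80))
  expect_equal(readBin(con, "integer", 1, size = 4, endian = "little"), 12L)
  close(con)
  unlink(path)
  empty <- trimesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_mesh(empty, path), "empty")
})

test_that("JMesh and STL twins decode to the same mesh", {
  m <- tetra_mesh()
  p1 <- tempfile(fileext = ".stl"); p2 <- tempfile(fileext = ".jmsh")
  write_mesh(m, p1); write_mesh(m, p2)
  expect_same_geometry(read_mesh(p1), read_mesh(p2))
  unlink(c(p1, p2))
})

test_that("format sniffing and parse errors are informative", {
  p <- tempfile(fileext = ".xyz")
  writeLines("not a mesh", p)
  expect_error(read_mesh(p), "cannot infer")
  p2 <- tempfile(fileext = ".off")
  writeLines(c("NOT-OFF", "1 2 3"), p2)
  expect_error(read_mesh(p2), "OFF")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
  unlink(c(p, p2))
})

test_that("NIfTI volumes round-trip foreground counts and voxel sizes", {
  vol <- make_voxel_ball(10, grid = c(32, 32, 32), voxel_size = c(1, 1, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(sum(back$array != 0), sum(vol$array != 0))
  expect_equal(back$voxel_size, c(1, 1, 2), tolerance = 1e-6)
  unlink(path)
})

test_that("4D volumes are rejected with a clear error", {
  path <- tempfile(fileext = ".nii.gz")
  arr <- array(0, c(8, 8, 8, 3))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  expect_error(read_volume(path), "3D")
  unlink(path)
})
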