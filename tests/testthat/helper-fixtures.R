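# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

sphere100 <- function() fixture("sphere100", function() make_sphere(100, density = 5))
sphere_small <- function() fixture("sphere_small", function() make_sphere(100, density = 4))
unit_sphere <- function() fixture("unit_sphere", function() make_sphere(1, density = 5))
ellipsoid_std <- function() fixture("ellipsoid_std",
                                    function() make_ellipsoid(100, 80, 90, density = 5))

landmarks100 <- function() fixture("landmarks100", function()
  compute_landmarks(sphere100()$mesh, sphere100()$fiducials, "10-10"))

# full cap build on the sphere phantom (shared by the printability and
# metrology end-to-end checks)
cap_build <- function() fixture("cap_build", function() {
  ph <- sphere100()
  lmk <- landmarks100()
  body <- coarsen(ph$mesh, 0.05)
  reg <- register_landmarks(lmk, body)
  cutters <- place_grommets(body, reg, grommet_spec(radius = 4, cutter_depth = 20))
  holed <- cut_grommet_holes(body, cutters)
  cap <- cut_margins(holed, ph$fiducials, cap_params())
  cap <- thicken_margin(cap, 10)
  solid <- wireframe(cap, 2.5)
  list(phantom = ph, landmarks = lmk, body = body, registered = reg,
       cutters = cutters, holed = holed, cap = cap, solid = solid)
})

# simple closed tetrahedron for I/O round trips
tetra_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  trimesh(v, f)
}

expect_same_geometry <- function(m1, m2, tol = 1e-6) {
  expect_equal(nrow(m1$vertices), nrow(m2$vertices))
  expect_equal(nrow(m1$faces), nrow(m2$faces))
  # compare as vertex sets (index permutations allowed)
  o1 <- do.call(order, as.data.frame(round(m1$vertices, 9)))
  o2 <- do.call(order, as.data.frame(round(m2$vertices, 9)))
  scale <- max(1, max(abs(m1$vertices)))
  expect_lt(max(abs(m1$vertices[o1, ] - m2$vertices[o2, ])), tol * scale)
}
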