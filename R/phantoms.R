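#' Synthetic head phantoms
#'
#' Spheres, ellipsoids and voxelized balls with analytically known fiducials
#' (and, for spheres, closed-form landmark positions). These are the test
#' oracles for the whole pipeline: every other module is validated against
#' them. Canonical phantom frame: Nz on +x, RPA on +y, Cz on +z, units mm.
#'
#' @name phantoms
NULL

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  trimesh(v, f)
}

unit_icosphere <- function(density) {
  m <- icosahedron()
  for (i in seq_len(density)) {
    m <- mesh_subdivide(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m
}

phantom <- function(mesh, fid, analytic_landmarks = NULL, kind, params = list()) {
  structure(list(mesh = mesh, fiducials = fid,
                 analytic_landmarks = analytic_landmarks,
                 kind = kind, params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> %d vertices, %d faces\n", x$kind,
              nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  invisible(x)
}

#' Spherical head phantom
#'
#' Icosphere of the given radius with fiducials Nz = (R,0,0), Iz = (-R,0,0),
#' LPA = (0,-R,0), RPA = (0,R,0) and Cz0 deliberately displaced from the true
#' pole by a fixed rotation toward Nz (deterministic, so tests are exactly
#' reproducible). Analytic landmark positions for the sagittal row, coronal
#' row and the 10% ring come from closed-form great-circle subdivision.
#'
#' @param radius sphere radius (mm), > 0.
#' @param density icosphere subdivision level (0 = icosahedron); capped at 7.
#' @param cz0_offset_deg angular displacement of the initial vertex guess
#'   toward Nz, degrees (default 20, may be up to 30).
#' @return a `phantom` object.
#' @export
make_sphere <- function(radius, density = 4, cz0_offset_deg = 20) {
  if (radius <= 0) stop("radius must be positive")
  if (density < 0) stop("density must be >= 0")
  if (density > 7) stop("density > 7 would exceed the vertex-count guard")
  m <- unit_icosphere(density)
  m$vertices <- m$vertices * radius
  th <- cz0_offset_deg * pi / 180
  fid <- fiducials(nz = c(radius, 0, 0), iz = c(-radius, 0, 0),
                   lpa = c(0, -radius, 0), rpa = c(0, radius, 0),
                   cz0 = radius * c(sin(th), 0, cos(th)))
  phantom(m, fid, analytic_landmarks = sphere_analytic_landmarks(radius),
          kind = "sphere", params = list(radius = radius, density = density))
}

# closed-form sagittal/coronal/ring landmark positions on a sphere
sphere_analytic_landmarks <- function(R) {
  out <- list()
  sag <- sagittal_1010
  for (i in seq_len(nrow(sag))) {
    a <- sag$fraction[i] * pi               # polar angle from Nz in x-z plane
    out[[sag$label[i]]] <- R * c(cos(a), 0, sin(a))
  }
  cor <- coronal_1010
  for (i in seq_len(nrow(cor))) {
    a <- cor$fraction[i] * pi               # from LPA (-y) toward RPA (+y)
    if (is.null(out[[cor$label[i]]]))
      out[[cor$label[i]]] <- R * c(0, -cos(a), sin(a))
  }
  rc <- R * cos(0.1 * pi)                   # 10% ring latitude
  rz <- R * sin(0.1 * pi)
  ring <- ring_left_1010
  for (i in seq_len(nrow(ring))) {
    a <- ring$fraction[i] * pi              # from Fpz (front) via left (-y)
    lab <- ring$label[i]
    if (is.null(out[[lab]]))
      out[[lab]] <- c(rc * cos(a), -rc * sin(a), rz)
    labr <- mirror_label(lab)
    if (is.null(out[[labr]]))
      out[[labr]] <- c(rc * cos(a), rc * sin(a), rz)
  }
  mat <- do.call(rbind, out)
  rownames(mat) <- names(out)
  mat
}

#' Ellipsoidal head phantom
#'
#' Triaxial ellipsoid with semi-axes `a` (Nz-Iz), `b` (LPA-RPA), `c` (vertex)
#' and fiducials at the axis intersections. No closed-form landmark table is
#' attached; use [oracle_landmarks()] for reference positions.
#'
#' @param a,b,c semi-axes (mm), > 0.
#' @param density icosphere subdivision level.
#' @param cz0_offset_deg deterministic angular displacement of Cz0 toward Nz.
#' @return a `phantom` object.
#' @export
make_ellipsoid <- function(a, b, c, density = 4, cz0_offset_deg = 20) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be positive")
  if (density > 7) stop("density > 7 would exceed the vertex-count guard")
  m <- unit_icosphere(density)
  m$vertices <- sweep(m$vertices, 2, c(a, b, c), "*")
  th <- cz0_offset_deg * pi / 180
  d <- c(sin(th), 0, cos(th))
  cz0 <- d / sqrt(sum((d / c(a, b, c))^2))
  fid <- fiducials(nz = c(a, 0, 0), iz = c(-a, 0, 0),
                   lpa = c(0, -b, 0), rpa = c(0, b, 0), cz0 = cz0)
  phantom(m, fid, analytic_landmarks = NULL, kind = "ellipsoid",
          params = list(axes = c(a, b, c), density = density))
}

#' Voxelized ball volume
#'
#' Binary volume with one (or several) solid balls, used as the fixture for
#' surface extraction. A ball touching the grid boundary is rejected.
#'
#' @param radius ball radius in voxels (scalar or vector, one per ball).
#' @param grid integer voxel counts per axis (default `c(64, 64, 64)`).
#' @param voxel_size mm per voxel (scalar or length 3).
#' @param centers optional matrix of ball centers in voxel coordinates
#'   (defaults to the grid center).
#' @return a [volume_image] with value 1 inside the ball(s).
#' @export
make_voxel_ball <- function(radius, grid = c(64, 64, 64), voxel_size = 1,
                            centers = NULL) {
  grid <- as.integer(grid)
  if (length(grid) == 1L) grid <- rep(grid, 3)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (is.null(centers)) centers <- matrix((grid + 1) / 2, 1, 3)
  centers <- rbind(centers)
  radius <- rep_len(radius, nrow(centers))
  for (k in seq_len(nrow(centers))) {
    if (radius[k] > 0 &&
        (any(centers[k, ] - radius[k] < 1.5) ||
         any(centers[k, ] + radius[k] > grid - 0.5)))
      stop("ball touches the grid boundary; enlarge the grid or pad")
  }
  arr <- array(0, grid)
  ix <- seq_len(grid[1]); iy <- seq_len(grid[2]); iz <- seq_len(grid[3])
  for (k in seq_len(nrow(centers))) {
    if (radius[k] <= 0) next
    dx2 <- (ix - centers[k, 1])^2
    dy2 <- (iy - centers[k, 2])^2
    dz2 <- (iz - centers[k, 3])^2
    r2 <- radius[k]^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    arr[inside] <- 1
  }
  volume_image(arr, voxel_size = voxel_size)
}

# ------------------------------------------------------- independent oracle
# Landmarks by dense uniform sampling of ANALYTIC cross-section ellipses,
# entirely independent of the production mesh cross-section code. Sphere and
# ellipsoid surfaces are quadrics: a plane cut is an exact ellipse obtained
# by mapping the ellipsoid to the unit sphere, cutting a circle, and mapping
# back.

oracle_axes <- function(phantom) {
  switch(phantom$kind,
         sphere = rep(phantom$params$radius, 3),
         ellipsoid = phantom$params$axes,
         stop("oracle_landmarks supports sphere and ellipsoid phantoms only"))
}

# dense closed polyline of the plane (p1,p2,p3) cut of the ellipsoid
oracle_section <- function(axes, p1, p2, p3, n_dense) {
  q1 <- p1 / axes; q2 <- p2 / axes; q3 <- p3 / axes   # unit-sphere space
  m <- pracma_cross(q2 - q1, q3 - q1)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-14) stop("oracle: collinear section points")
  m <- m / nm
  h <- sum(m * q1)
  rho2 <- 1 - h^2
  if (rho2 <= 0) stop("oracle: plane misses the unit sphere")
  c0 <- h * m
  u <- q1 - c0
  u <- u / sqrt(sum(u^2))
  v <- pracma_cross(m, u)
  th <- 2 * pi * (seq_len(n_dense) - 1) / n_dense
  circ <- outer(cos(th), u) + outer(sin(th), v)
  pts <- sweep(sqrt(rho2) * circ, 2, c0, "+")         # circle on unit sphere
  sweep(pts, 2, axes, "*")                            # back to ellipsoid
}

ocumlen <- function(pts, closed = TRUE) {
  p2 <- if (closed) rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) else
    pts[-1, , drop = FALSE]
  p1 <- if (closed) pts else pts[-nrow(pts), , drop = FALSE]
  c(0, cumsum(sqrt(rowSums((p2 - p1)^2))))
}

# interpolated projection of p onto a closed polyline: arc-length parameter
# and projected point
oproject <- function(pts, p) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  ab <- nxt - pts
  ap <- matrix(p, n, 3, byrow = TRUE) - pts
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1
  t <- pmin(1, pmax(0, rowSums(ap * ab) / len2))
  q <- pts + t * ab
  dd <- rowSums((q - matrix(p, n, 3, byrow = TRUE))^2)
  i <- which.min(dd)
  cum <- ocumlen(pts, closed = TRUE)
  list(s = cum[i] + t[i] * sqrt(len2[i]), point = q[i, ])
}

# open arc a -> b through via on a closed polyline, endpoints interpolated
oarc <- function(pts, a, b, via) {
  pa <- oproject(pts, a)
  pb <- oproject(pts, b)
  pv <- oproject(pts, via)
  cum <- ocumlen(pts, closed = TRUE)
  L <- cum[length(cum)]
  fwd_len <- (pb$s - pa$s) %% L
  forward <- ((pv$s - pa$s) %% L) <= fwd_len
  s0 <- if (forward) pa$s else pb$s
  span <- if (forward) fwd_len else (pa$s - pb$s) %% L
  rel <- (cum[seq_len(nrow(pts))] - s0) %% L
  inside <- which(rel > 1e-12 * L & rel < span - 1e-12 * L)
  ord <- inside[order(rel[inside])]
  arc <- rbind(if (forward) pa$point else pb$point,
               pts[ord, , drop = FALSE],
               if (forward) pb$point else pa$point)
  if (!forward) arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
  arc
}

opoint_at <- function(pts, t) {
  cum <- ocumlen(pts, closed = FALSE)
  L <- cum[length(cum)]
  target <- t * L
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- cum[i + 1] - cum[i]
  u <- if (seg > 0) (target - cum[i]) / seg else 0
  pts[i, ] + u * (pts[i + 1, ] - pts[i, ])
}

#' Brute-force landmark oracle for analytic phantoms
#'
#' Computes montage landmark positions by dense uniform sampling of exact
#' plane-quadric intersection ellipses, independent of the production mesh
#' cross-section machinery. Intended for tests.
#'
#' @param phantom sphere or ellipsoid `phantom`.
#' @param system montage system id.
#' @param n_dense samples per analytic curve (>= 1e4).
#' @return named matrix of landmark positions.
#' @export
oracle_landmarks <- function(phantom, system = "10-10", n_dense = 1e5) {
  if (n_dense < 1e4) stop("n_dense must be >= 1e4")
  axes <- oracle_axes(phantom)
  fid <- phantom$fiducials
  recipe <- montage_recipe(system)
  cz <- fid$cz0
  # Cz bisection on analytic curves (coronal update then sagittal)
  for (it in 1:200) {
    cl <- oracle_section(axes, fid$lpa, fid$rpa, cz, n_dense)
    arc <- oarc(cl, fid$lpa, fid$rpa, cz)
    cz1 <- opoint_at(arc, 0.5)
    sl <- oracle_section(axes, fid$nz, fid$iz, cz1, n_dense)
    arc <- oarc(sl, fid$nz, fid$iz, cz1)
    cz2 <- opoint_at(arc, 0.5)
    d <- sqrt(sum((cz2 - cz)^2))
    cz <- cz2
    if (d < 1e-10 * max(axes)) break
  }
  pos <- list()
  place <- function(pos, pts_arc, fractions, labels) {
    for (k in seq_along(labels)) {
      if (!is.null(pos[[labels[k]]])) next
      pos[[labels[k]]] <- opoint_at(pts_arc, fractions[k])
    }
    pos
  }
  sl <- oracle_section(axes, fid$nz, fid$iz, cz, n_dense)
  sarc <- oarc(sl, fid$nz, fid$iz, cz)
  pos <- place(pos, sarc, recipe$sagittal$fraction, recipe$sagittal$label)
  cl <- oracle_section(axes, fid$lpa, fid$rpa, cz, n_dense)
  carc <- oarc(cl, fid$lpa, fid$rpa, cz)
  pos <- place(pos, carc, recipe$coronal$fraction, recipe$coronal$label)
  for (cv in recipe$curves) {
    anchors <- lapply(cv$anchors, function(a) {
      if (is.null(pos[[a]])) stop("oracle: anchor not yet placed: ", a)
      pos[[a]]
    })
    lp <- oracle_section(axes, anchors[[1]], anchors[[2]], anchors[[3]], n_dense)
    arc <- oarc(lp, anchors[[1]], anchors[[3]], anchors[[2]])
    pos <- place(pos, arc, cv$fractions, cv$labels)
  }
  if (!is.null(recipe$subset)) pos <- pos[names(pos) %in% recipe$subset]
  mat <- do.call(rbind, pos)
  rownames(mat) <- names(pos)
  mat
}
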