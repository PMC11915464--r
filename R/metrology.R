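#' Head circumference along the 10% ring
#'
#' Length of the closed cross-section through Fpz, T7 and Oz -- the standard
#' cap-sizing ring. When those landmarks are unavailable the loop through
#' Nz, LPA, Iz is used instead (with a note).
#'
#' @param mesh head [trimesh].
#' @param landmarks a [landmark_set] (or `fiducials` for the fallback).
#' @return circumference in mm.
#' @export
circumference <- function(mesh, landmarks) {
  if (inherits(landmarks, "landmark_set") &&
      all(c("Fpz", "T7", "Oz") %in% rownames(landmarks$positions))) {
    p <- landmarks$positions
    loop <- cross_section(mesh, p["Fpz", ], p["T7", ], p["Oz", ])
    return(loop$length)
  }
  fid <- if (inherits(landmarks, "fiducials")) landmarks else landmarks$fiducials
  message("circumference: ring anchors missing, falling back to the Nz-LPA-Iz loop")
  cross_section(mesh, fid$nz, fid$lpa, fid$iz)$length
}

#' Scale a head/cap mesh to a target circumference
#'
#' Uniform scaling about the canonical-frame origin (preauricular midpoint).
#'
#' @param mesh [trimesh] to scale.
#' @param landmarks [landmark_set] used both for the ring measurement and
#'   the scaling center.
#' @param target desired circumference (mm), > 0.
#' @return scaled [trimesh] with the applied factor in attribute `"scale"`.
#' @export
scale_to_circumference <- function(mesh, landmarks, target) {
  if (target <= 0) stop("target circumference must be positive")
  cur <- circumference(mesh, landmarks)
  s <- target / cur
  origin <- as.numeric((landmarks$fiducials$lpa + landmarks$fiducials$rpa) / 2)
  v <- sweep(sweep(mesh$vertices, 2, origin), 2, rep(s, 3), "*")
  v <- sweep(v, 2, origin, "+")
  out <- trimesh(v, mesh$faces, validate = FALSE)
  attr(out, "scale") <- s
  out
}

# arc-length positions of points projected onto a curve, measured from a
# reference point on (or near) the same curve
arc_distances <- function(curve, points, origin, tol = NULL) {
  if (is.null(tol)) tol <- 4 * curve$length / nrow(curve$points)
  po <- curve_project(curve, as.numeric(origin))
  if (po$dist > tol)
    stop(sprintf("origin is %.3g mm from the curve (tolerance %.3g)", po$dist, tol))
  points <- rbind(points)
  vapply(seq_len(nrow(points)), function(i) {
    pp <- curve_project(curve, points[i, ])
    if (curve$closed) {
      dd <- abs(pp$s - po$s)
      min(dd, curve$length - dd)
    } else {
      abs(pp$s - po$s)
    }
  }, numeric(1))
}

#' Geodesic landmark distances along a reference row
#'
#' Distances from an origin landmark to each row landmark, measured along the
#' corresponding reference cross-section curve (sagittal: Nz-Cz-Iz arc from
#' Iz; coronal: LPA-Cz-RPA arc from RPA).
#'
#' @param mesh head [trimesh].
#' @param landmarks a [landmark_set] (with fiducials and converged Cz).
#' @param row `"sagittal"` or `"coronal"`.
#' @param origin_label reference landmark/fiducial (default Iz sagittal,
#'   RPA coronal).
#' @return named vector, label -> distance (mm).
#' @export
geodesic_landmark_distances <- function(mesh, landmarks,
                                        row = c("sagittal", "coronal"),
                                        origin_label = NULL) {
  row <- match.arg(row)
  fid <- landmarks$fiducials
  cz <- landmarks$cz
  if (row == "sagittal") {
    if (is.null(origin_label)) origin_label <- "Iz"
    loop <- cross_section(mesh, fid$nz, fid$iz, cz)
    arc <- arc_on_loop(loop, fid$nz, fid$iz, via = cz)
    labels <- intersect(sagittal_1010$label, rownames(landmarks$positions))
  } else {
    if (is.null(origin_label)) origin_label <- "RPA"
    loop <- cross_section(mesh, fid$lpa, fid$rpa, cz)
    arc <- arc_on_loop(loop, fid$lpa, fid$rpa, via = cz)
    labels <- intersect(coronal_1010$label, rownames(landmarks$positions))
  }
  origin <- resolve_label(origin_label, landmarks)
  d <- arc_distances(arc, landmarks$positions[labels, , drop = FALSE], origin)
  names(d) <- labels
  d
}

resolve_label <- function(label, landmarks) {
  fid_names <- c(Nz = "nz", Iz = "iz", LPA = "lpa", RPA = "rpa")
  if (label %in% names(fid_names))
    return(landmarks$fiducials[[fid_names[[label]]]])
  if (label %in% rownames(landmarks$positions))
    return(landmarks$positions[label, ])
  stop("unknown origin label: ", label)
}

#' Radially project points onto a surface
#'
#' Maps each point along the ray from `center` through the point to the first
#' surface intersection beyond the center.
#'
#' @param points n x 3 matrix.
#' @param center projection center (the preauricular midpoint by convention).
#' @param target_mesh [trimesh] to project onto.
#' @return n x 3 matrix of projected points.
#' @export
radial_project <- function(points, center, target_mesh) {
  points <- rbind(points)
  center <- as.numeric(center)
  dirs <- sweep(points, 2, center)
  lens <- sqrt(rowSums(dirs^2))
  if (any(lens == 0)) stop("point coincides with the projection center")
  dirs <- dirs / lens
  res <- mesh_raycast(matrix(center, nrow(points), 3, byrow = TRUE), dirs,
                      target_mesh, tmin = 1e-9, tmax = Inf)
  miss <- which(is.na(res$t))
  if (length(miss)) {
    lab <- rownames(points)
    lab <- if (is.null(lab)) as.character(miss) else lab[miss]
    stop("radial projection missed the surface for: ",
         paste(lab, collapse = ", "))
  }
  out <- matrix(center, nrow(points), 3, byrow = TRUE) + res$t * dirs
  rownames(out) <- rownames(points)
  out
}

#' Landmark distance error statistics
#'
#' Coefficient of determination of the linear fit of measured vs reference
#' distances, plus mean and standard deviation of the absolute errors.
#'
#' @param reference,measured named distance vectors (matched labels, mm).
#' @return object of class `validation_report` with fields `pairs`,
#'   `r_squared`, `mean_error`, `sd_error`.
#' @export
landmark_error_stats <- function(reference, measured) {
  labels <- intersect(names(reference), names(measured))
  if (length(labels) < 3) stop("need at least 3 matched label pairs")
  ref <- reference[labels]
  mea <- measured[labels]
  fit <- stats::lm(mea ~ ref)
  err <- abs(mea - ref)
  # summary.lm warns on numerically perfect fits; those are legitimate here
  rsq <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    pairs = data.frame(label = labels, reference = as.numeric(ref),
                       measured = as.numeric(mea), stringsAsFactors = FALSE),
    r_squared = rsq,
    mean_error = mean(err),
    sd_error = stats::sd(err)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d pairs, R^2 = %.5f, error %.3f +/- %.3f mm\n",
              nrow(x$pairs), x$r_squared, x$mean_error, x$sd_error))
  invisible(x)
}

#' Recover grommet hole centers from a cut cap surface
#'
#' Finds the boundary loops of the holed cap and matches each loop centroid
#' to its nearest landmark; loops farther than `max_dist` from every landmark
#' (e.g. the face opening and neck rim) are ignored.
#'
#' @param cap_surface holed cap [trimesh] (before wireframe extrusion).
#' @param landmarks the registered [landmark_set] used for the holes.
#' @param max_dist matching radius (mm), default 2x grommet radius ~ 8.
#' @return matrix of hole centroids with landmark rownames.
#' @export
recover_grommet_centers <- function(cap_surface, landmarks, max_dist = 8) {
  loops <- mesh_boundary_loops(cap_surface)
  if (!length(loops)) stop("cap has no boundary loops")
  cent <- t(vapply(loops, function(lp)
    colMeans(cap_surface$vertices[lp, , drop = FALSE]), numeric(3)))
  P <- landmarks$positions
  out <- NULL
  labs <- character(0)
  for (i in seq_len(nrow(cent))) {
    d <- sqrt(rowSums((P - matrix(cent[i, ], nrow(P), 3, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= max_dist) {
      out <- rbind(out, cent[i, ])
      labs <- c(labs, rownames(P)[j])
    }
  }
  if (is.null(out)) stop("no grommet holes matched any landmark")
  rownames(out) <- labs
  out
}

#' End-to-end landmark accuracy of a built cap
#'
#' Computational analog of measuring a printed cap against its head model:
#' recovers the grommet-hole centroids from the holed cap surface, radially
#' projects them from the head center back onto the head surface, measures
#' their distances along the sagittal (from Iz) and coronal (from RPA)
#' reference curves, and compares with the head-surface landmark distances.
#'
#' @param head_mesh original head [trimesh].
#' @param landmarks the [landmark_set] computed on `head_mesh`.
#' @param cap_surface holed cap surface (from [cut_grommet_holes()] /
#'   [cut_margins()]).
#' @param max_dist hole-to-landmark matching radius (mm).
#' @return a `validation_report`.
#' @export
validate_cap_landmarks <- function(head_mesh, landmarks, cap_surface,
                                   max_dist = 8) {
  centers <- recover_grommet_centers(cap_surface, landmarks, max_dist)
  frame_origin <- (landmarks$fiducials$lpa + landmarks$fiducials$rpa) / 2
  projected <- radial_project(centers, frame_origin, head_mesh)
  fid <- landmarks$fiducials
  cz <- landmarks$cz
  sag_labels <- intersect(sagittal_1010$label, rownames(projected))
  cor_labels <- intersect(setdiff(coronal_1010$label, "Cz"), rownames(projected))
  reference <- measured <- numeric(0)
  if (length(sag_labels) >= 2) {
    loop <- cross_section(head_mesh, fid$nz, fid$iz, cz)
    arc <- arc_on_loop(loop, fid$nz, fid$iz, via = cz)
    ref <- arc_distances(arc, landmarks$positions[sag_labels, , drop = FALSE],
                         fid$iz)
    mea <- arc_distances(arc, projected[sag_labels, , drop = FALSE], fid$iz)
    names(ref) <- names(mea) <- sag_labels
    reference <- c(reference, ref)
    measured <- c(measured, mea)
  }
  if (length(cor_labels) >= 2) {
    loop <- cross_section(head_mesh, fid$lpa, fid$rpa, cz)
    arc <- arc_on_loop(loop, fid$lpa, fid$rpa, via = cz)
    ref <- arc_distances(arc, landmarks$positions[cor_labels, , drop = FALSE],
                         fid$rpa)
    mea <- arc_distances(arc, projected[cor_labels, , drop = FALSE], fid$rpa)
    names(ref) <- names(mea) <- cor_labels
    reference <- c(reference, ref)
    measured <- c(measured, mea)
  }
  landmark_error_stats(reference, measured)
}
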