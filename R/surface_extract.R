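#' Surface extraction parameters
#'
#' @param threshold foreground rule: `NULL` (all nonzero voxels, the default
#'   for label maps), a scalar grayscale threshold, or an integer vector of
#'   label values to union.
#' @param max_circumradius upper bound on the circumscribed-circle radius of
#'   output triangles (mm) -- the mesh density control.
#' @param smoothing_iterations Taubin smoothing passes applied to the raw
#'   iso-surface.
#' @return object of class `extraction_params`.
#' @export
extraction_params <- function(threshold = NULL, max_circumradius = 2,
                              smoothing_iterations = 5) {
  if (max_circumradius <= 0) stop("max_circumradius must be positive")
  if (smoothing_iterations < 0) stop("smoothing_iterations must be >= 0")
  structure(list(threshold = threshold, max_circumradius = max_circumradius,
                 smoothing_iterations = smoothing_iterations),
            class = "extraction_params")
}

# separable (1,2,1)/4 blur along each axis, `passes` times
blur3 <- function(a, passes = 2) {
  d <- dim(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      idx_lo <- pmax(seq_len(d[ax]) - 1L, 1L)
      idx_hi <- pmin(seq_len(d[ax]) + 1L, d[ax])
      if (ax == 1) a <- (a[idx_lo, , , drop = FALSE] + 2 * a +
                         a[idx_hi, , , drop = FALSE]) / 4
      if (ax == 2) a <- (a[, idx_lo, , drop = FALSE] + 2 * a +
                         a[, idx_hi, , drop = FALSE]) / 4
      if (ax == 3) a <- (a[, , idx_lo, drop = FALSE] + 2 * a +
                         a[, , idx_hi, drop = FALSE]) / 4
    }
  }
  a
}

#' Extract the outer head surface from a volumetric image
#'
#' Thresholds the volume, keeps the largest connected foreground component,
#' fills interior cavities (so only the outer scalp boundary remains),
#' iso-surfaces the smoothed occupancy at 0.5 with marching tetrahedra in
#' physical (mm) coordinates, applies Taubin smoothing, and subdivides until
#' every triangle's circumscribed-circle radius is below the requested bound.
#'
#' @param volume a [volume_image].
#' @param params an [extraction_params].
#' @return closed genus-0 [trimesh] in mm.
#' @export
extract_head_surface <- function(volume, params = extraction_params()) {
  stopifnot(inherits(volume, "volume_image"), inherits(params, "extraction_params"))
  arr <- volume$array
  thr <- params$threshold
  fg <- if (is.null(thr)) arr != 0
        else if (length(thr) == 1L && !is.integer(thr)) arr >= thr
        else array(arr %in% thr, dim(arr))
  if (!any(fg)) stop("empty foreground after thresholding")
  d <- dim(fg)
  if (any(fg[1, , ]) || any(fg[d[1], , ]) || any(fg[, 1, ]) ||
      any(fg[, d[2], ]) || any(fg[, , 1]) || any(fg[, , d[3]]))
    stop("foreground touches the grid boundary; pad the volume first")

  # largest connected component
  lab <- cpp_label_components(as.logical(fg), d, 6L)
  lab <- array(lab, d)
  counts <- tabulate(lab[lab > 0])
  fg <- lab == which.max(counts)

  # fill interior cavities: background components not connected to the border
  bg_lab <- array(cpp_label_components(as.logical(!fg), d, 6L), d)
  border_ids <- unique(c(bg_lab[1, , ], bg_lab[d[1], , ], bg_lab[, 1, ],
                         bg_lab[, d[2], ], bg_lab[, , 1], bg_lab[, , d[3]]))
  border_ids <- border_ids[border_ids > 0]
  cavity <- bg_lab > 0 & !(bg_lab %in% border_ids)
  fg[cavity] <- TRUE

  field <- blur3(array(as.numeric(fg), d), passes = 2)
  origin <- volume$origin
  mt <- cpp_marching_tetra(as.numeric(field), d, origin, volume$voxel_size, 0.5)
  mesh <- trimesh(mt$vertices, mt$faces + 1L, validate = FALSE)
  mesh <- weld(mesh, tolerance = 1e-9 * mesh_bbox_diag(mesh))
  if (params$smoothing_iterations > 0)
    mesh <- mesh_taubin_smooth(mesh, params$smoothing_iterations)
  for (round in 1:6) {
    if (max(mesh_circumradii(mesh)) <= params$max_circumradius) break
    mesh <- mesh_subdivide(mesh)
  }
  if (max(mesh_circumradii(mesh)) > params$max_circumradius)
    stop("could not satisfy the circumradius bound")
  mesh
}
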