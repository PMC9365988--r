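#' B-spline prefilter: convert samples to interpolation coefficients
#'
#' For spline degree >= 2, interpolation (as opposed to smoothing) requires
#' recursive prefiltering of the samples into B-spline coefficients; this is
#' applied automatically by [resample()] and exposed here for reuse when the
#' same volume is evaluated many times.
#'
#' @param arr 3D numeric array of samples.
#' @param degree Spline degree (0, 1, 3 or 4). Degrees 0/1 return `arr`.
#' @return Array of B-spline coefficients, same shape.
#' @export
bspline_coefficients <- function(arr, degree) {
  check_degree(degree)
  if (degree <= 1L) return(arr)
  array(spline_filter3_cpp(as.double(arr), dim(arr), as.integer(degree)),
        dim(arr))
}

check_degree <- function(degree) {
  if (!degree %in% c(0L, 1L, 2L, 3L, 4L))
    stop("interpolation degree must be one of 0, 1, 2, 3, 4", call. = FALSE)
  invisible(as.integer(degree))
}

# Evaluate a (pre-filtered if degree >= 2) coefficient array at continuous
# 0-based voxel coordinates (N x 3). Outside [0, dim-1] -> background.
interp_coeffs <- function(coeffs, coords, degree, background = 0) {
  bspline_eval3_cpp(as.double(coeffs), dim(coeffs), rbind_coords(coords),
                    as.integer(degree), background)
}

#' Resample a volume through an arbitrary coordinate mapping
#'
#' Evaluates the B-spline interpolant of `v` at the input-voxel coordinates
#' that `mapping` assigns to every output voxel. Coordinates outside the
#' input domain evaluate to 0 (constant padding): brain images and masks are
#' zero outside the head, so this avoids inflating regions at the edges.
#'
#' @param v A [volume3d()].
#' @param mapping Function taking an N x 3 matrix of 0-based output voxel
#'   coordinates and returning an N x 3 matrix of continuous 0-based input
#'   voxel coordinates. `NULL` means identity (requires matching grids).
#' @param degree Interpolation degree: 0 (nearest), 1 (trilinear), 3 (cubic)
#'   or 4 (quartic, the "4th-degree B-spline" used throughout the
#'   parcellation pipeline).
#' @param out_shape,out_affine Geometry of the output grid; default the
#'   input grid.
#' @return A `volume3d` on the output grid.
#' @export
resample <- function(v, mapping = NULL, degree = 4,
                     out_shape = dim(v$data), out_affine = v$affine) {
  degree <- check_degree(degree)
  if (abs(det(out_affine)) < 1e-12)
    stop("out_affine must be invertible", call. = FALSE)
  geom <- grid_geometry(dim = out_shape, affine = out_affine)
  out_vox <- grid_coords(geom)
  in_vox <- if (is.null(mapping)) out_vox else rbind_coords(mapping(out_vox))
  coeffs <- bspline_coefficients(v$data, degree)
  vals <- interp_coeffs(coeffs, in_vox, degree)
  volume3d(array(vals, geom$dim), out_affine)
}

# Build a voxel->voxel mapping for resampling `source` onto `target_geom`
# through `transform` (maps target-world -> source-world; NULL = identity).
pullback_mapping <- function(source_affine, target_affine, transform = NULL) {
  function(out_vox) {
    w <- voxel_to_world(target_affine, out_vox)
    if (!is.null(transform)) w <- apply_to_points(transform, w)
    world_to_voxel(source_affine, w)
  }
}

#' Resample a volume onto a target grid through a spatial transform
#'
#' @param v Source [volume3d()].
#' @param target A `grid_geometry` or `volume3d` defining the output grid.
#' @param transform An `affine_transform`, `deformation_field`, or `NULL`
#'   (identity); maps target-space world coordinates to source-space world
#'   coordinates (the pull-back convention).
#' @param degree Interpolation degree.
#' @return A `volume3d` on the target grid.
#' @export
resample_to_grid <- function(v, target, transform = NULL, degree = 4) {
  geom <- grid_geometry(target)
  resample(v, pullback_mapping(v$affine, geom$affine, transform),
           degree = degree, out_shape = geom$dim, out_affine = geom$affine)
}

# Gaussian smoothing in voxel units
smooth_volume <- function(v, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  volume3d(array(gauss_smooth3_cpp(as.double(v$data), dim(v$data),
                                   as.double(sigma_vox)), dim(v$data)),
           v$affine)
}

# Smooth + decimate by 2 along axes with more than `min_dim` samples.
downsample_volume <- function(v, min_dim = 8L) {
  d <- dim(v$data)
  keep <- d >= 2L * min_dim
  if (!any(keep)) return(v)
  sig <- ifelse(keep, 0.85, 0)
  sm <- smooth_volume(v, sig)
  idx <- lapply(1:3, function(i) if (keep[i]) seq(1L, d[i], by = 2L) else seq_len(d[i]))
  arr <- sm$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  a <- v$affine
  step <- ifelse(keep, 2, 1)
  a[1:3, 1:3] <- sweep(a[1:3, 1:3], 2, step, "*")
  volume3d(arr, a)
}
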