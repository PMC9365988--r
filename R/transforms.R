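#' Affine world-to-world transform
#'
#' Represents the 12-parameter transform obtained by the template
#' registration path. By convention a transform maps world coordinates of
#' the space it will resample INTO (the fixed/target space) to world
#' coordinates of the source space, so it can be used directly as a
#' pull-back map by [resample_to_grid()].
#'
#' @param matrix 4x4 matrix, last row (0,0,0,1).
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4))) stop("affine must be 4x4", call. = FALSE)
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0,0,0,1)", call. = FALSE)
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine transform is singular", call. = FALSE)
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
identity_affine <- function() affine_transform(diag(4))

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Dense deformation field
#'
#' A per-voxel displacement (mm) on a reference grid. The field maps a
#' world point `x` to `x + u(x)` where `u` is interpolated trilinearly from
#' the displacement grid.
#'
#' @param displacement 4D array `nx x ny x nz x 3` of mm displacements.
#' @param affine 4x4 affine of the reference grid.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(displacement, affine = diag(4)) {
  displacement <- as.array(displacement)
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement must be an nx x ny x nz x 3 array", call. = FALSE)
  if (!all(is.finite(displacement)))
    stop("displacement must be finite everywhere", call. = FALSE)
  if (abs(det(affine)) < 1e-12) stop("grid affine must be invertible", call. = FALSE)
  structure(list(displacement = displacement, affine = affine),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$displacement, ncol = 3)^2))
  cat("<deformation_field> grid ",
      paste(dim(x$displacement)[1:3], collapse = " x "),
      ", |u| mean ", signif(mean(mag), 3), " / max ", signif(max(mag), 3),
      " mm\n", sep = "")
  invisible(x)
}

field_grid <- function(d)
  grid_geometry(dim = dim(d$displacement)[1:3], affine = d$affine)

# displacement (mm, N x 3) at world points. Points outside the reference
# grid give NA rows ("na") or the nearest-edge value ("clamp", used by the
# iterative inversion/integration machinery).
field_displacement_at <- function(d, pts, extrapolate = c("na", "clamp")) {
  extrapolate <- match.arg(extrapolate)
  pts <- rbind_coords(pts)
  vox <- world_to_voxel(d$affine, pts)
  dm <- dim(d$displacement)[1:3]
  inside <- vox[, 1] >= 0 & vox[, 1] <= dm[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= dm[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= dm[3] - 1
  if (extrapolate == "clamp")
    for (k in 1:3) vox[, k] <- pmin(pmax(vox[, k], 0), dm[k] - 1)
  u <- matrix(0, nrow(pts), 3)
  for (k in 1:3)
    u[, k] <- interp_coeffs(array(d$displacement[, , , k], dm), vox, 1L)
  if (extrapolate == "na") u[!inside, ] <- NA_real_
  u
}

#' Apply a transform to world-space points
#'
#' @param t An `affine_transform` or `deformation_field`.
#' @param points N x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return N x 3 matrix of mapped coordinates. For deformation fields,
#'   points outside the reference grid map to `NA` and are flagged in the
#'   `outside` attribute.
#' @export
apply_to_points <- function(t, points) UseMethod("apply_to_points")

#' @export
apply_to_points.affine_transform <- function(t, points) {
  pts <- rbind_coords(points)
  sweep(pts %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], "+")
}

#' @export
apply_to_points.deformation_field <- function(t, points) {
  pts <- rbind_coords(points)
  u <- field_displacement_at(t, pts)
  out <- pts + u
  structure(out, outside = !stats::complete.cases(u))
}

#' Invert an affine transform
#'
#' @param t An `affine_transform`.
#' @return The exact inverse `affine_transform`.
#' @export
invert_affine <- function(t) {
  m <- tryCatch(solve(t$matrix), error = function(e)
    stop("affine transform is singular", call. = FALSE))
  affine_transform(m)
}

#' Invert a deformation field by fixed-point iteration
#'
#' Computes the displacement `v` on the target grid such that
#' `x + v(x)` is mapped back to `x` by the forward field, via the damped
#' fixed-point iteration `v <- -u(x + v)`. This yields the
#' standard-to-individual inverse needed to pull atlas masks onto the
#' individual grid.
#'
#' @param d Forward `deformation_field`.
#' @param target Grid on which to evaluate the inverse (a `grid_geometry`
#'   or `volume3d`); defaults to the forward field's own grid.
#' @param tol Convergence tolerance in voxels (max update).
#' @param max_iter Maximum iterations.
#' @return An `inverse_deformation` (a `deformation_field` with `residual`,
#'   the max interior composition error in voxels, and `provenance`).
#' @export
invert_deformation <- function(d, target = NULL, tol = 0.01, max_iter = 50L) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  geom <- if (is.null(target)) field_grid(d) else grid_geometry(target)
  vs <- voxel_size(list(affine = geom$affine))
  x <- voxel_to_world(geom$affine, grid_coords(geom))
  v <- matrix(0, nrow(x), 3)
  prev_update <- Inf
  damp <- 1
  for (it in seq_len(max_iter)) {
    u <- field_displacement_at(d, x + v, extrapolate = "clamp")
    v_new <- -u
    step <- v_new - v
    upd <- max(abs(sweep(step, 2, vs, "/")))
    if (upd > prev_update) damp <- max(0.25, damp / 2)  # damp on oscillation
    v <- v + damp * step
    prev_update <- upd
    if (upd < tol) break
  }
  # composition residual ||v(x) + u(x + v(x))|| on the interior, voxel units
  u <- field_displacement_at(d, x + v, extrapolate = "clamp")
  res_vec <- sweep(v + u, 2, vs, "/")
  res <- sqrt(rowSums(res_vec^2))
  interior <- interior_mask(geom$dim)
  res_int <- max(res[interior])
  if (res_int > 10 * tol) {
    worst <- which.max(res * interior)
    stop(sprintf(
      "deformation inversion did not converge: residual %.4f voxels at voxel (%d,%d,%d)",
      res_int, arrayInd(worst, geom$dim)[1], arrayInd(worst, geom$dim)[2],
      arrayInd(worst, geom$dim)[3]), call. = FALSE)
  }
  out <- deformation_field(array(v, c(geom$dim, 3)), geom$affine)
  out$residual <- res_int
  out$provenance <- "fixed-point inverse"
  class(out) <- c("inverse_deformation", class(out))
  out
}

# logical vector marking voxels more than one voxel away from the grid edge
interior_mask <- function(dm) {
  m <- array(TRUE, dm)
  m[c(1L, dm[1]), , ] <- FALSE
  m[, c(1L, dm[2]), ] <- FALSE
  m[, , c(1L, dm[3])] <- FALSE
  as.vector(m)
}

#' Compose two transforms
#'
#' Returns the map `outer(inner(x))`. Two affines compose exactly (matrix
#' product); any combination involving a deformation field is evaluated on
#' the inner transform's reference grid (or the outer's, if the inner is
#' affine) and returned as a dense field.
#'
#' @param outer,inner Transforms (`affine_transform` or `deformation_field`).
#' @param grid Optional `grid_geometry` on which to evaluate a composed
#'   field.
#' @return An `affine_transform` (affine-affine) or `deformation_field`.
#' @export
compose_transforms <- function(outer, inner, grid = NULL) {
  if (inherits(outer, "affine_transform") && inherits(inner, "affine_transform"))
    return(affine_transform(outer$matrix %*% inner$matrix))
  geom <- if (!is.null(grid)) grid_geometry(grid)
          else if (inherits(inner, "deformation_field")) field_grid(inner)
          else field_grid(outer)
  x <- voxel_to_world(geom$affine, grid_coords(geom))
  y <- apply_to_points(inner, x)
  z <- apply_to_points(outer, y)
  disp <- z - x
  disp[is.na(disp)] <- 0
  deformation_field(array(disp, c(geom$dim, 3)), geom$affine)
}

#' Read / write transforms
#'
#' Affine transforms are stored as a plain-text 4x4 matrix; deformation
#' fields as 5D displacement NIfTI (x, y, z, 1, 3) in mm.
#'
#' @param t Transform to write.
#' @param path File path.
#' @return `path` (write) or the transform (read).
#' @export
write_affine_transform <- function(t, path) {
  utils::write.table(t$matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine_transform
#' @export
read_affine_transform <- function(path) {
  affine_transform(as.matrix(utils::read.table(path)))
}

#' @rdname write_affine_transform
#' @param d Deformation field to write.
#' @export
write_deformation <- function(d, path) {
  dm <- dim(d$displacement)
  arr <- array(d$displacement, c(dm[1:3], 1L, 3L))
  write_nifti_array(arr, d$affine, path)
}

#' @rdname write_affine_transform
#' @export
read_deformation <- function(path) {
  im <- RNifti::readNifti(path)
  dm <- dim(im)
  if (length(dm) != 5L || dm[5] != 3L)
    stop("expected a 5D (x,y,z,1,3) displacement image", call. = FALSE)
  deformation_field(array(as.vector(as.array(im)), c(dm[1:3], 3L)),
                    unclass(RNifti::xform(im)))
}
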