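#' Construct a 3D volume with world-space geometry
#'
#' A `volume3d` couples a 3D numeric array with a 4x4 affine mapping 0-based
#' voxel indices to world coordinates in mm (NIfTI RAS+ convention; the
#' continuous voxel coordinate `i.0` is the voxel centre).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible matrix; voxel index (0-based) to world mm.
#' @return An object of class `volume3d` with elements `data` and `affine`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), affine = diag(c(0.14, 0.14, 1.2, 1)))
#' voxel_size(v)
#' @export
volume3d <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume3d requires a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be positive", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4", call. = FALSE)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x), 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Voxel dimensions of a volume (mm)
#'
#' @param v A `volume3d` (or anything with an `affine` element).
#' @return Numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_size <- function(v) {
  a <- if (is.list(v)) v$affine else v
  sqrt(colSums(a[1:3, 1:3]^2))
}

#' Grid geometry (shape + affine) of a volume
#'
#' @param v A `volume3d`, or pass `dim` and `affine` directly.
#' @param dim,affine Alternative direct specification.
#' @return A `grid_geometry` list with `dim` and `affine`.
#' @export
grid_geometry <- function(v = NULL, dim = NULL, affine = NULL) {
  if (!is.null(v)) {
    if (inherits(v, "grid_geometry")) return(v)
    dim <- base::dim(v$data)
    affine <- v$affine
  }
  structure(list(dim = as.integer(dim), affine = affine),
            class = "grid_geometry")
}

# voxel (0-based, N x 3) -> world mm (N x 3)
voxel_to_world <- function(affine, vox) {
  vox <- rbind_coords(vox)
  sweep(vox %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# world mm (N x 3) -> voxel (0-based, N x 3)
world_to_voxel <- function(affine, pts) {
  pts <- rbind_coords(pts)
  inv <- solve(affine)
  sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.matrix(x)
}

# all 0-based voxel coordinates of a grid, N x 3, column-major order
grid_coords <- function(geom) {
  d <- geom$dim
  cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L) {
    if (length(dim(im)) > 3L && all(dim(im)[-(1:3)] == 1L)) {
      im <- array(as.array(im), dim(im)[1:3])
    } else {
      stop("expected a 3D volume, got ", length(dim(im)),
           " dimensions; use read_series4d() for 4D data", call. = FALSE)
    }
  }
  volume3d(strip_attrs(as.array(im)), affine = unclass(RNifti::xform(im)))
}

# drop RNifti bookkeeping attributes, keeping only dim
strip_attrs <- function(arr) {
  array(as.vector(arr), dim(arr))
}

#' Write a 3D volume as NIfTI-1
#'
#' @param v A [volume3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  write_nifti_array(v$data, v$affine, path)
}

write_nifti_array <- function(arr, affine, path) {
  im <- RNifti::asNifti(arr)
  pd <- c(voxel_size(list(affine = affine)), rep(1, length(dim(arr)) - 3L))
  RNifti::pixdim(im) <- pd
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::qform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Construct / read / write a 4D series of volumes
#'
#' A `series4d` is an ordered set of [volume3d()] volumes sharing one grid,
#' e.g. the repeated MEMRI acquisitions of one session.
#'
#' @param volumes List of `volume3d`, all with identical shape and affine.
#' @return A `series4d` object (elements `volumes`, `affine`).
#' @export
series4d <- function(volumes) {
  if (length(volumes) < 1L) stop("series4d needs at least one volume", call. = FALSE)
  d0 <- dim(volumes[[1]]$data); a0 <- volumes[[1]]$affine
  for (v in volumes) {
    if (!identical(dim(v$data), d0) || max(abs(v$affine - a0)) > 1e-6)
      stop("all volumes in a series must share shape and affine", call. = FALSE)
  }
  structure(list(volumes = volumes, affine = a0), class = "series4d")
}

#' @export
print.series4d <- function(x, ...) {
  cat("<series4d> ", length(x$volumes), " volumes of ",
      paste(dim(x$volumes[[1]]$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' @rdname series4d
#' @param path NIfTI path (4D image).
#' @export
read_series4d <- function(path) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 4L)
    stop("expected a 4D series", call. = FALSE)
  aff <- unclass(RNifti::xform(im))
  arr <- strip_attrs(as.array(im))
  series4d(lapply(seq_len(dim(arr)[4]), function(k)
    volume3d(arr[, , , k, drop = TRUE], aff)))
}

#' @rdname series4d
#' @param s A `series4d`.
#' @export
write_series4d <- function(s, path) {
  arr <- vapply(s$volumes, function(v) v$data,
                array(0, dim(s$volumes[[1]]$data)))
  write_nifti_array(arr, s$affine, path)
}

#' Enlarge or shrink the voxel size recorded in the header
#'
#' Rodent images are routinely rescaled (classically by a factor of 10)
#' before registration with tools whose priors assume human-sized heads.
#' Only the affine is changed; the voxel data are untouched.
#'
#' @param v A [volume3d()].
#' @param factor Positive scalar applied to the spatial part of the affine.
#' @return The rescaled `volume3d`.
#' @export
scale_voxels <- function(v, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a positive scalar", call. = FALSE)
  a <- v$affine
  a[1:3, ] <- a[1:3, ] * factor
  volume3d(v$data, a)
}

#' Place the world origin at a chosen point
#'
#' Shifts the affine translation so that the given world point becomes
#' (0,0,0) -- e.g. to pin the origin to an anatomical landmark such as the
#' dorsal third ventricle before registration. Data are untouched.
#'
#' @param v A [volume3d()].
#' @param world_point Length-3 world coordinate (mm) that should map to 0.
#' @return The re-originated `volume3d`.
#' @export
set_origin <- function(v, world_point) {
  world_point <- as.numeric(world_point)
  if (length(world_point) != 3L || !all(is.finite(world_point)))
    stop("world_point must be a finite length-3 coordinate", call. = FALSE)
  a <- v$affine
  a[1:3, 4] <- a[1:3, 4] - world_point
  volume3d(v$data, a)
}

#' Label atlas: integer-labelled volume plus lookup table
#'
#' @param labels A [volume3d()] whose data are non-negative integers
#'   (0 = background).
#' @param lut Data frame with columns `index` (positive integers, unique)
#'   and `name`. If omitted, names `roi_<k>` are generated.
#' @return A `label_atlas` (elements `labels`, `lut`).
#' @export
label_atlas <- function(labels, lut = NULL) {
  vals <- sort(unique(as.vector(labels$data)))
  vals <- vals[vals != 0]
  if (any(vals < 0) || any(vals != round(vals)))
    stop("atlas labels must be non-negative integers", call. = FALSE)
  if (is.null(lut))
    lut <- data.frame(index = as.integer(vals),
                      name = sprintf("roi_%d", as.integer(vals)))
  if (!all(c("index", "name") %in% names(lut)))
    stop("lut needs columns `index` and `name`", call. = FALSE)
  if (anyDuplicated(lut$index)) stop("lut indices must be unique", call. = FALSE)
  missing <- setdiff(vals, lut$index)
  if (length(missing))
    stop("labels present in image but missing from lut: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, lut = lut), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> ", nrow(x$lut), " regions on ",
      paste(dim(x$labels$data), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Read / write a label lookup table (TSV with header `index<TAB>name`)
#'
#' @param path Path to a tab-separated table.
#' @return Data frame with `index` and `name`.
#' @export
read_lut <- function(path) {
  lut <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("index", "name") %in% names(lut)))
    stop("lookup table must have columns `index` and `name`", call. = FALSE)
  lut$index <- as.integer(lut$index)
  lut
}

#' @rdname read_lut
#' @param lut Data frame with `index`, `name`.
#' @export
write_lut <- function(lut, path) {
  utils::write.table(lut[, c("index", "name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binary region mask
#'
#' @param data A [volume3d()] with values in \{0, 1\}, or a logical/numeric
#'   array plus `affine`.
#' @param source_index Atlas index the mask originates from (or `NA`).
#' @param affine Affine, used when `data` is a bare array.
#' @return A `binary_mask` (elements `data` = volume3d, `source_index`).
#' @export
binary_mask <- function(data, source_index = NA_integer_, affine = diag(4)) {
  if (!inherits(data, "volume3d")) data <- volume3d(data * 1, affine)
  if (!all(data$data %in% c(0, 1)))
    stop("binary mask may only contain 0 and 1", call. = FALSE)
  structure(list(data = data, source_index = as.integer(source_index)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> index ", x$source_index, ", ",
      sum(x$data$data), " voxels\n", sep = "")
  invisible(x)
}

mask_count <- function(m) sum(m$data$data != 0)

# internal: run code with a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
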