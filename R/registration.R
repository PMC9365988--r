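# Registration of an individual image into standard (template/atlas) space.
#
# All registrations return transforms in the pull-back convention: the
# result maps fixed-space world coordinates to moving-space world
# coordinates, i.e. registering the individual (moving) to the template
# (fixed) yields the standard-to-individual map whose inverse carries atlas
# masks onto the individual grid.

# --- parameterized affine -------------------------------------------------

rot3 <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# p = (t1 t2 t3, r1 r2 r3, log s1..s3, h1..h3); rotation/scale/shear about
# `center` (world mm)
affine_from_params <- function(p, center = c(0, 0, 0)) {
  p <- c(p, rep(0, 12 - length(p)))
  R <- rot3(p[4:6])
  S <- diag(exp(p[7:9]))
  H <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  L <- R %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- p[1:3] + center - L %*% center
  m
}

# decompose the 3x3 part: rotation angles via polar factor (for reporting)
rotation_angles <- function(m) {
  L <- m[1:3, 1:3]
  sv <- svd(L)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  c(atan2(R[3, 2], R[3, 3]),
    -asin(max(-1, min(1, R[3, 1]))),
    atan2(R[2, 1], R[1, 1]))
}

# --- similarity metrics ---------------------------------------------------

metric_ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

metric_mi <- function(a, b, bins = 32L) {
  ia <- pmin(bins, pmax(1L, as.integer(1 + (a - min(a)) /
          max(diff(range(a)), 1e-12) * (bins - 1e-9))))
  ib <- pmin(bins, pmax(1L, as.integer(1 + (b - min(b)) /
          max(diff(range(b)), 1e-12) * (bins - 1e-9))))
  h <- tabulate(ia + bins * (ib - 1L), bins * bins)
  p <- h / sum(h)
  px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[(seq_len(bins * bins) - 1L) %% bins + 1L][nz] *
                           py[(seq_len(bins * bins) - 1L) %/% bins + 1L][nz])))
}

eval_metric <- function(metric, a, b) {
  switch(metric, ncc = metric_ncc(a, b), mi = metric_mi(a, b),
         stop("unknown metric ", metric, call. = FALSE))
}

# --- pyramids -------------------------------------------------------------

make_pyramid <- function(v, levels) {
  out <- vector("list", levels)
  out[[levels]] <- v
  for (l in rev(seq_len(levels - 1))) out[[l]] <- downsample_volume(out[[l + 1]])
  out
}

# --- affine registration --------------------------------------------------

#' Affine registration of an individual image to a template
#'
#' Estimates the 12-parameter (translation, rotation, scale, shear) world
#' transform maximizing a similarity metric under a 3-level Gaussian-pyramid
#' schedule (rigid first at the coarsest level, then full affine at every
#' level). Deterministic for fixed inputs.
#'
# greedy single-axis scan: for each listed parameter in turn, try the
# candidate offsets and keep the best. Widens the capture range of the
# local optimizer; deterministic.
scan_axes <- function(obj, p, idx, offsets) {
  best <- obj(p)
  for (i in idx) {
    trial_p <- p
    for (o in offsets) {
      q <- trial_p
      q[i] <- q[i] + o
      val <- obj(q)
      if (val < best) {
        best <- val
        p <- q
      }
    }
  }
  p
}

#' @param moving,fixed [volume3d()] images (e.g. individual and template).
#' @param metric `"ncc"` (normalized cross-correlation, same modality) or
#'   `"mi"` (32-bin mutual information, cross-modality).
#' @param levels Pyramid levels.
#' @param maxit Optimizer iteration cap per stage.
#' @param smooth_sigma Gaussian smoothing (voxels, per axis) applied to
#'   both images before metric evaluation; widens the capture range and
#'   suppresses noise-floor cusps in the similarity landscape.
#' @return An `affine_transform` mapping fixed-space world coordinates to
#'   moving-space world coordinates.
#' @export
register_affine <- function(moving, fixed, metric = c("ncc", "mi"),
                            levels = 3L, maxit = 400L,
                            smooth_sigma = c(1, 1, 0.5)) {
  metric <- match.arg(metric)
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("registration error: constant image has no structure to register",
         call. = FALSE)
  smooth_sigma <- rep_len(smooth_sigma, 3L)
  mv0 <- if (any(smooth_sigma > 0)) smooth_volume(moving, smooth_sigma)
         else moving
  fx0 <- if (any(smooth_sigma > 0)) smooth_volume(fixed, smooth_sigma)
         else fixed
  pyr_m <- make_pyramid(mv0, levels)
  pyr_f <- make_pyramid(fx0, levels)
  dmf <- dim(fixed$data)
  center <- as.vector(voxel_to_world(fixed$affine,
                                     matrix((dmf - 1) / 2, ncol = 3)))
  vs_f <- voxel_size(fixed)
  p <- rep(0, 12)
  for (l in seq_len(levels)) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    W <- voxel_to_world(fx$affine, grid_coords(grid_geometry(fx)))
    fvals <- as.vector(fx$data)
    obj <- function(q, nq = length(q)) {
      m <- affine_from_params(replace(p, seq_len(nq), q), center)
      mvx <- world_to_voxel(mv$affine,
                            sweep(W %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+"))
      wv <- interp_coeffs(mv$data, mvx, 1L)
      -eval_metric(metric, fvals, wv)
    }
    vs <- mean(voxel_size(fx))
    # capture scan at every level: translations (up to ~6 fixed voxels)
    # and single-axis rotations (up to 10 degrees) relative to the current
    # estimate, keeping only strict improvements. The coarsest level alone
    # cannot arbitrate rotations of a smooth brain outline.
    p6 <- p[1:6]
    for (ax in 1:3)
      p6 <- scan_axes(function(q) obj(q, 6L), p6, ax,
                      vs_f[ax] * c(-6, -4, -2, -1, 1, 2, 4, 6))
    p6 <- scan_axes(function(q) obj(q, 6L), p6, 4:6,
                    pi / 180 * c(-10, -7.5, -5, -2.5, 2.5, 5, 7.5, 10))
    p[1:6] <- p6
    if (l == 1L) {
      ps6 <- c(rep(vs, 3), rep(0.05, 3))
      fit <- stats::optim(p[1:6], obj, nq = 6L, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10,
                                         parscale = ps6))
      p[1:6] <- fit$par
    }
    ps12 <- c(rep(vs, 3), rep(0.05, 3), rep(0.05, 3), rep(0.05, 3))
    fit <- stats::optim(p, obj, nq = 12L, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = ps12))
    p <- fit$par
  }
  affine_transform(affine_from_params(p, center))
}

# --- B-spline free-form deformation registration --------------------------

ffd_lattice <- function(dm, spacing) {
  nc <- floor((dm - 1) / spacing) + 4L
  offset <- 1
  list(nc = as.integer(nc), spacing = spacing, offset = offset)
}

ffd_coords <- function(vox, lat) sweep(vox, 2, lat$spacing, "/") + lat$offset

ffd_dense <- function(coefs, lat, coords_c) {
  u <- matrix(0, nrow(coords_c), 3)
  for (k in 1:3)
    u[, k] <- interp_coeffs(array(coefs[, , , k], lat$nc), coords_c, 3L)
  u
}

# second-difference bending penalty on the control lattice and its gradient
bending_energy <- function(coefs, nc) {
  e <- 0
  g <- array(0, dim(coefs))
  for (k in 1:3) {
    c3 <- array(coefs[, , , k], nc)
    for (ax in 1:3) {
      if (nc[ax] < 3) next
      d2 <- diff_axis2(c3, ax)
      e <- e + sum(d2^2)
      g[, , , k] <- g[, , , k] + diff_axis2_adj(d2, ax, nc)
    }
  }
  list(value = e, grad = 2 * g)
}

diff_axis2 <- function(a, ax) {
  n <- dim(a)[ax]
  i0 <- slice_idx(a, ax, 1:(n - 2)); i1 <- slice_idx(a, ax, 2:(n - 1))
  i2 <- slice_idx(a, ax, 3:n)
  i0 - 2 * i1 + i2
}

diff_axis2_adj <- function(d2, ax, nc) {
  out <- array(0, nc)
  n <- nc[ax]
  add_slice(out, ax, 1:(n - 2), d2) -> out
  add_slice(out, ax, 2:(n - 1), -2 * d2) -> out
  add_slice(out, ax, 3:n, d2) -> out
  out
}

slice_idx <- function(a, ax, idx) {
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

add_slice <- function(a, ax, idx, val) {
  switch(ax,
         a[idx, , ] <- a[idx, , ] + val,
         a[, idx, ] <- a[, idx, ] + val,
         a[, , idx] <- a[, , idx] + val)
  a
}

# world-space intensity gradient volumes (per moving voxel axis -> world)
gradient_volumes <- function(v) {
  g <- vector("list", 3)
  d <- v$data
  dm <- dim(d)
  vsinv <- solve(v$affine[1:3, 1:3])
  for (ax in 1:3) {
    gp <- array(0, dm)
    n <- dm[ax]
    hi <- slice_idx(d, ax, c(2:n, n)); lo <- slice_idx(d, ax, c(1, 1:(n - 1)))
    gp[] <- (hi - lo) / 2
    g[[ax]] <- gp
  }
  list(g = g, vox_to_world = vsinv)  # dI/dworld = t(vsinv) %*% dI/dvox
}

#' Nonlinear (B-spline free-form) registration refinement
#'
#' Refines an affine initialization with a cubic B-spline free-form
#' deformation on the fixed grid, minimizing sum-of-squares intensity
#' mismatch with a bending-energy penalty on the control lattice, by
#' L-BFGS-B with an analytic gradient.
#'
#' @param moving,fixed [volume3d()] images.
#' @param init Initialization: an `affine_transform` (e.g. from
#'   [register_affine()]) or a `deformation_field` (e.g. a coarser-level
#'   estimate); the free-form displacement is estimated additively on top.
#' @param grid_spacing Control-point spacing in fixed-grid voxels (>= 2).
#' @param reg_weight Bending-energy weight (dimensionless; larger gives
#'   smoother fields).
#' @param maxit L-BFGS-B iteration cap.
#' @param smooth_sigma Gaussian pre-smoothing of both images (voxels,
#'   per axis).
#' @return A `deformation_field` on the fixed grid holding the total
#'   (initial + free-form) displacement, mapping fixed-space world
#'   coordinates to moving-space world coordinates.
#' @export
register_nonlinear <- function(moving, fixed, init = identity_affine(),
                               grid_spacing = 4, reg_weight = 0.005,
                               maxit = 100L, smooth_sigma = c(1, 1, 0.5)) {
  if (any(grid_spacing < 2))
    stop("grid_spacing must be at least 2 fixed-grid voxels", call. = FALSE)
  dmf <- dim(fixed$data)
  smooth_sigma <- rep_len(smooth_sigma, 3L)
  mv <- if (any(smooth_sigma > 0)) smooth_volume(moving, smooth_sigma) else moving
  fx <- if (any(smooth_sigma > 0)) smooth_volume(fixed, smooth_sigma) else fixed
  lat <- ffd_lattice(dmf, rep_len(grid_spacing, 3L))
  vox <- grid_coords(grid_geometry(fixed))
  cc <- ffd_coords(vox, lat)
  W <- voxel_to_world(fixed$affine, vox)
  # initialization evaluated once; free-form displacement is added to it
  Wm <- if (inherits(init, "deformation_field"))
    W + field_displacement_at(init, W, extrapolate = "clamp")
  else apply_to_points(init, W)
  fvals <- as.vector(fx$data)
  nvox <- length(fvals)
  gv <- gradient_volumes(mv)
  Ainv <- solve(mv$affine)
  ncoef <- prod(lat$nc) * 3
  scale_I <- max(stats::sd(fvals), 1e-12)^2
  vs_f <- voxel_size(fixed)  # coefficients kept in voxel units for
                             # conditioning on anisotropic grids

  loss_grad <- function(cvec) {
    coefs <- array(cvec, c(lat$nc, 3L))
    u <- ffd_dense(coefs, lat, cc)
    u <- sweep(u, 2, vs_f, "*")
    mapped <- Wm + u
    mvx <- sweep(mapped %*% t(Ainv[1:3, 1:3]), 2, Ainv[1:3, 4], "+")
    wv <- interp_coeffs(mv$data, mvx, 1L)
    r <- wv - fvals
    be <- bending_energy(coefs, lat$nc)
    val <- sum(r^2) / (nvox * scale_I) + reg_weight * be$value / ncoef
    # dL/du (world mm) then splat onto control points
    gvx <- vapply(1:3, function(ax) interp_coeffs(gv$g[[ax]], mvx, 1L),
                  numeric(nvox))
    gw <- gvx %*% gv$vox_to_world  # chain: voxel gradient -> world mm
    gc <- array(0, c(lat$nc, 3L))
    for (k in 1:3) {
      gk <- 2 * r * gw[, k] * vs_f[k] / (nvox * scale_I)
      gc[, , , k] <- array(bspline_splat3_cpp(gk, cc, lat$nc, 3L), lat$nc)
    }
    list(value = val, grad = as.vector(gc + reg_weight * be$grad / ncoef))
  }

  last <- new.env()
  fn <- function(cvec) {
    res <- loss_grad(cvec)
    assign("g", res$grad, envir = last)
    res$value
  }
  gr <- function(cvec) get("g", envir = last)
  fit <- stats::optim(rep(0, ncoef), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e8))
  coefs <- array(fit$par, c(lat$nc, 3L))
  u <- sweep(ffd_dense(coefs, lat, cc), 2, vs_f, "*")
  total <- (Wm - W) + u
  deformation_field(array(total, c(dmf, 3L)), fixed$affine)
}

#' Coarse-to-fine nonlinear registration
#'
#' Runs [register_nonlinear()] on a Gaussian pyramid: the control lattice is
#' effectively coarse at the first level (capturing larger displacements)
#' and the estimate initializes the next level.
#'
#' @inheritParams register_nonlinear
#' @param levels Pyramid levels (final level = native resolution).
#' @return A `deformation_field` on the fixed grid.
#' @export
register_nonlinear_multires <- function(moving, fixed,
                                        init = identity_affine(),
                                        grid_spacing = 4, reg_weight = 0.005,
                                        maxit = 100L,
                                        smooth_sigma = c(1, 1, 0.5),
                                        levels = 3L) {
  pyr_m <- make_pyramid(moving, levels)
  pyr_f <- make_pyramid(fixed, levels)
  est <- init
  for (l in seq_len(levels)) {
    est <- register_nonlinear(pyr_m[[l]], pyr_f[[l]], init = est,
                              grid_spacing = grid_spacing,
                              reg_weight = reg_weight, maxit = maxit,
                              smooth_sigma = smooth_sigma)
  }
  est
}

# --- diffeomorphic (stationary velocity field) registration ---------------

#' Exponentiate a stationary velocity field by scaling and squaring
#'
#' @param velocity A `deformation_field` interpreted as a stationary
#'   velocity (mm per unit time) on its grid.
#' @param n_steps Number of squarings (the field is first scaled by
#'   `2^-n_steps`).
#' @return A `deformation_field` approximating the flow at time 1.
#' @export
exp_velocity <- function(velocity, n_steps = 6L) {
  geom <- field_grid(velocity)
  x <- voxel_to_world(geom$affine, grid_coords(geom))
  u <- matrix(velocity$displacement, ncol = 3) / 2^n_steps
  for (i in seq_len(n_steps)) {
    d <- deformation_field(array(u, c(geom$dim, 3L)), geom$affine)
    du <- field_displacement_at(d, x + u, extrapolate = "clamp")
    u <- u + du
  }
  deformation_field(array(u, c(geom$dim, 3L)), geom$affine)
}

# Euler integration of the same flow (reference integrator for testing)
integrate_velocity_euler <- function(velocity, n_steps = 64L) {
  geom <- field_grid(velocity)
  x <- voxel_to_world(geom$affine, grid_coords(geom))
  pos <- x
  for (i in seq_len(n_steps)) {
    u <- field_displacement_at(velocity, pos, extrapolate = "clamp")
    pos <- pos + u / n_steps
  }
  deformation_field(array(pos - x, c(geom$dim, 3L)), geom$affine)
}

#' Diffeomorphic registration on tissue probability maps
#'
#' Estimates a stationary velocity field minimizing the multi-channel
#' sum-of-squares between the fixed maps and the warped moving maps
#' (greedy gradient iterations with fluid-like Gaussian regularization of
#' the velocity), and returns its exponential computed by scaling and
#' squaring, which is diffeomorphic (positive Jacobian) by construction.
#'
#' @param moving_tpms,fixed_tpms Equal-length lists of [volume3d()] tissue
#'   probability maps with values in `[0, 1]`, sharing one grid each.
#' @param n_steps Squarings in the exponential.
#' @param iters Gradient iterations.
#' @param step_voxels Maximum velocity update per iteration (voxels).
#' @param sigma_fluid Gaussian smoothing of the velocity (voxels).
#' @return A `deformation_field` mapping fixed-space world coordinates to
#'   moving-space world coordinates, with the estimated velocity in the
#'   `velocity` element.
#' @export
register_diffeomorphic <- function(moving_tpms, fixed_tpms, n_steps = 6L,
                                   iters = 30L, step_voxels = 0.4,
                                   sigma_fluid = 1.5) {
  if (length(moving_tpms) != length(fixed_tpms) || !length(moving_tpms))
    stop("TPM lists must be non-empty and of equal length", call. = FALSE)
  for (tp in c(moving_tpms, fixed_tpms))
    if (min(tp$data) < -1e-6 || max(tp$data) > 1 + 1e-6)
      stop("TPM values must lie in [0, 1]", call. = FALSE)
  fx1 <- fixed_tpms[[1]]
  geom <- grid_geometry(fx1)
  vox <- grid_coords(geom)
  x <- voxel_to_world(geom$affine, vox)
  vs <- voxel_size(fx1)
  v <- matrix(0, nrow(x), 3)
  grads <- lapply(moving_tpms, gradient_volumes)
  Ainv <- solve(moving_tpms[[1]]$affine)
  nvox <- nrow(x)

  for (it in seq_len(iters)) {
    phi <- exp_velocity(deformation_field(array(v, c(geom$dim, 3L)),
                                          geom$affine), n_steps)
    mapped <- x + matrix(phi$displacement, ncol = 3)
    mvx <- sweep(mapped %*% t(Ainv[1:3, 1:3]), 2, Ainv[1:3, 4], "+")
    force <- matrix(0, nvox, 3)
    for (ch in seq_along(moving_tpms)) {
      wv <- interp_coeffs(moving_tpms[[ch]]$data, mvx, 1L)
      r <- wv - as.vector(fixed_tpms[[ch]]$data)
      gvx <- vapply(1:3, function(ax)
        interp_coeffs(grads[[ch]]$g[[ax]], mvx, 1L), numeric(nvox))
      force <- force + r * (gvx %*% grads[[ch]]$vox_to_world)
    }
    fmax <- max(sqrt(rowSums(force^2)))
    if (fmax < 1e-12) break
    # normalized greedy step: max velocity update = step_voxels voxels (mm)
    v <- v - force * (step_voxels * min(vs) / fmax)
    for (k in 1:3)
      v[, k] <- gauss_smooth3_cpp(v[, k], geom$dim, rep(sigma_fluid, 3))
  }
  vel <- deformation_field(array(v, c(geom$dim, 3L)), geom$affine)
  out <- exp_velocity(vel, n_steps)
  out$velocity <- vel
  out
}

# --- rigid realignment of a 4D series -------------------------------------

#' Rigidly realign a 4D series to its first volume
#'
#' Six-parameter rigid registration (least-squares on intensities) of every
#' volume to the first, followed by reslicing and voxel-wise averaging --
#' the head-motion correction applied to repeated MEMRI acquisitions before
#' parcellation.
#'
#' @param series A [series4d()].
#' @param degree Interpolation degree for reslicing.
#' @return List with `series` (realigned), `mean` (voxel-wise mean
#'   [volume3d()]), and `params` (data frame of per-volume translations in
#'   mm and rotations in radians).
#' @export
realign_series <- function(series, degree = 4) {
  vols <- series$volumes
  n <- length(vols)
  params <- data.frame(volume = seq_len(n), tx = 0, ty = 0, tz = 0,
                       rx = 0, ry = 0, rz = 0)
  if (n == 1L)
    return(list(series = series, mean = vols[[1]], params = params))
  fixed <- vols[[1]]
  dmf <- dim(fixed$data)
  center <- as.vector(voxel_to_world(fixed$affine,
                                     matrix((dmf - 1) / 2, ncol = 3)))
  vs_f <- voxel_size(fixed)
  # metric images are lightly smoothed (noise-floor cusps trap the simplex
  # on raw data); reslicing always uses the original volumes
  smooth_metric <- function(v) smooth_volume(v, c(1, 1, 0.5))
  pyr_f <- make_pyramid(smooth_metric(fixed), 2L)
  out <- vols
  fixed_flat <- stats::sd(fixed$data) == 0
  for (k in 2:n) {
    # structureless volumes cannot be registered; keep them as they are
    if (fixed_flat || stats::sd(vols[[k]]$data) == 0) next
    pyr_m <- make_pyramid(smooth_metric(vols[[k]]), 2L)
    p <- rep(0, 6)
    for (l in 1:2) {
      fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
      W <- voxel_to_world(fx$affine, grid_coords(grid_geometry(fx)))
      fvals <- as.vector(fx$data)
      obj <- function(q) {
        m <- affine_from_params(c(q, rep(0, 6)), center)
        mvx <- world_to_voxel(mv$affine,
                              sweep(W %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+"))
        wv <- interp_coeffs(mv$data, mvx, 1L)
        mean((wv - fvals)^2)
      }
      offs <- if (l == 1L) c(-2, -1, -0.5, 0.5, 1, 2)
              else c(-0.5, -0.25, -0.1, 0.1, 0.25, 0.5)
      for (ax in 1:3)
        p <- scan_axes(obj, p, ax, vs_f[ax] * offs)
      vsl <- mean(voxel_size(fx))
      fit <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = 300L, reltol = 1e-12,
                                         parscale = c(rep(vsl, 3), rep(0.05, 3))))
      p <- fit$par
    }
    params[k, 2:7] <- p
    tr <- affine_transform(affine_from_params(c(p, rep(0, 6)), center))
    out[[k]] <- resample_to_grid(vols[[k]], grid_geometry(fixed), tr,
                                 degree = degree)
  }
  realigned <- series4d(out)
  msum <- Reduce(`+`, lapply(out, function(v) v$data)) / n
  list(series = realigned, mean = volume3d(msum, fixed$affine),
       params = params)
}

# --- spatial normalization ------------------------------------------------

regrid_geometry <- function(geom, out_voxel) {
  vs <- voxel_size(list(affine = geom$affine))
  out_voxel <- rep_len(out_voxel, 3L)
  scale <- out_voxel / vs
  a <- geom$affine
  a[1:3, 1:3] <- sweep(a[1:3, 1:3], 2, scale, "*")
  dims <- pmax(1L, as.integer(ceiling((geom$dim - 1) / scale)) + 1L)
  grid_geometry(dim = dims, affine = a)
}

#' Normalize an image into standard space
#'
#' Resamples an individual image onto the standard grid through the forward
#' (standard-to-individual) transform, optionally reslicing to a new voxel
#' size -- the conventional spatial normalization against which
#' individual-space parcellation is compared.
#'
#' @param v Individual [volume3d()].
#' @param transform `affine_transform` or `deformation_field` mapping
#'   standard-space world coordinates to individual-space world coordinates.
#' @param out_voxel Target voxel size in mm (length 3), or `NULL` to keep
#'   the reference grid.
#' @param degree Interpolation degree (the pipeline's default is the
#'   4th-degree B-spline).
#' @param reference Standard-space grid (`grid_geometry` or `volume3d`);
#'   defaults to a deformation field's own grid.
#' @return A `volume3d` in standard space.
#' @export
normalize_image <- function(v, transform, out_voxel = NULL, degree = 4,
                            reference = NULL) {
  geom <- if (!is.null(reference)) grid_geometry(reference)
          else if (inherits(transform, "deformation_field")) field_grid(transform)
          else stop("an affine transform needs an explicit `reference` grid",
                    call. = FALSE)
  if (!is.null(out_voxel)) geom <- regrid_geometry(geom, out_voxel)
  resample_to_grid(v, geom, transform, degree = degree)
}
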