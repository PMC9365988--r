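# Affine, nonlinear and diffeomorphic registration; rigid realignment;
# spatial normalization. Thresholds are expressed in voxels/degrees of the
# fixed image.

test_that("affine self-registration returns near-identity", {
  b <- small_bundle()
  A <- register_affine(b$template, b$template)
  vs <- voxel_size(b$template)
  t_vox <- abs(A$matrix[1:3, 4]) / vs
  expect_lt(max(t_vox), 0.1)
  rot <- memriparc:::rotation_angles(A$matrix) * 180 / pi
  expect_lt(max(abs(rot)), 0.2)
})

test_that("affine registration recovers known translations and rotations", {
  tm <- study_bundle()$template
  vs <- voxel_size(tm)
  # known 3-voxel in-plane shift (the returned transform is the pull-back
  # map fixed -> moving, so it should equal the inverse of the applied one)
  shift_mm <- c(3 * vs[1], -2 * vs[2], 0)
  tr <- affine_transform({
    m <- diag(4); m[1:3, 4] <- shift_mm; m
  })
  moving <- resample_to_grid(tm, grid_geometry(tm), tr, degree = 3)
  A <- register_affine(moving, tm)
  err_vox <- abs(A$matrix[1:3, 4] - (-shift_mm)) / vs
  expect_lt(max(err_vox), 0.5)

  # known 5-degree in-plane rotation about the volume centre
  th <- 5 * pi / 180
  ctr <- as.vector(memriparc:::voxel_to_world(
    tm$affine, matrix((dim(tm$data) - 1) / 2, ncol = 3)))
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  R[1:3, 4] <- ctr - R[1:3, 1:3] %*% ctr
  moving2 <- resample_to_grid(tm, grid_geometry(tm), affine_transform(R),
                              degree = 3)
  A2 <- register_affine(moving2, tm)
  ang <- memriparc:::rotation_angles(A2$matrix) * 180 / pi
  expect_lt(abs(ang[3] - (-5)), 1)
  expect_lt(max(abs(ang[1:2])), 1)
})

test_that("registration rejects structureless images and is deterministic", {
  flat <- volume3d(array(1, c(16, 16, 8)))
  expect_error(register_affine(flat, flat), "registration error")
  b <- small_bundle()
  A1 <- register_affine(b$individual, b$template)
  A2 <- register_affine(b$individual, b$template)
  expect_identical(A1$matrix, A2$matrix)
})

test_that("nonlinear self-registration stays near the identity", {
  b <- small_bundle()
  d <- register_nonlinear(b$template, b$template, maxit = 30)
  vs <- voxel_size(b$template)
  disp_vox <- sweep(matrix(d$displacement, ncol = 3), 2, vs, "/")
  expect_lt(max(abs(disp_vox)), 0.25)
})

test_that("stronger bending regularization always yields smoother fields", {
  # identity init isolates the regularized free-form part; the penalty
  # controls field roughness (second differences), which must not grow
  # when its weight is increased tenfold
  b <- small_bundle()
  roughness <- function(d) {
    u <- d$displacement
    dm <- dim(u)[1:3]
    e <- 0
    for (k in 1:3) for (ax in 1:3)
      e <- e + sum(memriparc:::diff_axis2(array(u[, , , k], dm), ax)^2)
    e
  }
  d1 <- register_nonlinear(b$individual, b$template,
                           reg_weight = 0.01, maxit = 40)
  d10 <- register_nonlinear(b$individual, b$template,
                            reg_weight = 0.1, maxit = 40)
  expect_lte(roughness(d10), roughness(d1) + 1e-9)
})

test_that("nonlinear registration recovers a known smooth warp (Dice)", {
  b <- study_bundle()
  A <- register_affine(b$individual, b$template)
  d <- register_nonlinear_multires(b$individual, b$template, init = A)
  # warp the individual-space truth brain mask back to standard space and
  # compare with the template-space original
  geomT <- grid_geometry(b$template)
  wb <- resample_to_grid(b$truth_brain_mask$data, geomT, d, degree = 1)
  wbm <- binary_mask(volume3d((wb$data >= 0.5) * 1, wb$affine))
  expect_gte(dice(wbm, b$template_brain_mask)$value, 0.8)
})

test_that("velocity exponential: exp(0) = identity, agrees with Euler flow", {
  z <- deformation_field(array(0, c(12, 12, 6, 3)))
  expect_equal(max(abs(exp_velocity(z)$displacement)), 0)

  sp <- phantom_spec(shape = c(24, 24, 12), amplitude = 1, wavelength = 12)
  v <- memriparc:::sin_field(sp, c(0.3, 1.1, 2.0))
  e_ss <- exp_velocity(v, 6)
  e_eu <- memriparc:::integrate_velocity_euler(v, 64)
  disc_vox <- sweep(matrix(abs(e_ss$displacement - e_eu$displacement),
                           ncol = 3), 2, sp$voxel_size, "/")
  expect_lt(max(disc_vox), 0.05)
})

test_that("diffeomorphic registration: contracts, validates, positive Jacobian", {
  b <- small_bundle()
  expect_error(register_diffeomorphic(list(volume3d(array(2, c(4, 4, 4)))),
                                      list(volume3d(array(0.5, c(4, 4, 4))))),
               "\\[0, 1\\]")
  expect_error(register_diffeomorphic(b$tpms, list()), "equal length")

  dself <- register_diffeomorphic(b$tpms, b$tpms, iters = 8)
  vs <- voxel_size(b$template)
  expect_lt(max(abs(sweep(matrix(dself$displacement, ncol = 3), 2, vs, "/"))),
            0.25)

  d <- register_diffeomorphic(b$individual_tpms, b$tpms, iters = 15)
  dm <- dim(d$displacement)[1:3]
  u <- d$displacement
  J11 <- (memriparc:::slice_idx(array(u[, , , 1], dm), 1, c(2:dm[1], dm[1])) -
          memriparc:::slice_idx(array(u[, , , 1], dm), 1,
                                c(1, 1:(dm[1] - 1)))) / (2 * vs[1])
  # full Jacobian determinant check on the interior
  J <- array(0, c(dm, 3, 3))
  for (i in 1:3) for (j in 1:3)
    J[, , , i, j] <-
      (memriparc:::slice_idx(array(u[, , , i], dm), j, c(2:dm[j], dm[j])) -
       memriparc:::slice_idx(array(u[, , , i], dm), j,
                             c(1, 1:(dm[j] - 1)))) / (2 * vs[j])
  D <- (1 + J[, , , 1, 1]) *
         ((1 + J[, , , 2, 2]) * (1 + J[, , , 3, 3]) -
            J[, , , 2, 3] * J[, , , 3, 2]) -
       J[, , , 1, 2] * (J[, , , 2, 1] * (1 + J[, , , 3, 3]) -
                          J[, , , 2, 3] * J[, , , 3, 1]) +
       J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                          (1 + J[, , , 2, 2]) * J[, , , 3, 1])
  expect_gt(min(D[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)]), 0)
})

test_that("realignment: no-motion series, known shifts, arithmetic mean", {
  b <- small_bundle()
  v <- b$individual
  vs <- voxel_size(v)

  same <- series4d(list(v, v, v, v, v, v))
  ra <- realign_series(same)
  expect_lt(max(abs(as.matrix(ra$params[, 2:4])) / min(vs)), 0.05)
  expect_lt(max(abs(ra$mean$data - v$data)), 1e-6)

  # one-voxel translations along each axis in turn
  shifted <- list(v)
  applied <- matrix(0, 4, 3)
  for (k in 2:4) {
    sh <- c(0, 0, 0)
    sh[k - 1] <- vs[k - 1]
    applied[k, ] <- sh
    m <- diag(4); m[1:3, 4] <- sh
    shifted[[k]] <- resample_to_grid(v, grid_geometry(v),
                                     affine_transform(m), degree = 3)
  }
  ra2 <- realign_series(series4d(shifted))
  # recovered parameters are the pull-back maps: negatives of the applied
  for (k in 2:4) {
    err_vox <- abs(as.numeric(ra2$params[k, 2:4]) + applied[k, ]) / vs
    expect_lt(max(err_vox), 0.3)
  }

  consts <- lapply(1:6, function(k) volume3d(array(k, c(8, 8, 4))))
  ra3 <- realign_series(series4d(consts), degree = 1)
  expect_equal(max(abs(ra3$mean$data - 3.5)), 0, tolerance = 1e-9)

  one <- series4d(list(v))
  ra4 <- realign_series(one)
  expect_identical(ra4$mean$data, v$data)
  expect_equal(nrow(ra4$params), 1L)
})

test_that("normalization reproduces, reslices and shifts analytically", {
  b <- small_bundle()
  v <- b$individual
  nid <- normalize_image(v, identity_affine(), out_voxel = NULL,
                         reference = v)
  expect_lt(max(abs(nid$data - v$data)), 1e-6)

  nv <- normalize_image(v, identity_affine(), out_voxel = c(1, 1, 1.5),
                        reference = v)
  expect_equal(voxel_size(nv), c(1, 1, 1.5), tolerance = 1e-9)

  # pure translation of a linear in-plane ramp: analytic oracle
  dm <- c(32, 16, 8)
  ramp <- volume3d(array(rep(0:(dm[1] - 1), prod(dm[2:3])), dm),
                   diag(c(0.5, 0.5, 1, 1)))
  tr <- affine_transform({
    m <- diag(4); m[1:3, 4] <- c(1.0, 0, 0); m  # 2 voxels in x
  })
  nt <- normalize_image(ramp, tr, reference = ramp)
  interior <- nt$data[8:24, 4:13, 3:6]
  expect_lt(max(abs(interior - (ramp$data[8:24, 4:13, 3:6] + 2))), 1e-3)

  expect_error(normalize_image(v, identity_affine()), "reference")
})
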