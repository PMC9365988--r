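# Atlas splitting, mask warping, binarization, morphological refinement,
# recombination, and the assembled pipeline.

test_that("split_atlas yields one strictly binary mask per label", {
  arr <- array(0L, c(6, 6, 4))
  arr[1:2, 1:2, 1] <- 1L; arr[4:5, 4:5, 2] <- 2L; arr[1, 6, 4] <- 3L
  atlas <- label_atlas(volume3d(arr))
  masks <- split_atlas(atlas)
  expect_length(masks, 3)
  for (m in masks) expect_true(all(m$data$data %in% c(0, 1)))
  expect_equal(vapply(masks, function(m) m$source_index, integer(1)), 1:3)

  # union of masks equals the atlas nonzero support exactly, disjointly
  un <- Reduce(`+`, lapply(masks, function(m) m$data$data))
  expect_true(all(un %in% c(0, 1)))
  expect_equal(sum(un), sum(arr != 0))
  expect_identical(un != 0, arr != 0)

  expect_error(split_atlas(label_atlas(volume3d(array(0L, c(4, 4, 4))))),
               "no nonzero")
})

test_that("the study atlas splits into 66 masks covering its support", {
  b <- study_bundle()
  masks <- split_atlas(b$atlas)
  expect_length(masks, 66)
  un <- Reduce(`+`, lapply(masks, function(m) m$data$data))
  expect_true(all(un %in% c(0, 1)))
  expect_identical(un != 0, b$atlas$labels$data != 0)
})

test_that("warp_mask: identity is exact, integer shifts stay binary", {
  arr <- array(0, c(12, 12, 6)); arr[4:8, 4:8, 2:4] <- 1
  m <- binary_mask(volume3d(arr), source_index = 7L)
  geom <- grid_geometry(m$data)

  fid <- warp_mask(m, identity_affine(), geom)
  expect_lt(max(abs(fid$data$data - arr)), 1e-6)
  expect_equal(binarize(fid)$data$data, arr)

  sh <- affine_transform({ t <- diag(4); t[1, 4] <- 2; t })  # +2 voxels in x
  fsh <- warp_mask(m, sh, geom)
  shifted <- array(0, c(12, 12, 6)); shifted[2:6, 4:8, 2:4] <- 1
  expect_lt(max(abs(fsh$data$data - shifted)), 1e-6)

  # half-voxel shift of a slab: boundary columns take intermediate values
  half <- affine_transform({ t <- diag(4); t[1, 4] <- 0.5; t })
  fh <- warp_mask(m, half, geom)
  edge_vals <- fh$data$data[c(3, 8), 6, 3]
  expect_true(all(edge_vals > 0 & edge_vals < 1))
  # and they match the dense 1D spline oracle along that profile
  prof <- arr[, 6, 3]
  want <- bspline_1d_oracle(prof, (0:11) + 0.5, 4)
  expect_lt(max(abs(fh$data$data[1:11, 6, 3] - want[1:11])), 1e-6)

  # geometry mismatch between inverse field grid and target errors
  f <- deformation_field(array(0, c(5, 5, 5, 3)))
  expect_error(warp_mask(m, f, geom), "geometry")
})

test_that("binarize applies >= threshold semantics", {
  v <- volume3d(array(0.9, c(3, 3, 3)))
  expect_true(all(binarize(fuzzy_mask(v))$data$data == 1))
  v2 <- volume3d(array(c(0.49, 0.5, 0.51), c(3, 1, 1)))
  expect_equal(as.vector(binarize(fuzzy_mask(volume3d(
    array(c(0.49, 0.5, 0.51), c(3, 1, 1)))))$data$data), c(0, 1, 1))
  expect_error(binarize(fuzzy_mask(v), threshold = 0), "between 0 and 1")
  expect_error(binarize(fuzzy_mask(v), threshold = 1), "between 0 and 1")
})

test_that("refine_boundary is an opening: oracle match, idempotent, shrinking", {
  empty <- binary_mask(volume3d(array(0, c(5, 5, 3))))
  expect_equal(sum(refine_boundary(empty)$data$data), 0)

  lone <- array(0, c(3, 3, 3)); lone[2, 2, 2] <- 1
  expect_equal(sum(refine_boundary(binary_mask(volume3d(lone)))$data$data), 0)
  expect_equal(sum(refine_boundary(binary_mask(volume3d(lone)),
                                   element = "ball3D")$data$data), 0)

  set.seed(21)
  for (i in 1:8) {
    arr <- array(rbinom(7 * 7 * 3, 1, 0.55), c(7, 7, 3))
    got2 <- refine_boundary(binary_mask(volume3d(arr)))$data$data
    expect_equal(got2, brute_opening(arr, cross2d_offsets))
    got3 <- refine_boundary(binary_mask(volume3d(arr)),
                            element = "ball3D")$data$data
    expect_equal(got3, brute_opening(arr, cross3d_offsets))
    # idempotence and antiextensivity relative to the dilation of erosion
    expect_equal(refine_boundary(binary_mask(volume3d(got2)))$data$data, got2)
    expect_true(all(got2 <= brute_opening(arr, cross2d_offsets)))
  }

  # solid block: erosion-then-dilation oracle on a 7x7x3 grid
  blk <- array(0, c(9, 9, 5)); blk[2:8, 2:8, 2:4] <- 1
  expect_equal(refine_boundary(binary_mask(volume3d(blk)))$data$data,
               brute_opening(blk, cross2d_offsets))
})

test_that("slice-wise opening agrees with EBImage on 2D sections", {
  # embed the pattern in an empty frame: the two implementations differ
  # only in their (arbitrary) out-of-border conventions
  set.seed(22)
  sl <- matrix(0, 17, 17)
  sl[2:16, 2:16] <- rbinom(15 * 15, 1, 0.55)
  arr <- array(sl, c(17, 17, 1))
  got <- refine_boundary(binary_mask(volume3d(arr)))$data$data[, , 1]
  want <- as.matrix(EBImage::opening(EBImage::Image(sl),
                                     EBImage::makeBrush(3, "diamond")))
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("combine_rois resolves overlaps by membership, volume, index", {
  dm <- c(6, 6, 2)
  aff <- diag(4)
  mk <- function(vox_idx, index) {
    a <- array(0, dm); a[vox_idx] <- 1
    binary_mask(volume3d(a, aff), source_index = index)
  }
  fz <- function(mask, vals) {
    a <- mask$data$data * vals
    fuzzy_mask(volume3d(a, aff), mask$source_index)
  }

  # disjoint masks: counts preserved exactly
  m3 <- mk(1:4, 3L); m7 <- mk(20:29, 7L)
  parc <- combine_rois(list(m3, m7), list(fz(m3, 1), fz(m7, 1)))
  expect_setequal(unique(as.vector(parc$labels$data)), c(0, 3, 7))
  expect_equal(parc$per_roi$voxel_count[parc$per_roi$index == 3], 4)
  expect_equal(parc$per_roi$voxel_count[parc$per_roi$index == 7], 10)
  expect_equal(sum(parc$per_roi$conflict_voxels_resolved), 0)

  # contested voxel goes to the higher membership
  a <- mk(c(1, 2), 1L); b <- mk(c(2, 3), 2L)
  parc2 <- combine_rois(list(a, b), list(fz(a, 0.9), fz(b, 0.6)))
  expect_equal(parc2$labels$data[2], 1)
  expect_equal(sum(parc2$per_roi$conflict_voxels_resolved), 1)

  # membership tie: smaller refined volume wins
  big <- mk(1:10, 5L); small <- mk(c(10, 30, 31), 9L)
  parc3 <- combine_rois(list(big, small), list(fz(big, 0.7), fz(small, 0.7)))
  expect_equal(parc3$labels$data[10], 9)

  # volume-and-membership tie: lower index wins; order independence
  x <- mk(c(5, 6), 4L); y <- mk(c(6, 7), 2L)
  p1 <- combine_rois(list(x, y), list(fz(x, 0.8), fz(y, 0.8)))
  p2 <- combine_rois(list(y, x), list(fz(y, 0.8), fz(x, 0.8)))
  expect_equal(p1$labels$data[6], 2)
  expect_equal(p1$labels$data, p2$labels$data)

  expect_error(combine_rois(list(a, mk(4:5, 1L)),
                            list(fz(a, 1), fz(mk(4:5, 1L), 1))),
               "duplicate")
})

test_that("combined label counts never exceed refined mask counts", {
  b <- small_bundle()
  masks <- split_atlas(b$atlas)
  geom <- grid_geometry(b$individual)
  fuzzies <- lapply(masks, warp_mask, inv = b$truth_ind_to_std,
                    target = geom)
  refined <- lapply(fuzzies, function(f) refine_boundary(binarize(f)))
  parc <- combine_rois(refined, fuzzies, b$atlas$lut)
  for (j in seq_along(refined)) {
    k <- refined[[j]]$source_index
    expect_lte(parc$per_roi$voxel_count[parc$per_roi$index == k],
               sum(refined[[j]]$data$data))
  }
})

test_that("identity pipeline reproduces the atlas", {
  tm <- fixture("identity_template", function()
    make_template(phantom_spec(seed = 7L, amplitude = 0, noise_sd = 0)))
  parc <- parcellate_individual(tm$template, tm$template, tm$atlas,
                                path = "template")
  per <- per_roi_dice(tm$atlas$labels$data, parc$labels$data, 1:66)
  expect_gte(min(per, na.rm = TRUE), 0.95)
})

test_that("a 4D series input equals running on its precomputed mean", {
  b <- small_bundle()
  ra <- realign_series(b$series)
  p_series <- parcellate_individual(b$series, NULL, b$atlas,
                                    path = "template",
                                    transform = b$truth_std_to_ind)
  p_mean <- parcellate_individual(ra$mean, NULL, b$atlas,
                                  path = "template",
                                  transform = b$truth_std_to_ind)
  expect_identical(p_series$labels$data, p_mean$labels$data)
})

test_that("pipeline errors carry their stage name", {
  b <- small_bundle()
  expect_error(parcellate_individual(b$individual, NULL, b$atlas,
                                     path = "tpm"),
               "\\[register-dartel\\]")
  flat <- volume3d(array(1, dim(b$individual$data)), b$individual$affine)
  expect_error(parcellate_individual(flat, b$template, b$atlas,
                                     path = "template"),
               "\\[register-affine\\]")
})
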