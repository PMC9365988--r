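# Dice similarity, brain masking, time-course extraction, space
# comparison, and the case-control t-test.

test_that("dice matches its definition and brute-force counting", {
  arr <- array(0, c(4, 4, 2)); arr[1:2, 1:2, 1] <- 1
  a <- binary_mask(volume3d(arr))
  expect_equal(dice(a, a)$value, 1)

  brr <- array(0, c(4, 4, 2)); brr[3:4, 3:4, 2] <- 1
  b <- binary_mask(volume3d(brr))
  expect_equal(dice(a, b)$value, 0)

  # |A| = 8, |B| = 4, |A n B| = 4 -> 2*4/12
  aarr <- array(0, c(4, 4, 2)); aarr[1:8] <- 1
  barr <- array(0, c(4, 4, 2)); barr[5:8] <- 1
  d <- dice(binary_mask(volume3d(aarr)), binary_mask(volume3d(barr)))
  expect_equal(d$value, 2 * 4 / 12)
  expect_equal(c(d$mask_a_count, d$mask_b_count, d$intersection_count),
               c(8, 4, 4))

  empty <- binary_mask(volume3d(array(0, c(4, 4, 2))))
  expect_error(dice(empty, empty), "empty")
  expect_error(dice(a, binary_mask(volume3d(array(0, c(3, 3, 3))))), "grid")
})

test_that("dice is symmetric, bounded, and monotone in shared overlap", {
  set.seed(31)
  for (i in 1:50) {
    p <- random_mask_pair()
    if (sum(p$a$data$data) + sum(p$b$data$data) == 0) next
    d1 <- dice(p$a, p$b)
    expect_equal(d1$value, dice(p$b, p$a)$value)
    expect_gte(d1$value, 0); expect_lte(d1$value, 1)
    expect_equal(d1$value, dice_brute(p$a$data$data, p$b$data$data))
    # add one voxel to both masks: value never decreases
    free <- which(p$a$data$data == 0 & p$b$data$data == 0)
    if (length(free)) {
      a2 <- p$a$data$data; b2 <- p$b$data$data
      a2[free[1]] <- 1; b2[free[1]] <- 1
      d2 <- dice(binary_mask(volume3d(a2)), binary_mask(volume3d(b2)))
      expect_gte(d2$value, d1$value)
    }
  }
})

test_that("brain_mask recovers the phantom support and rejects flats", {
  b <- small_bundle()
  bm <- brain_mask(b$individual)
  expect_gte(dice(bm, b$truth_brain_mask)$value, 0.95)

  # planted bright ellipsoid in noise: one connected component
  set.seed(32)
  arr <- array(rnorm(24 * 24 * 10, 0, 1), c(24, 24, 10))
  vox <- memriparc:::grid_coords(grid_geometry(dim = c(24, 24, 10),
                                               affine = diag(4)))
  inside <- ((vox[, 1] - 11.5) / 7)^2 + ((vox[, 2] - 11.5) / 7)^2 +
            ((vox[, 3] - 4.5) / 3)^2 <= 1
  arr[array(inside, c(24, 24, 10))] <- 20
  bm2 <- brain_mask(volume3d(arr))
  lab <- memriparc:::label_components6_cpp(bm2$data$data != 0, c(24, 24, 10))
  expect_equal(max(lab), 1L)

  expect_error(brain_mask(volume3d(array(2, c(4, 4, 4)))), "constant")
})

test_that("time-course extraction is the per-volume ROI mean", {
  aff <- diag(4)
  lab <- array(0L, c(4, 4, 2)); lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  parc <- structure(list(labels = volume3d(lab, aff)), class = "parcellation")

  consts <- lapply(1:5, function(k) volume3d(array(7.5, c(4, 4, 2)), aff))
  tc <- extract_timecourse(series4d(consts), parc, 1)
  expect_equal(tc$means, rep(7.5, 5))

  v1 <- array(0, c(4, 4, 2)); v1[1, 1, 1] <- 1; v1[2, 1, 1] <- 3
  tc2 <- extract_timecourse(series4d(list(volume3d(v1, aff))), parc, 1)
  expect_equal(tc2$means, 2)

  expect_error(extract_timecourse(series4d(consts), parc, 9), "empty ROI")
})

test_that("phantom enhancement yields strictly decreasing ROI means", {
  b <- small_bundle()
  tc <- extract_timecourse(b$series, b$truth_labels, 1)
  expect_true(all(diff(tc$means) < 0))
})

test_that("compare_spaces: identity agreement and enhancement dilution", {
  b <- small_bundle()
  # identity transform on identical grids: courses agree to rounding
  parc_truth <- structure(list(labels = b$truth_labels$labels),
                          class = "parcellation")
  cs_id <- compare_spaces(b$series, parc_truth, identity_affine(),
                          b$truth_labels, 1, degree = 1)
  expect_lt(max(abs(cs_id$difference)), 1e-6)

  # genuine warp: interpolation mixes enhanced with unenhanced signal, so
  # the individual-space course dominates at every time point
  cs <- compare_spaces(b$series, parc_truth, b$truth_std_to_ind,
                       b$atlas, 1)
  expect_true(all(cs$individual$means > cs$standard$means))

  # a background-uniform ROI is interpolation-invariant
  flat_series <- series4d(lapply(1:3, function(k)
    volume3d(array(11, dim(b$individual$data)), b$individual$affine)))
  cs_flat <- compare_spaces(flat_series, parc_truth, b$truth_std_to_ind,
                            b$atlas, 1)
  expect_lt(max(abs(cs_flat$difference)), 1e-3 * 11)
})

test_that("two-sample t-test matches the closed-form oracle", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- two_sample_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ab <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ab$t, -3.6742, tolerance = 1e-4)
  expect_equal(ab$df, 4)
  ba <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba$t, -ab$t)
  expect_equal(ba$p, ab$p)

  set.seed(33)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    got <- two_sample_ttest(a, b)
    want <- ttest_pooled_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }

  w <- two_sample_ttest(c(1, 2, 3, 9), c(4, 5), variant = "welch")
  ref <- t.test(c(1, 2, 3, 9), c(4, 5))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)

  # degenerate zero-variance cases
  expect_equal(two_sample_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(two_sample_ttest(c(2, 2), c(3, 3))$p, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least two")
})

test_that("compare_groups reports means, dispersion and p per ROI", {
  va <- data.frame(DG = c(10, 11, 12, 10.5, 11.5), Hip = c(5, 6, 5.5, 6.2, 5.8))
  vb <- data.frame(DG = c(7, 8, 7.5, 8.2, 7.8, 7.1, 8.3, 7.7, 7.2, 8.0),
                   Hip = c(5.1, 5.9, 5.6, 6.1, 5.7, 5.3, 6.0, 5.5, 5.9, 5.4))
  tab <- compare_groups(va, vb)
  expect_setequal(tab$roi, c("DG", "Hip"))
  expect_true(all(c("mean_a", "sd_a", "se_a", "t", "df", "p") %in% names(tab)))
  expect_lt(tab$p[tab$roi == "DG"], 0.05)
  expect_error(compare_groups(va[0, ], vb), "non-empty")
})
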