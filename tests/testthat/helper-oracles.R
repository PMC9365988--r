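# Independent oracles and shared fixtures. Oracles are deliberately written
# as plain R re-derivations (dense linear algebra, brute-force counting) so
# they share no code path with the package internals they check.

# --- 1D B-spline interpolation oracle (dense mirror-boundary solve) -------

bspline_kernel_r <- function(t, degree) {
  a <- abs(t)
  if (degree == 3) {
    ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
           ifelse(a < 2, (2 - a)^3 / 6, 0))
  } else if (degree == 4) {
    ifelse(a < 0.5, 115 / 192 + a^2 * (-5 / 8 + a^2 / 4),
    ifelse(a < 1.5, (55 + 20 * a - 120 * a^2 + 80 * a^3 - 16 * a^4) / 96,
    ifelse(a < 2.5, (5 - 2 * a)^4 / 384, 0)))
  } else stop("oracle supports degrees 3 and 4")
}

# mirror-fold an arbitrary integer index into 0..n-1 (period 2n-2)
mirror_idx_r <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  p <- 2 * n - 2
  i <- abs(i) %% p
  ifelse(i >= n, p - i, i)
}

# interpolate `samples` (1D) at positions x (0-based) by solving the dense
# mirror-boundary coefficient system
bspline_1d_oracle <- function(samples, x, degree) {
  n <- length(samples)
  supp <- -(degree + 2):(degree + 2)
  A <- matrix(0, n, n)
  for (i in seq_len(n) - 1L) {
    for (o in supp) {
      j <- i + o
      w <- bspline_kernel_r(o, degree)
      if (w > 0) {
        jm <- mirror_idx_r(j, n)
        A[i + 1, jm + 1] <- A[i + 1, jm + 1] + w
      }
    }
  }
  coef <- solve(A, samples)
  vapply(x, function(xx) {
    js <- floor(xx) + (-(degree + 2)):(degree + 2)
    sum(vapply(js, function(j)
      coef[mirror_idx_r(j, n) + 1] * bspline_kernel_r(xx - j, degree),
      numeric(1)))
  }, numeric(1))
}

# --- brute-force binary morphology oracle ---------------------------------

brute_opening <- function(arr, offsets) {
  d <- dim(arr)
  er <- array(0, d)
  idx <- which(arr == 1, arr.ind = TRUE)
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    ok <- TRUE
    for (o in seq_len(nrow(offsets))) {
      q <- p + offsets[o, ]
      if (!inb(q) || arr[q[1], q[2], q[3]] != 1) { ok <- FALSE; break }
    }
    if (ok) er[p[1], p[2], p[3]] <- 1
  }
  di <- array(0, d)
  idx <- which(er == 1, arr.ind = TRUE)
  if (nrow(idx)) for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (o in seq_len(nrow(offsets))) {
      q <- p + offsets[o, ]
      if (inb(q)) di[q[1], q[2], q[3]] <- 1
    }
  }
  di
}

cross2d_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                         c(0, 1, 0), c(0, -1, 0))
cross3d_offsets <- rbind(cross2d_offsets, c(0, 0, 1), c(0, 0, -1))

# --- two-sample t-test formula oracle -------------------------------------

ttest_pooled_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# --- brute-force Dice -----------------------------------------------------

dice_brute <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# --- shared fixtures (built once per test run) ----------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small fast phantom for unit tests
small_spec <- function(seed = 5L)
  phantom_spec(shape = c(32L, 32L, 12L), n_rois = 12L,
               enhancement_rois = 1L, seed = seed)

small_bundle <- function()
  fixture("small_bundle", function() make_phantom(small_spec()))

# the full-size study phantom (used by acceptance and heavier tests)
study_bundle <- function()
  fixture("study_bundle", function() make_phantom(phantom_spec(seed = 42L)))

# full registered template-path parcellation of the study phantom
study_parcellation <- function()
  fixture("study_parc", function() {
    b <- study_bundle()
    parcellate_individual(b$individual, b$template, b$atlas,
                          path = "template")
  })

per_roi_dice <- function(truth_labels, parc_labels, indices) {
  vapply(indices, function(k) {
    a <- truth_labels == k
    p <- parc_labels == k
    if (!any(a) && !any(p)) return(NA_real_)
    2 * sum(a & p) / (sum(a) + sum(p))
  }, numeric(1))
}

random_mask_pair <- function(dm = c(8L, 8L, 4L)) {
  a <- array(rbinom(prod(dm), 1, 0.4), dm)
  b <- array(rbinom(prod(dm), 1, 0.4), dm)
  list(a = binary_mask(volume3d(a)), b = binary_mask(volume3d(b)))
}
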