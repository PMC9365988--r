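# Binary morphology on 3D arrays. Structuring elements are the in-plane
# city-block disc of radius 1 (the 3x3 cross applied slice-wise, suited to
# thick-slice rodent acquisitions) and its 6-connected 3D counterpart.

shift_zero <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  ok_x <- fx >= 1 & fx <= d[1]; ok_y <- fy >= 1 & fy <= d[2]
  ok_z <- fz >= 1 & fz <= d[3]
  out[sx[ok_x], sy[ok_y], sz[ok_z]] <-
    a[fx[ok_x], fy[ok_y], fz[ok_z], drop = FALSE]
  out
}

element_offsets <- function(element) {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  if (element == "ball3D") base <- rbind(base, c(0, 0, 1), c(0, 0, -1))
  base
}

erode_once <- function(a, offsets) {
  out <- array(1, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- out * shift_zero(a, -offsets[i, 1], -offsets[i, 2], -offsets[i, 3])
  out
}

dilate_once <- function(a, offsets) {
  out <- array(0, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- pmax(out, shift_zero(a, offsets[i, 1], offsets[i, 2], offsets[i, 3]))
  array(out, dim(a))
}

morph_open <- function(a, radius = 1L, element = "disc2D") {
  offs <- element_offsets(element)
  for (i in seq_len(radius)) a <- erode_once(a, offs)
  for (i in seq_len(radius)) a <- dilate_once(a, offs)
  a
}

# Otsu's threshold (maximum between-class variance) on a numeric vector
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bcv)]
}

largest_component <- function(mask_arr) {
  lab <- array(label_components6_cpp(as.logical(mask_arr), dim(mask_arr)),
               dim(mask_arr))
  if (max(lab) == 0L) return(mask_arr * 0)
  counts <- tabulate(lab[lab > 0])
  (lab == which.max(counts)) * 1
}

fill_holes <- function(mask_arr) {
  d <- dim(mask_arr)
  bg <- array(label_components6_cpp(mask_arr == 0, d), d)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  hole_labels <- setdiff(unique(as.vector(bg)), c(0L, border))
  hole <- array(as.vector(bg) %in% hole_labels, d)
  (mask_arr != 0 | hole) * 1
}

# apply per-label morphological opening to an integer label array (labels
# processed independently; disjointness is preserved)
open_labels <- function(lab_arr, radius = 1L, element = "disc2D") {
  out <- array(0L, dim(lab_arr))
  for (k in sort(unique(lab_arr[lab_arr > 0]))) {
    cell <- morph_open((lab_arr == k) * 1, radius, element)
    out[cell != 0] <- as.integer(k)
  }
  out
}
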