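# Evaluation of individual parcellations: Dice overlap, brain masking,
# ROI time-course extraction in individual vs standard space, and
# case-control two-sample t-tests.

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`: the volume-and-position agreement between two
#' segmentations, 1 for identical masks. Values above 0.8 are conventionally
#' taken as excellent agreement.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return A `dice_report` list: `value`, `variant`, `mask_a_count`,
#'   `mask_b_count`, `intersection_count`.
#' @param variant Label recording which comparison this is, e.g. `"MePa"`
#'   (image vs its parcellation), `"TempMe"` (template vs normalized image)
#'   or `"MeTemp"` (image vs individually-registered template).
#' @export
dice <- function(a, b, variant = "MePa") {
  if (!identical(dim(a$data$data), dim(b$data$data)))
    stop("masks must share one grid", call. = FALSE)
  na <- sum(a$data$data != 0)
  nb <- sum(b$data$data != 0)
  if (na + nb == 0)
    stop("Dice undefined: both masks are empty", call. = FALSE)
  ni <- sum(a$data$data != 0 & b$data$data != 0)
  structure(list(value = 2 * ni / (na + nb), variant = variant,
                 mask_a_count = na, mask_b_count = nb,
                 intersection_count = ni),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice_%s = %.4f  (|A| = %d, |B| = %d, |AnB| = %d)\n",
              x$variant, x$value, x$mask_a_count, x$mask_b_count,
              x$intersection_count))
  invisible(x)
}

#' Whole-brain foreground mask
#'
#' Otsu threshold, largest 6-connected component, morphological hole fill.
#' Used to compute whole-brain Dice agreement between an image and the
#' union of its parcellation.
#'
#' @param v A [volume3d()] with bimodal foreground/background intensities.
#' @param method Currently only `"otsu"`.
#' @return A [binary_mask()].
#' @export
brain_mask <- function(v, method = "otsu") {
  if (stats::sd(v$data) == 0)
    stop("masking error: constant image", call. = FALSE)
  thr <- otsu_threshold(as.vector(v$data))
  m <- (v$data > thr) * 1
  m <- largest_component(m)
  m <- fill_holes(m)
  binary_mask(volume3d(m, v$affine))
}

#' Union of all labelled voxels of a parcellation as a mask
#'
#' @param parc A `parcellation`.
#' @return A [binary_mask()] covering every nonzero label.
#' @export
parcellation_union <- function(parc) {
  binary_mask(volume3d((parc$labels$data != 0) * 1, parc$labels$affine))
}

#' Extract the mean ROI signal over a 4D series
#'
#' Per-volume arithmetic mean of the (untransformed) voxel intensities
#' inside one parcellation region -- the individual-space time course that
#' motivates parcellating in native space.
#'
#' @param series A [series4d()] (typically realigned).
#' @param parc A `parcellation` (or [label_atlas()]) on the series grid.
#' @param roi_index Region index to extract.
#' @param space Label recorded in the result (`"individual"` or
#'   `"standard"`).
#' @return A `timecourse` list: `roi_index`, `means` (one per volume),
#'   `space`.
#' @export
extract_timecourse <- function(series, parc, roi_index,
                               space = "individual") {
  labels <- if (inherits(parc, "label_atlas")) parc$labels else parc$labels
  sel <- labels$data == roi_index
  if (!any(sel))
    stop("empty ROI: index ", roi_index, " has no voxels", call. = FALSE)
  if (!identical(dim(labels$data), dim(series$volumes[[1]]$data)))
    stop("parcellation and series grids differ", call. = FALSE)
  means <- vapply(series$volumes, function(v) mean(v$data[sel]), numeric(1))
  structure(list(roi_index = roi_index, means = means, space = space),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> ROI ", x$roi_index, " (", x$space, "): ",
      paste(signif(x$means, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare individual-space and standard-space ROI time courses
#'
#' Extracts the ROI mean signal once in individual space (native voxels,
#' individual parcellation) and once after conventional spatial
#' normalization (each volume resampled into standard space through the
#' forward transform, ROI taken from the atlas). Interpolation during
#' normalization averages enhanced with unenhanced neighbours, so the
#' standard-space course of an enhanced ROI is expected to sit below the
#' individual-space course.
#'
#' @param series Realigned [series4d()] in individual space.
#' @param parc_individual Individual-space `parcellation`.
#' @param transform Forward transform (standard-to-individual map) used for
#'   normalization.
#' @param atlas Standard-space [label_atlas()].
#' @param roi_index Region to compare.
#' @param out_voxel Reslice size for normalization (mm), or `NULL`.
#' @param degree Interpolation degree for normalization.
#' @return List with `individual` and `standard` `timecourse`s and their
#'   per-volume `difference` (individual minus standard).
#' @export
compare_spaces <- function(series, parc_individual, transform, atlas,
                           roi_index, out_voxel = NULL, degree = 4) {
  tc_ind <- extract_timecourse(series, parc_individual, roi_index,
                               space = "individual")
  ref <- grid_geometry(atlas$labels)
  geom <- if (is.null(out_voxel)) ref else regrid_geometry(ref, out_voxel)
  atlas_std <- if (is.null(out_voxel)) atlas$labels
    else resample_to_grid(atlas$labels, geom, NULL, degree = 0)
  sel <- atlas_std$data == roi_index
  if (!any(sel))
    stop("empty ROI ", roi_index, " in standard space", call. = FALSE)
  means <- vapply(series$volumes, function(v) {
    nv <- normalize_image(v, transform, out_voxel = out_voxel,
                          degree = degree, reference = ref)
    mean(nv$data[sel])
  }, numeric(1))
  tc_std <- structure(list(roi_index = roi_index, means = means,
                           space = "standard"), class = "timecourse")
  list(individual = tc_ind, standard = tc_std,
       difference = tc_ind$means - tc_std$means)
}

#' Two-sample t-test for case-control ROI comparisons
#'
#' Pooled-variance (classic) or Welch two-sample t-test of per-subject ROI
#' means, as used to compare model against healthy animals. Two-sided.
#'
#' @param group_a,group_b Numeric vectors of per-subject values (n >= 2
#'   each).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `p`, `df`, and per-group `mean`, `sd`, `se`.
#' @export
two_sample_ttest <- function(group_a, group_b,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        se = stats::sd(x) / sqrt(length(x)))
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    # degenerate: no within-group variance
    df <- length(group_a) + length(group_b) - 2
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1, df = df,
                  group_a = summ(group_a), group_b = summ(group_b)))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = df, group_a = summ(group_a), group_b = summ(group_b)))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"))
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter),
       group_a = summ(group_a), group_b = summ(group_b))
}

#' Group comparison table for a set of ROIs
#'
#' @param values_a,values_b Data frames / matrices with one column per ROI
#'   and one row per subject.
#' @param variant Passed to [two_sample_ttest()].
#' @return Data frame with per-ROI group means, SD, SE, t, df, p.
#' @export
compare_groups <- function(values_a, values_b,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  values_a <- as.data.frame(values_a)
  values_b <- as.data.frame(values_b)
  if (!nrow(values_a) || !nrow(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  rois <- intersect(names(values_a), names(values_b))
  do.call(rbind, lapply(rois, function(r) {
    tt <- two_sample_ttest(values_a[[r]], values_b[[r]], variant)
    data.frame(roi = r,
               mean_a = tt$group_a["mean"], sd_a = tt$group_a["sd"],
               se_a = tt$group_a["se"],
               mean_b = tt$group_b["mean"], sd_b = tt$group_b["sd"],
               se_b = tt$group_b["se"],
               t = tt$t, df = tt$df, p = tt$p, row.names = NULL)
  }))
}
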