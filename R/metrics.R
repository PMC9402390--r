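#' Dice-Sorensen coefficient between two masks
#'
#' `2|X ∩ Y| / (|X| + |Y|)`, the overlap between a manual segmentation X
#' and an automated segmentation Y, ranging from 0 (no overlap) to 1
#' (perfect match). Symmetric. When both masks are empty the agreement on
#' absence is perfect and 1 is returned; when exactly one is empty, 0.
#'
#' @param X,Y `binary_mask` objects on identical geometry.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(X, Y) {
  stopifnot(is_binary_mask(X), is_binary_mask(Y))
  check_same_geometry(X, Y, "masks")
  sx <- sum(X$data)
  sy <- sum(Y$data)
  if (sx + sy == 0) return(1)
  2 * sum(X$data * Y$data) / (sx + sy)
}

boundary_points_mm <- function(mask) {
  idx <- boundary_indices_cpp(as.integer(mask$data != 0), dim(mask$data))
  sweep(idx, 2, mask$spacing, `*`)
}

#' 95th-percentile Hausdorff distance in mm
#'
#' The symmetric max of the two directed 95th-percentile distances between
#' mask boundary voxels (foreground voxels with a background 6-neighbour;
#' the volume edge counts as background), measured between voxel centres in
#' mm using the voxel spacing, so anisotropic grids are handled correctly.
#' Percentiles use linear interpolation (R quantile type 7). Undefined when
#' either mask is empty: returns `NA` with a warning rather than an error.
#'
#' @param X,Y `binary_mask` objects on identical geometry.
#' @param percentile Percentile of boundary distances, default 0.95 (1 gives
#'   the classical Hausdorff distance).
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
hd95 <- function(X, Y, percentile = 0.95) {
  stopifnot(is_binary_mask(X), is_binary_mask(Y))
  check_same_geometry(X, Y, "masks")
  if (sum(X$data) == 0 || sum(Y$data) == 0) {
    warning("hd95 undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  a <- boundary_points_mm(X)
  b <- boundary_points_mm(Y)
  dab <- quantile(min_cross_dists_cpp(a, b), percentile, type = 7,
                  names = FALSE)
  dba <- quantile(min_cross_dists_cpp(b, a), percentile, type = 7,
                  names = FALSE)
  max(dab, dba)
}

#' Mask volume in ml
#'
#' Foreground voxel count times the per-voxel volume (spacing product /
#' 1000).
#'
#' @param mask A `binary_mask`.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$data) * voxel_volume_ml(mask)
}

#' Percent volume difference
#'
#' `|pred - true| / true * 100`, the relative volume error of the
#' prediction against the manual volume. Undefined (NA) when the true
#' volume is 0.
#'
#' @param vol_pred,vol_true Volumes in ml.
#' @return Percent, or `NA` when `vol_true` is 0.
#' @export
pvd <- function(vol_pred, vol_true) {
  if (vol_true <= 0) return(NA_real_)
  abs(vol_pred - vol_true) / vol_true * 100
}

#' Detection outcome for one subject
#'
#' For a resection subject (truth supplied): false negative iff the
#' prediction has no overlap at all with the manual mask, else true
#' positive -- an overlap criterion, deliberately weaker than DSC. For a
#' control subject (`truth = NULL`): false positive iff the screened
#' prediction is non-empty, else true negative.
#'
#' @param pred Screened predicted `binary_mask`.
#' @param truth Manual `binary_mask`, or `NULL` for a control subject.
#' @return One of `"true_positive"`, `"false_negative"`, `"true_negative"`,
#'   `"false_positive"`.
#' @export
detection_outcome <- function(pred, truth = NULL) {
  stopifnot(is_binary_mask(pred))
  if (is.null(truth)) {
    if (sum(pred$data) > 0) "false_positive" else "true_negative"
  } else {
    stopifnot(is_binary_mask(truth))
    check_same_geometry(pred, truth, "masks")
    if (sum(pred$data * truth$data) == 0) "false_negative" else "true_positive"
  }
}

#' Evaluate one subject's prediction against the manual mask
#'
#' @param pred,truth `binary_mask` objects on identical geometry.
#' @param subject_id Identifier carried into the result row.
#' @return One-row data frame: `subject_id`, `dsc`, `hd95_mm`,
#'   `vol_true_ml`, `vol_pred_ml`, `pvd_pct`, `outcome`.
#' @export
evaluate_subject <- function(pred, truth, subject_id = NA_character_) {
  vt <- mask_volume_ml(truth)
  vp <- mask_volume_ml(pred)
  h <- suppressWarnings(hd95(pred, truth))
  data.frame(subject_id = subject_id,
             dsc = dsc(truth, pred),
             hd95_mm = h,
             vol_true_ml = vt,
             vol_pred_ml = vp,
             pvd_pct = pvd(vp, vt),
             outcome = detection_outcome(pred, truth),
             stringsAsFactors = FALSE)
}

iqr7 <- function(x) diff(quantile(x, c(0.25, 0.75), type = 7, names = FALSE))

#' Summarize per-subject metrics over a cohort
#'
#' Median/IQR/mean/SD of DSC and HD95 (undefined HD95 values excluded, with
#' the exclusion count reported), Pearson correlation and mean absolute
#' error between manual and predicted volumes, and detection counts.
#'
#' @param results Data frame of [evaluate_subject()] rows.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  d <- results$dsc
  h <- results$hd95_mm[!is.na(results$hd95_mm)]
  vt <- results$vol_true_ml
  vp <- results$vol_pred_ml
  r <- if (nrow(results) >= 2 && sd(vt) > 0 && sd(vp) > 0)
    cor(vt, vp) else NA_real_
  out <- list(
    n = nrow(results),
    dsc_median = median(d), dsc_iqr = iqr7(d),
    dsc_mean = mean(d), dsc_sd = if (length(d) > 1) sd(d) else NA_real_,
    hd95_median = if (length(h)) median(h) else NA_real_,
    hd95_iqr = if (length(h)) iqr7(h) else NA_real_,
    hd95_mean = if (length(h)) mean(h) else NA_real_,
    hd95_sd = if (length(h) > 1) sd(h) else NA_real_,
    hd95_n_excluded = sum(is.na(results$hd95_mm)),
    volume_pearson_r = r,
    volume_mae_ml = mean(abs(vp - vt)),
    fn_count = sum(results$outcome == "false_negative"),
    fp_count = sum(results$outcome == "false_positive"))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n=%d | DSC median %.3f IQR %.3f (mean %.3f +- %.3f)\n",
    x$n, x$dsc_median, x$dsc_iqr, x$dsc_mean,
    ifelse(is.na(x$dsc_sd), 0, x$dsc_sd)))
  cat(sprintf("  HD95 median %s mm | volume r=%s MAE=%.2f ml | FN=%d FP=%d\n",
              ifelse(is.na(x$hd95_median), "-", sprintf("%.2f", x$hd95_median)),
              ifelse(is.na(x$volume_pearson_r), "-",
                     sprintf("%.3f", x$volume_pearson_r)),
              x$volume_mae_ml, x$fn_count, x$fp_count))
  invisible(x)
}

#' Stratify accuracy by resection size
#'
#' Splits subjects into small (< threshold) and large (>= threshold) groups
#' on the manual volume -- the conventional cut is 17.92 ml -- and compares
#' DSC and PVD between groups with a two-sample t-test. An empty group
#' yields NA comparison fields.
#'
#' @param results Data frame of [evaluate_subject()] rows.
#' @param threshold_ml Volume threshold in ml (> 0), default 17.92.
#' @return List with `threshold_ml`, per-group summary data frame `groups`,
#'   and `comparisons` (metric, t statistic, p value).
#' @export
stratify_by_size <- function(results, threshold_ml = 17.92) {
  stopifnot(threshold_ml > 0)
  grp <- ifelse(results$vol_true_ml >= threshold_ml, "large", "small")
  summarise_grp <- function(g) {
    rows <- results[grp == g, , drop = FALSE]
    data.frame(group = g, n = nrow(rows),
               mean_dsc = if (nrow(rows)) mean(rows$dsc) else NA_real_,
               mean_pvd = if (nrow(rows)) mean(rows$pvd_pct, na.rm = TRUE)
                          else NA_real_,
               mean_vol_true_ml = if (nrow(rows)) mean(rows$vol_true_ml)
                                  else NA_real_,
               mean_vol_pred_ml = if (nrow(rows)) mean(rows$vol_pred_ml)
                                  else NA_real_)
  }
  groups <- rbind(summarise_grp("small"), summarise_grp("large"))
  cmp_one <- function(metric, values) {
    a <- values[grp == "small"]
    b <- values[grp == "large"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0))
      return(data.frame(metric = metric, t = NA_real_, p = NA_real_))
    tt <- t.test(a, b)
    data.frame(metric = metric, t = unname(tt$statistic), p = tt$p.value)
  }
  comparisons <- rbind(cmp_one("dsc", results$dsc),
                       cmp_one("pvd_pct", results$pvd_pct))
  list(threshold_ml = threshold_ml, groups = groups,
       comparisons = comparisons)
}
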