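PLANES <- c(axial = 3L, coronal = 2L, sagittal = 1L)

#' Min-max intensity normalization to \[0, 1\]
#'
#' Each 3D volume is normalized as a whole (not per slice): a linear,
#' order-preserving map sending the volume minimum to 0 and maximum to 1.
#' Constant volumes return all zeros with a warning. Geometry is unchanged;
#' idempotent on non-constant volumes already spanning \[0, 1\].
#'
#' @param vol A `volume_image`.
#' @return The normalized `volume_image`.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(is_volume_image(vol))
  rng <- range(vol$data)
  if (diff(rng) == 0) {
    warning("constant-valued volume; returning all zeros")
    vol$data[] <- 0
    return(vol)
  }
  vol$data <- (vol$data - rng[1]) / (rng[2] - rng[1])
  vol
}

#' Extract 2D slices of one anatomical plane at network resolution
#'
#' Slices the canonicalized volume along the plane's axis (axial = third
#' axis, coronal = second, sagittal = first), centre-pads each slice with
#' zeros to a square, and resamples it bilinearly to
#' `resolution x resolution`. The per-slice transform log is sufficient to
#' invert the mapping exactly in shape.
#'
#' @param vol A `volume_image` (normalized intensities in \[0, 1\]).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param resolution Network resolution (square), default 256.
#' @param subject_id Optional identifier carried through training.
#' @return A `slice_stack`: list with `plane`, `slices` (array
#'   `resolution x resolution x n`), `transform_log`, `slice_index_map`,
#'   `subject_id` and the source `geometry`.
#' @export
extract_slices <- function(vol, plane, resolution = 256L,
                           subject_id = NA_character_) {
  stopifnot(is_volume_image(vol))
  if (!plane %in% names(PLANES))
    stop("unknown plane '", plane, "'; expected one of ",
         paste(names(PLANES), collapse = ", "))
  axis <- PLANES[[plane]]
  d <- dim(vol$data)
  n_slices <- d[axis]
  inplane <- d[-axis]
  side <- max(inplane)
  off <- (side - inplane) %/% 2L  # centre-pad offsets (rows, cols)
  slices <- array(0, c(resolution, resolution, n_slices))
  log1 <- list(orig = inplane, side = side, offset = off,
               resolution = as.integer(resolution))
  for (k in seq_len(n_slices)) {
    sl <- switch(plane,
                 axial = vol$data[, , k],
                 coronal = vol$data[, k, ],
                 sagittal = vol$data[k, , ])
    if (inplane[1] != inplane[2]) {
      padded <- matrix(0, side, side)
      padded[off[1] + seq_len(inplane[1]), off[2] + seq_len(inplane[2])] <- sl
    } else padded <- sl
    slices[, , k] <- if (side == resolution) padded
                     else resample_bilinear_cpp(padded, resolution, resolution)
  }
  structure(list(plane = plane,
                 slices = slices,
                 transform_log = rep(list(log1), n_slices),
                 slice_index_map = seq_len(n_slices),
                 subject_id = subject_id,
                 geometry = list(dim = d, spacing = vol$spacing,
                                 affine = vol$affine)),
            class = "slice_stack")
}

#' Reassemble per-slice predictions into a 3D binary mask
#'
#' Inverts the resize and padding recorded in the stack's transform log,
#' stacks the slices along the plane's axis, and thresholds. For binary
#' input at native network resolution the round trip is exact.
#'
#' @param pred_slices Array `resolution x resolution x n` (or list of
#'   matrices) of probabilities or binary values.
#' @param stack The `slice_stack` the predictions correspond to.
#' @param geometry Optional `volume_image` supplying the output frame;
#'   defaults to the stack's recorded source geometry.
#' @param threshold Binarization threshold, default 0.5.
#' @return A `binary_mask` with the source volume's geometry.
#' @export
reassemble <- function(pred_slices, stack, geometry = NULL, threshold = 0.5) {
  stopifnot(inherits(stack, "slice_stack"))
  if (is.list(pred_slices))
    pred_slices <- array(unlist(pred_slices),
                         c(dim(pred_slices[[1]]), length(pred_slices)))
  n <- dim(pred_slices)[3]
  if (n != length(stack$slice_index_map))
    stop("got ", n, " prediction slices for a stack of ",
         length(stack$slice_index_map))
  g <- stack$geometry
  if (!is.null(geometry)) {
    stopifnot(is_volume_image(geometry))
    if (!all(dim(geometry$data) == g$dim))
      stop("geometry dimensions do not match the slice stack's source")
    g <- list(dim = dim(geometry$data), spacing = geometry$spacing,
              affine = geometry$affine)
  }
  axis <- PLANES[[stack$plane]]
  out <- array(0, g$dim)
  for (k in seq_len(n)) {
    tl <- stack$transform_log[[k]]
    sl <- pred_slices[, , k]
    if (tl$side != tl$resolution)
      sl <- resample_bilinear_cpp(sl, tl$side, tl$side)
    sl <- sl[tl$offset[1] + seq_len(tl$orig[1]),
             tl$offset[2] + seq_len(tl$orig[2]), drop = FALSE]
    sl <- (sl >= threshold) * 1
    switch(stack$plane,
           axial = out[, , k] <- sl,
           coronal = out[, k, ] <- sl,
           sagittal = out[k, , ] <- sl)
  }
  binary_mask(out, spacing = g$spacing, affine = g$affine)
}

#' Export a slice stack as 8-bit grayscale PNG files
#'
#' Inspection aid mirroring slice-wise training exports; the canonical data
#' path stays in memory.
#'
#' @param stack A `slice_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
export_slices_png <- function(stack, dir, prefix = stack$plane) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(stack$slices)[3]
  paths <- character(n)
  for (k in seq_len(n)) {
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    img <- pmin(pmax(stack$slices[, , k], 0), 1)
    png::writePNG(img, p)
    paths[k] <- p
  }
  invisible(paths)
}
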