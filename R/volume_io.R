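#' 3D volumes and binary masks with physical geometry
#'
#' A `volume_image` couples a 3D numeric array with its voxel spacing (mm),
#' a 4x4 voxel-to-world affine, and an orientation tag (e.g. `"RAS"`). A
#' `binary_mask` is a `volume_image` whose values are exactly 0 or 1; it is
#' the container for both manual and predicted segmentations.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, per-axis voxel edge length in mm (all > 0).
#' @param affine Optional 4x4 voxel-to-world matrix. Defaults to a diagonal
#'   RAS-aligned affine built from `spacing` with the origin at the first
#'   voxel.
#' @return An object of class `volume_image` (or `binary_mask`).
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- strip_attrs(data)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got shape (",
         paste(dim(data), collapse = ", "), ")")
  if (any(dim(data) < 1L)) stop("all axes must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!all(dim(affine) == c(4, 4))) stop("affine must be a 4x4 matrix")
  structure(
    list(data = data, spacing = spacing, affine = affine,
         orientation = affine_orientation(affine)),
    class = "volume_image")
}

#' @rdname volume_image
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- strip_attrs(data)
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  vol <- volume_image(data, spacing, affine)
  if (!all(vol$data %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  class(vol) <- c("binary_mask", "volume_image")
  vol
}

#' @rdname volume_image
#' @param x Object to test.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

#' @rdname volume_image
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

strip_attrs <- function(a) {
  d <- dim(a)
  a <- as.numeric(a)
  dim(a) <- d
  a
}

affine_orientation <- function(affine) {
  RNifti::orientation(structure(unclass(affine)[1:4, 1:4], code = 2L))
}

#' Make a binary mask sharing a volume's geometry
#' @param data Array of 0/1 values (or logical), same shape as `like`.
#' @param like A `volume_image` supplying spacing and affine.
#' @return A `binary_mask`.
#' @export
mask_like <- function(data, like) {
  stopifnot(is_volume_image(like))
  binary_mask(data, spacing = like$spacing, affine = like$affine)
}

#' Test that two volumes share a geometric frame
#' @param a,b `volume_image` objects.
#' @param tol Numeric tolerance on spacing/affine entries.
#' @return Logical.
#' @export
same_geometry <- function(a, b, tol = 1e-5) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

check_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(what, " must share dimensions, spacing and affine")
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file as stored on disk: no intensity rescaling
#' and no reorientation (use [canonicalize()] for a fixed frame).
#'
#' @param path Path to a NIfTI-1 file.
#' @param mask Logical; validate and class the result as a [binary_mask()].
#' @return A `volume_image` (or `binary_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got shape (", paste(d, collapse = ", "),
         "): 4D time series are not supported")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  affine <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (mask) binary_mask(as.array(img), spacing, affine)
  else volume_image(as.array(img), spacing, affine)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written with an integer datatype (foreground strictly 1);
#' images keep floating point. The affine is stored in both qform and sform.
#'
#' @param vol A `volume_image` or `binary_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume_image(vol))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  dtype <- if (is_binary_mask(vol)) "int16" else "float"
  tryCatch(
    RNifti::writeNifti(img, path, datatype = dtype),
    error = function(e) stop("could not write ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Reorient a volume to the canonical RAS frame
#'
#' Permutes and flips the voxel grid so axes run left->right, posterior->
#' anterior, inferior->superior, updating the affine so every voxel keeps its
#' world coordinates. Plane names are defined against this frame: "axial"
#' slices along the third axis, "coronal" along the second, "sagittal" along
#' the first. Idempotent; pure re-indexing (the multiset of voxel values is
#' unchanged).
#'
#' @param vol A `volume_image` or `binary_mask`.
#' @return The reoriented object, with `orientation == "RAS"`.
#' @export
canonicalize <- function(vol) {
  stopifnot(is_volume_image(vol))
  if (abs(det(vol$affine[1:3, 1:3])) < 1e-12)
    stop("affine is not invertible; cannot determine orientation")
  if (identical(vol$orientation, "RAS")) return(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::orientation(img) <- "RAS"
  spacing <- abs(RNifti::pixdim(img))[1:3]
  affine <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (is_binary_mask(vol)) binary_mask(as.array(img), spacing, affine)
  else volume_image(as.array(img), spacing, affine)
}

#' Physical volume of one voxel, in ml
#'
#' The product of the three spacing components (mm^3) divided by 1000.
#'
#' @param vol A `volume_image`, `binary_mask` or `parcellation`.
#' @return Scalar volume in ml (1 mm^3 = 0.001 ml).
#' @export
voxel_volume_ml <- function(vol) {
  prod(vol$spacing) / 1000
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, orientation %s\n",
              class(x)[1], paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing, trim = TRUE), collapse = ", "),
              x$orientation))
  invisible(x)
}
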