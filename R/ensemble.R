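#' Ensemble fusion and post-processing configuration
#'
#' @param min_votes Votes (of 3 plane models) required to include a voxel;
#'   the standard rule is 2.
#' @param component_mode `"largest"` keeps the single largest connected
#'   component (appropriate when one contiguous resection site is expected);
#'   `"min_size"` keeps every component with at least
#'   `min_component_voxels` voxels (for multi-site cases).
#' @param min_component_voxels Minimum component size for `"min_size"` mode.
#' @param detection_threshold_ml Total-volume screen: predictions below this
#'   are treated as "no resection detected" (0.5 ml equals 500 voxels at
#'   1 mm isotropic).
#' @param connectivity 6 or 26 (default) neighbourhood for components.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(min_votes = 2L, component_mode = "largest",
                            min_component_voxels = 50L,
                            detection_threshold_ml = 0.5,
                            connectivity = 26L) {
  min_votes <- as.integer(min_votes)
  if (min_votes < 1 || min_votes > 3) stop("min_votes must be 1, 2 or 3")
  if (!component_mode %in% c("largest", "min_size"))
    stop("component_mode must be 'largest' or 'min_size'")
  if (min_component_voxels < 0 || detection_threshold_ml < 0)
    stop("thresholds must be >= 0")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(min_votes = min_votes, component_mode = component_mode,
                 min_component_voxels = as.integer(min_component_voxels),
                 detection_threshold_ml = detection_threshold_ml,
                 connectivity = as.integer(connectivity)),
            class = "ensemble_config")
}

#' Per-voxel majority vote across the three plane masks
#'
#' A voxel enters the fused mask iff it is labelled by at least `min_votes`
#' of the three plane segmentations. The output is always contained in the
#' union of the inputs and contains their intersection.
#'
#' @param mask_ax,mask_cor,mask_sag `binary_mask` objects on one geometry.
#' @param min_votes Required votes (1-3), default 2.
#' @return The fused `binary_mask`.
#' @export
majority_vote <- function(mask_ax, mask_cor, mask_sag, min_votes = 2L) {
  stopifnot(is_binary_mask(mask_ax), is_binary_mask(mask_cor),
            is_binary_mask(mask_sag))
  check_same_geometry(mask_ax, mask_cor, "plane masks")
  check_same_geometry(mask_ax, mask_sag, "plane masks")
  if (min_votes < 1 || min_votes > 3) stop("min_votes must be 1, 2 or 3")
  votes <- mask_ax$data + mask_cor$data + mask_sag$data
  mask_like((votes >= min_votes) * 1, mask_ax)
}

#' Label 3D connected components of a mask
#'
#' @param mask A `binary_mask`.
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is_binary_mask(mask))
  lab <- label_components_cpp(as.integer(mask$data != 0),
                              dim(mask$data), as.integer(connectivity))
  array(lab, dim(mask$data))
}

#' Remove isolated voxels by connected-component filtering
#'
#' In `"largest"` mode exactly the largest component of a non-empty mask
#' survives (ties resolved to the first-labelled, i.e. lowest-index,
#' component); in `"min_size"` mode all components with at least
#' `min_component_voxels` voxels survive. Never adds voxels; an empty mask
#' passes through empty.
#'
#' @param mask A `binary_mask`.
#' @param config An [ensemble_config()].
#' @return The filtered `binary_mask`.
#' @export
filter_components <- function(mask, config = ensemble_config()) {
  stopifnot(is_binary_mask(mask))
  if (sum(mask$data) == 0) return(mask)
  lab <- label_components(mask, config$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- if (config$component_mode == "largest") which.max(sizes)
          else which(sizes >= config$min_component_voxels)
  mask_like(array(as.numeric(lab %in% keep), dim(lab)), mask)
}

#' Screen out sub-threshold detections
#'
#' Declares a detection only when the total mask volume reaches the
#' configured threshold; otherwise the mask is emptied, the behaviour used
#' to reject the small spurious segmentations seen in control scans.
#'
#' @param mask A post-filtering `binary_mask`.
#' @param config An [ensemble_config()].
#' @return List with `detected` (logical), `mask` (emptied when not
#'   detected), and `volume_ml` of the input mask.
#' @export
screen_detection <- function(mask, config = ensemble_config()) {
  stopifnot(is_binary_mask(mask))
  vol <- mask_volume_ml(mask)
  detected <- vol >= config$detection_threshold_ml && vol > 0
  if (!detected) mask <- mask_like(array(0, dim(mask$data)), mask)
  list(detected = detected, mask = mask, volume_ml = vol)
}

#' Segment a volume with the three-plane ensemble
#'
#' Runs the full inference chain: intensity normalization, per-plane slice
#' extraction at each model's resolution, slice prediction, 3D reassembly,
#' per-voxel majority vote, connected-component filtering, and the
#' detection-size screen, in that order.
#'
#' @param models List of three `plane_model`s covering axial, coronal and
#'   sagittal (any order; matched by their `plane` field).
#' @param vol A canonicalized `volume_image`.
#' @param config An [ensemble_config()].
#' @param resolution Network resolution used for slice extraction; defaults
#'   to the trained slice size if recorded, else 256.
#' @return List with `mask` (`binary_mask` on the input geometry),
#'   `detected`, `volume_ml` (post-screen volume), `plane_volumes_ml`, and
#'   the `config` used.
#' @export
segment_volume <- function(models, vol, config = ensemble_config(),
                           resolution = NULL) {
  stopifnot(is_volume_image(vol))
  planes <- vapply(models, function(m) m$plane, "")
  if (!setequal(planes, names(PLANES)))
    stop("models must cover axial, coronal and sagittal exactly once")
  names(models) <- planes
  if (is.null(resolution)) {
    resolution <- models[[1]]$resolution
    if (is.null(resolution)) resolution <- 256L
  }
  nv <- normalize_intensity(vol)
  plane_masks <- lapply(names(PLANES), function(pl) {
    m <- models[[pl]]
    stack <- extract_slices(nv, pl, resolution = resolution)
    probs <- predict_slices(m, stack)
    reassemble(probs, stack, geometry = vol,
               threshold = m$config$binarization_threshold)
  })
  names(plane_masks) <- names(PLANES)
  fused <- majority_vote(plane_masks$axial, plane_masks$coronal,
                         plane_masks$sagittal, config$min_votes)
  filtered <- filter_components(fused, config)
  screened <- screen_detection(filtered, config)
  list(mask = screened$mask, detected = screened$detected,
       volume_ml = mask_volume_ml(screened$mask),
       plane_volumes_ml = vapply(plane_masks, mask_volume_ml, 0),
       config = config)
}
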