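#' Specification of a synthetic brain phantom
#'
#' Describes a brain-like ellipsoidal volume with concentric tissue bands
#' (cortex / white-matter / ventricle analogues), an optional ellipsoidal
#' hypointense cavity standing in for a CSF-filled resection, optional
#' failure-mode artifacts (a hyperintense inclusion emulating blood product
#' or ablation necrosis, and a thin surgical tract), additive Gaussian noise,
#' and a toy parcellation that includes a designated "hippocampus" region
#' overlapping the cavity site. The same spec with the same seed always
#' produces a bit-identical phantom.
#'
#' @param grid_shape Integer length-3, voxel grid dimensions.
#' @param spacing_mm Numeric length-3, voxel spacing in mm.
#' @param brain_axes_mm Semi-axes of the brain ellipsoid in mm.
#' @param tissue_levels Named intensities in (0, 1] for `cortex`, `white`
#'   and `ventricle` bands (pre-noise).
#' @param cavity_center_frac Cavity centre as signed fractions of the brain
#'   semi-axes (0 = brain centre).
#' @param cavity_radius_mm Cavity radius in mm: scalar (sphere) or length-3
#'   semi-axes. 0 gives a control-like phantom with an empty mask.
#' @param cavity_intensity Pre-noise intensity inside the cavity; should lie
#'   below all tissue levels (CSF-like).
#' @param noise_sd Standard deviation of additive Gaussian noise; the result
#'   is clipped to \[0, 1\].
#' @param artifact_flags Named logical list with entries
#'   `hyperintense_inclusion` and `surgical_tract`.
#' @param seed Integer seed controlling the noise realisation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         brain_axes_mm = c(26, 30, 24),
                         tissue_levels = c(cortex = 0.5, white = 0.75,
                                           ventricle = 0.25),
                         cavity_center_frac = c(0.35, 0.2, 0.1),
                         cavity_radius_mm = 10,
                         cavity_intensity = 0.08,
                         noise_sd = 0.03,
                         artifact_flags = list(hyperintense_inclusion = FALSE,
                                               surgical_tract = FALSE),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  stopifnot(length(brain_axes_mm) == 3L, all(brain_axes_mm > 0))
  if (any(tissue_levels <= 0) || any(tissue_levels > 1))
    stop("tissue_levels must lie in (0, 1]")
  if (cavity_intensity < 0 || cavity_intensity > 1)
    stop("cavity_intensity must lie in [0, 1]")
  r <- as.numeric(cavity_radius_mm)
  if (length(r) == 1L) r <- rep(r, 3L)
  if (length(r) != 3L || any(r < 0))
    stop("cavity_radius_mm must be a non-negative scalar or length-3")
  ctr <- as.numeric(cavity_center_frac)
  stopifnot(length(ctr) == 3L)
  # sufficient containment condition: after scaling axes to the unit ball,
  # the cavity lies inside a ball of radius max(r/A) centred at ctr
  if (any(r > 0)) {
    slack <- sqrt(sum(ctr^2)) + max(r / brain_axes_mm)
    if (slack > 1)
      stop("cavity does not fit inside the brain ellipsoid ",
           sprintf("(centre+radius extent %.2f of semi-axis)", slack))
  }
  if (!is.list(artifact_flags) ||
      !all(c("hyperintense_inclusion", "surgical_tract") %in%
           names(artifact_flags)))
    stop("artifact_flags needs hyperintense_inclusion and surgical_tract")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 brain_axes_mm = as.numeric(brain_axes_mm),
                 tissue_levels = tissue_levels,
                 cavity_center_frac = ctr, cavity_radius_mm = r,
                 cavity_intensity = cavity_intensity, noise_sd = noise_sd,
                 artifact_flags = artifact_flags, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinates in mm relative to the grid centre, one matrix per
# axis direction (broadcastable arrays)
phantom_coords <- function(spec) {
  n <- spec$grid_shape
  sp <- spec$spacing_mm
  lapply(1:3, function(k) (seq_len(n[k]) - 1 - (n[k] - 1) / 2) * sp[k])
}

# squared ellipsoid norm field for centre (mm) and semi-axes (mm)
ellipsoid_field <- function(coords, center, axes, shape) {
  x <- (coords[[1]] - center[1]) / axes[1]
  y <- (coords[[2]] - center[2]) / axes[2]
  z <- (coords[[3]] - center[3]) / axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# noise-free scene construction shared by phantom and control paths
phantom_scene <- function(spec) {
  coords <- phantom_coords(spec)
  A <- spec$brain_axes_mm
  lv <- spec$tissue_levels
  e_brain <- ellipsoid_field(coords, c(0, 0, 0), A, spec$grid_shape)
  brain <- e_brain <= 1
  vol <- array(0, spec$grid_shape)
  vol[brain & e_brain > 0.85^2] <- lv[["cortex"]]
  vol[e_brain <= 0.85^2] <- lv[["white"]]
  # two lateral-ventricle analogues flanking the midline
  for (sgn in c(-1, 1)) {
    vent <- ellipsoid_field(coords, c(sgn * 0.35 * A[1], 0.05 * A[2],
                                      0.1 * A[3]),
                            c(4, 9, 5), spec$grid_shape) <= 1
    vol[vent & brain] <- lv[["ventricle"]]
  }
  cavity_center <- spec$cavity_center_frac * A
  mask <- array(0, spec$grid_shape)
  if (all(spec$cavity_radius_mm > 0)) {
    cav <- ellipsoid_field(coords, cavity_center, spec$cavity_radius_mm,
                           spec$grid_shape) <= 1
    cav <- cav & brain
    vol[cav] <- spec$cavity_intensity
    mask[cav] <- 1
  }
  list(vol = vol, mask = mask, brain = brain, coords = coords,
       cavity_center_mm = cavity_center)
}

phantom_noise <- function(vol, spec) {
  if (spec$noise_sd <= 0) return(vol)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  out <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim(vol))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Generate a synthetic brain phantom with ground truth
#'
#' Builds the noise-free scene, applies any requested artifacts, then adds
#' seeded Gaussian noise. The ground-truth mask is exactly the voxel set
#' whose intensity was replaced by the cavity intensity before noise (plus
#' tract voxels when the surgical-tract artifact is on, mirroring the manual
#' convention of including tracts in the segmentation).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (`volume_image`), `mask`
#'   (`binary_mask`), `parcellation` ([parcellation()]), and the analytic
#'   `cavity` and `hippocampus` ellipsoid parameters (centre and semi-axes
#'   in mm, relative to the grid centre).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sc <- phantom_scene(spec)
  vol <- sc$vol
  mask <- sc$mask
  flags <- spec$artifact_flags
  if (isTRUE(flags$hyperintense_inclusion) || isTRUE(flags$surgical_tract)) {
    art <- apply_artifacts(vol, mask, sc, spec)
    vol <- art$vol
    mask <- art$mask
  }
  vol <- phantom_noise(vol, spec)
  parc <- build_parcellation(sc, spec)
  vi <- volume_image(vol, spec$spacing_mm)
  list(volume = vi,
       mask = mask_like(mask, vi),
       parcellation = parc$parcellation,
       cavity = list(center_mm = sc$cavity_center_mm,
                     radii_mm = spec$cavity_radius_mm),
       hippocampus = parc$hippocampus,
       spec = spec)
}

# Hyperintense inclusion: bright blob strictly inside the cavity.
# Surgical tract: thin tube (~1 voxel radius) from the cavity surface to the
# brain surface, dark like the cavity; tract voxels are added to the mask.
apply_artifacts <- function(vol, mask, sc, spec) {
  flags <- spec$artifact_flags
  if (isTRUE(flags$hyperintense_inclusion)) {
    if (sum(mask) == 0)
      stop("hyperintense inclusion requested but the cavity mask is empty")
    incl <- ellipsoid_field(sc$coords, sc$cavity_center_mm,
                            pmax(0.4 * spec$cavity_radius_mm, 1),
                            spec$grid_shape) <= 1
    incl <- incl & mask == 1
    vol[incl] <- 0.95
  }
  if (isTRUE(flags$surgical_tract)) {
    if (sum(mask) == 0)
      stop("surgical tract requested but the cavity mask is empty")
    A <- spec$brain_axes_mm
    ctr <- sc$cavity_center_mm
    dir <- if (sqrt(sum(ctr^2)) < 1e-6) c(1, 0, 0) else ctr / sqrt(sum(ctr^2))
    # segment from cavity centre out to the brain surface along 'dir'
    tmax <- 1 / sqrt(sum((dir / A)^2))
    x <- sc$coords[[1]]; y <- sc$coords[[2]]; z <- sc$coords[[3]]
    n <- spec$grid_shape
    dist2 <- array(Inf, n)
    for (t in seq(0, tmax, by = min(spec$spacing_mm) / 2)) {
      p <- t * dir
      d2 <- outer(outer((x - p[1])^2, (y - p[2])^2, `+`), (z - p[3])^2, `+`)
      dist2 <- pmin(dist2, d2)
    }
    tube <- dist2 <= (1.4 * min(spec$spacing_mm))^2 & sc$brain
    vol[tube & mask == 0] <- spec$cavity_intensity
    mask[tube] <- 1
  }
  list(vol = vol, mask = mask)
}

#' Add failure-mode artifacts to an existing phantom
#'
#' Applies the artifacts named in `spec$artifact_flags` to a phantom volume
#' and its ground-truth mask: a hyperintense inclusion strictly inside the
#' cavity and/or a thin surgical tract from the cavity to the brain surface.
#' Tract voxels are added to the ground-truth mask.
#'
#' @param vol `volume_image` produced from `spec` (noise-free or noisy).
#' @param mask The phantom's ground-truth `binary_mask`.
#' @param spec The [phantom_spec()] (its `artifact_flags` are honoured).
#' @return List with updated `volume` and `mask`.
#' @export
add_artifacts <- function(vol, mask, spec) {
  stopifnot(is_volume_image(vol), is_binary_mask(mask),
            inherits(spec, "phantom_spec"))
  check_same_geometry(vol, mask, "volume and mask")
  sc <- phantom_scene(spec)
  art <- apply_artifacts(vol$data, mask$data, sc, spec)
  list(volume = volume_image(art$vol, vol$spacing, vol$affine),
       mask = mask_like(art$mask, vol))
}

#' Generate a control phantom (no cavity)
#'
#' @param spec A [phantom_spec()]; its cavity settings are ignored.
#' @return A `volume_image` identical to `generate_phantom` output for the
#'   same spec with cavity radius 0.
#' @export
generate_control <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec$cavity_radius_mm <- c(0, 0, 0)
  spec$artifact_flags <- list(hyperintense_inclusion = FALSE,
                              surgical_tract = FALSE)
  generate_phantom(spec)$volume
}

#' Toy multi-region parcellation
#'
#' Divides the brain interior into eight octant wedges plus an interior
#' "hippocampus" ellipsoid placed at the cavity site, so that remnant
#' volumetry has an aligned label field with a region the cavity actually
#' removes. Labels tile the brain interior exactly (mutually exclusive,
#' jointly covering).
#'
#' @param data 3D integer array of labels (0 = background).
#' @param labels Named character vector: names are region names, values or
#'   positions give integer labels; internally stored as a label -> name map.
#' @param spacing,affine Geometry, as for [volume_image()].
#' @return A `parcellation` object.
#' @export
parcellation <- function(data, labels, spacing = c(1, 1, 1), affine = NULL) {
  d <- dim(data)
  data <- as.integer(round(data))
  dim(data) <- d
  if (length(dim(data)) != 3L) stop("parcellation data must be 3D")
  if (any(data < 0)) stop("labels must be non-negative integers")
  present <- sort(unique(data[data > 0]))
  lab_ids <- as.integer(names(labels))
  if (any(is.na(lab_ids))) stop("labels must be named by integer label id")
  missing <- setdiff(present, lab_ids)
  if (length(missing) > 0)
    stop("labels present in data but unnamed: ", paste(missing, collapse = ", "))
  geom <- volume_image(array(0, dim(data)), spacing, affine)
  structure(list(data = data, labels = labels, spacing = geom$spacing,
                 affine = geom$affine, orientation = geom$orientation),
            class = "parcellation")
}

build_parcellation <- function(sc, spec) {
  n <- spec$grid_shape
  coords <- sc$coords
  xs <- coords[[1]] >= 0
  ys <- coords[[2]] >= 0
  zs <- coords[[3]] >= 0
  oct <- outer(outer(as.integer(xs), 2L * as.integer(ys), `+`),
               4L * as.integer(zs), `+`) + 1L
  lab <- array(0L, n)
  lab[sc$brain] <- oct[sc$brain]
  hip_axes <- pmin(c(7, 11, 7), spec$brain_axes_mm * 0.45)
  hip_center <- sc$cavity_center_mm
  hip <- ellipsoid_field(coords, hip_center, hip_axes, n) <= 1 & sc$brain
  lab[hip] <- 9L
  names_map <- c(
    "1" = "left_posterior_inferior",  "2" = "right_posterior_inferior",
    "3" = "left_anterior_inferior",   "4" = "right_anterior_inferior",
    "5" = "left_posterior_superior",  "6" = "right_posterior_superior",
    "7" = "left_anterior_superior",   "8" = "right_anterior_superior",
    "9" = "hippocampus")
  list(parcellation = parcellation(lab, names_map, spec$spacing_mm),
       hippocampus = list(center_mm = hip_center, radii_mm = hip_axes))
}

#' Generate a reproducible phantom cohort
#'
#' Draws per-subject cavity radii and centre positions uniformly from the
#' stated ranges (with rejection so every cavity fits inside the brain) and
#' builds one phantom per subject. Seeds are derived from `seed`, so the
#' cohort is bit-reproducible.
#'
#' @param n Number of subjects (>= 1).
#' @param spec_ranges List with `cavity_radius_mm = c(min, max)` and
#'   optionally `cavity_center_frac` as a 2x3 matrix of per-axis ranges.
#' @param seed Integer seed.
#' @param base_spec Template [phantom_spec()] supplying all other settings.
#' @return List of per-subject lists (`subject_id`, `volume`, `mask`,
#'   `parcellation`, `cavity`, `hippocampus`, `cavity_volume_ml`).
#' @export
generate_cohort <- function(n, spec_ranges = list(cavity_radius_mm = c(7, 14)),
                            seed = 1L, base_spec = phantom_spec()) {
  stopifnot(n >= 1)
  rr <- spec_ranges$cavity_radius_mm
  if (is.null(rr) || length(rr) != 2L || any(rr < 0) || rr[2] < rr[1])
    stop("spec_ranges$cavity_radius_mm must be a valid c(min, max) range")
  cr <- spec_ranges$cavity_center_frac
  if (is.null(cr)) cr <- rbind(c(-0.3, 0.3), c(-0.3, 0.3), c(-0.3, 0.3))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      radius <- runif(1, rr[1], rr[2])
      ctr <- vapply(1:3, function(k) runif(1, cr[k, 1], cr[k, 2]), 0)
      ok <- sqrt(sum(ctr^2)) + radius / min(base_spec$brain_axes_mm) <= 1
      if (ok) break
      if (try == 200) stop("could not place a cavity inside the brain; ",
                           "narrow the centre/radius ranges")
    }
    sp <- base_spec
    sp$cavity_radius_mm <- rep(radius, 3)
    sp$cavity_center_frac <- ctr
    sp$seed <- as.integer(seed %% 10000L) * 100000L + i
    ph <- generate_phantom(sp)
    ph$subject_id <- sprintf("sub-%03d", i)
    ph$cavity_volume_ml <- mask_volume_ml(ph$mask)
    subjects[[i]] <- ph
  }
  subjects
}
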