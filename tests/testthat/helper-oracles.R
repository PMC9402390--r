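# Independent brute-force oracles and small fixture builders.

# random binary mask on a given grid
random_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1)) {
  binary_mask(array(as.numeric(runif(prod(dims)) < p), dims),
              spacing = spacing)
}

# Dice via explicit voxel-index set operations
oracle_dsc <- function(X, Y) {
  xi <- which(X$data == 1)
  yi <- which(Y$data == 1)
  if (length(xi) + length(yi) == 0) return(1)
  2 * length(intersect(xi, yi)) / (length(xi) + length(yi))
}

# boundary voxels found by explicit 6-neighbour checks in R
oracle_boundary <- function(mask) {
  d <- dim(mask$data)
  idx <- which(mask$data == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  on_boundary <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (m in seq_len(6)) {
      q <- nb[m, ]
      if (any(q < 1) || any(q > d)) return(TRUE)
      if (mask$data[q[1], q[2], q[3]] == 0) return(TRUE)
    }
    FALSE
  }, TRUE)
  idx[on_boundary, , drop = FALSE]
}

# HD95 via the full pairwise distance matrix between boundary sets
oracle_hd95 <- function(X, Y, percentile = 0.95) {
  a <- oracle_boundary(X)
  b <- oracle_boundary(Y)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  am <- sweep(a, 2, X$spacing, `*`)
  bm <- sweep(b, 2, Y$spacing, `*`)
  dmat <- outer(seq_len(nrow(am)), seq_len(nrow(bm)),
                Vectorize(function(i, j) sqrt(sum((am[i, ] - bm[j, ])^2))))
  dab <- quantile(apply(dmat, 1, min), percentile, type = 7, names = FALSE)
  dba <- quantile(apply(dmat, 2, min), percentile, type = 7, names = FALSE)
  max(dab, dba)
}

# per-voxel vote counting by explicit triple loop
oracle_vote <- function(a, b, c, min_votes) {
  d <- dim(a$data)
  out <- array(0, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        v <- a$data[i, j, k] + b$data[i, j, k] + c$data[i, j, k]
        out[i, j, k] <- as.numeric(v >= min_votes)
      }
  out
}

# a small, fast phantom spec for unit tests
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(32, 32, 32), brain_axes_mm = c(13, 14, 12),
         cavity_center_frac = c(0.3, 0.15, 0.1), cavity_radius_mm = 5),
    list(...))
  do.call(phantom_spec, args)
}

# a plane model that always predicts (near-)zero probability everywhere
zero_model <- function(plane, resolution = 32L) {
  cfg <- train_config(epochs = 1L, encoder_depth = 1L, base_channels = 1L,
                      seed = 1L)
  net <- resectr:::unet_create(1L, 1L, 1L)
  w <- resectr:::unet_get_weights(net)
  last <- length(w)
  w[[last]]$W[] <- 0
  w[[last]]$b[] <- -10
  structure(list(plane = plane, weights = w, config = cfg,
                 history = data.frame(), best_epoch = 0L,
                 best_val_dsc = NA_real_, resolution = as.integer(resolution)),
            class = "plane_model")
}

# Reference hippocampal percent-resected by subvoxel numeric integration of
# the generating ellipsoids (independent of the voxelized mask), plus a
# one-voxel-shell tolerance: the fraction of the hippocampus lying within
# half a voxel diagonal of the cavity surface.
analytic_hippocampus_pct <- function(subject, refine = 3L) {
  sp <- subject$spec
  n <- sp$grid_shape
  sub <- lapply(1:3, function(k) {
    step <- sp$spacing_mm[k] / refine
    lo <- -(n[k] - 1) / 2 * sp$spacing_mm[k] - sp$spacing_mm[k] / 2 + step / 2
    lo + step * (seq_len(n[k] * refine) - 1)
  })
  enorm2 <- function(center, axes) {
    x <- (sub[[1]] - center[1]) / axes[1]
    y <- (sub[[2]] - center[2]) / axes[2]
    z <- (sub[[3]] - center[3]) / axes[3]
    outer(outer(x^2, y^2, `+`), z^2, `+`)
  }
  in_brain <- enorm2(c(0, 0, 0), sp$brain_axes_mm) <= 1
  in_hip <- enorm2(subject$hippocampus$center_mm,
                   subject$hippocampus$radii_mm) <= 1 & in_brain
  e_cav <- enorm2(subject$cavity$center_mm, subject$cavity$radii_mm)
  in_cav <- e_cav <= 1
  pct <- 100 * sum(in_hip & in_cav) / sum(in_hip)
  half_diag <- sqrt(sum(sp$spacing_mm^2)) / 2
  band <- abs(sqrt(e_cav) - 1) * min(subject$cavity$radii_mm) <= half_diag
  tol_pct <- 100 * sum(in_hip & band) / sum(in_hip)
  list(pct = pct, tol_pct = max(tol_pct, 1))
}
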