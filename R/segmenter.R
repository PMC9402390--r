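#' Training configuration for a plane segmenter
#'
#' Defaults mirror the clinical training protocol (Adam, learning rate 1e-4,
#' batch size 16, 50 epochs, flips plus rotations up to 10 degrees and
#' shifts up to 10% of width/height). Desk-scale runs typically lower
#' `epochs` and raise `learning_rate`; see the methods vignette.
#'
#' @param epochs Number of training epochs (>= 0).
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Slices per optimization step.
#' @param augmentation List: `hflip`, `vflip` (logical),
#'   `max_rotation_deg` (degrees), `max_shift_frac` (fraction of each
#'   dimension, in \[0, 0.5\]).
#' @param encoder_depth Number of encoder/decoder resolution levels.
#' @param base_channels Channel width of the first encoder level; doubles
#'   per level.
#' @param pretrained_encoder Must be `FALSE`: no pretrained weights are
#'   bundled; the encoder is a from-scratch convolutional stack.
#' @param loss_name Currently `"soft_dice"`.
#' @param seed Integer seed for weight init, shuffling and augmentation.
#' @param binarization_threshold Probability threshold in (0, 1) used when
#'   binarizing predictions.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-4, batch_size = 16L,
                         augmentation = list(hflip = TRUE, vflip = TRUE,
                                             max_rotation_deg = 10,
                                             max_shift_frac = 0.10),
                         encoder_depth = 2L, base_channels = 4L,
                         pretrained_encoder = FALSE,
                         loss_name = "soft_dice", seed = 42L,
                         binarization_threshold = 0.5) {
  stopifnot(epochs >= 0, learning_rate > 0, batch_size >= 1,
            encoder_depth >= 1, base_channels >= 1)
  aug <- utils::modifyList(list(hflip = TRUE, vflip = TRUE,
                                max_rotation_deg = 10, max_shift_frac = 0.10),
                           augmentation)
  if (aug$max_shift_frac < 0 || aug$max_shift_frac > 0.5)
    stop("max_shift_frac must lie in [0, 0.5]")
  if (aug$max_rotation_deg < 0) stop("max_rotation_deg must be >= 0")
  if (isTRUE(pretrained_encoder))
    stop("no pretrained encoder weights are bundled; ",
         "set pretrained_encoder = FALSE")
  if (!identical(loss_name, "soft_dice"))
    stop("unsupported loss: ", loss_name)
  if (binarization_threshold <= 0 || binarization_threshold >= 1)
    stop("binarization_threshold must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), augmentation = aug,
                 encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 pretrained_encoder = FALSE, loss_name = loss_name,
                 seed = as.integer(seed),
                 binarization_threshold = binarization_threshold),
            class = "train_config")
}

#' Subject-level k-fold cross-validation splits
#'
#' Partitions subjects into k groups; fold i uses group i as the test set,
#' the next group (cyclically) as validation, and the rest for training --
#' a 3:1:1 split for k = 5 up to integer rounding. Every subject appears in
#' exactly one fold's test set, and all slices of a subject stay in one set,
#' so subject-level leakage is impossible by construction.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds (2 <= k <= number of subjects).
#' @param seed Integer seed for the shuffle.
#' @return List of `fold_split` objects with `fold_id`, `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  n <- length(subject_ids)
  if (k < 2 || k > n)
    stop("k must satisfy 2 <= k <= number of subjects (", n, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(subject_ids)
  groups <- split(shuffled, sort(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(i) {
    test <- groups[[i]]
    val <- groups[[if (i == k) 1L else i + 1L]]
    train <- setdiff(shuffled, c(test, val))
    fs <- list(fold_id = i, train_ids = train, val_ids = val, test_ids = test)
    class(fs) <- "fold_split"
    stopifnot(length(intersect(train, val)) == 0,
              length(intersect(train, test)) == 0,
              length(intersect(val, test)) == 0)
    fs
  })
}

#' Apply one random paired augmentation draw
#'
#' Draws flips, a rotation and shifts from the config bounds (using R's
#' RNG stream, so the caller controls reproducibility via `set.seed`) and
#' applies the identical geometric transform to image and mask. The image
#' is interpolated bilinearly, the mask nearest-neighbour so it stays
#' binary; out-of-bounds regions fill with 0.
#'
#' @param image_slice,mask_slice Same-shaped matrices.
#' @param config A [train_config()].
#' @return List with transformed `image`, `mask` and the sampled `params`.
#' @export
augment_pair <- function(image_slice, mask_slice, config) {
  if (!all(dim(image_slice) == dim(mask_slice)))
    stop("image and mask slices must have identical shape")
  aug <- config$augmentation
  hflip <- isTRUE(aug$hflip) && runif(1) < 0.5
  vflip <- isTRUE(aug$vflip) && runif(1) < 0.5
  rot <- if (aug$max_rotation_deg > 0)
    runif(1, -aug$max_rotation_deg, aug$max_rotation_deg) else 0
  sh <- if (aug$max_shift_frac > 0)
    runif(2, -aug$max_shift_frac, aug$max_shift_frac) else c(0, 0)
  shift_i <- sh[1] * nrow(image_slice)
  shift_j <- sh[2] * ncol(image_slice)
  identity_draw <- !hflip && !vflip && rot == 0 && all(sh == 0)
  if (identity_draw)
    return(list(image = image_slice, mask = mask_slice,
                params = list(hflip = FALSE, vflip = FALSE, rotation_deg = 0,
                              shift_frac = c(0, 0))))
  img <- warp_slice_cpp(image_slice, rot, shift_i, shift_j, hflip, vflip,
                        nearest = FALSE)
  msk <- warp_slice_cpp(mask_slice, rot, shift_i, shift_j, hflip, vflip,
                        nearest = TRUE)
  list(image = img, mask = msk,
       params = list(hflip = hflip, vflip = vflip, rotation_deg = rot,
                     shift_frac = sh))
}

# Flatten a list of (image = slice_stack, mask = slice_stack) pairs into
# matching (res, res, N) arrays, checking plane consistency.
collect_stacks <- function(pairs, plane = NULL) {
  if (length(pairs) == 0) return(NULL)
  imgs <- list(); msks <- list(); subjects <- character(0)
  for (p in pairs) {
    stopifnot(inherits(p$image, "slice_stack"), inherits(p$mask, "slice_stack"))
    if (is.null(plane)) plane <- p$image$plane
    if (!identical(p$image$plane, plane) || !identical(p$mask$plane, plane))
      stop("all stacks must share one plane (expected ", plane, ")")
    if (dim(p$image$slices)[3] != dim(p$mask$slices)[3])
      stop("image and mask stacks have different slice counts")
    imgs[[length(imgs) + 1]] <- p$image$slices
    msks[[length(msks) + 1]] <- p$mask$slices
    subjects <- c(subjects, p$image$subject_id)
  }
  res <- dim(imgs[[1]])[1:2]
  X <- array(unlist(imgs), c(res, sum(vapply(imgs, function(a) dim(a)[3], 0L))))
  Y <- array(unlist(msks), dim(X))
  list(X = X, Y = (Y >= 0.5) * 1, plane = plane, subjects = unique(subjects))
}

global_dice <- function(pred, truth) {
  i2 <- 2 * sum(pred * truth)
  s <- sum(pred) + sum(truth)
  if (s == 0) 1 else i2 / s
}

predict_array <- function(net, X, batch = 16L) {
  n <- dim(X)[3]
  out <- array(0, dim(X))
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    out[, , idx] <- unet_predict_batch(net, X[, , idx, drop = FALSE])
  }
  out
}

fit_unet <- function(train_pairs, val_pairs, config, init_weights = NULL,
                     plane = NULL, prior_history = NULL, verbose = FALSE) {
  tr <- collect_stacks(train_pairs, plane)
  if (is.null(tr) || dim(tr$X)[3] == 0) stop("empty training set")
  va <- collect_stacks(val_pairs, tr$plane)
  if (!is.null(va) && length(intersect(tr$subjects, va$subjects)) > 0)
    stop("training and validation sets share subjects: ",
         paste(intersect(tr$subjects, va$subjects), collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  net <- unet_create(config$encoder_depth, config$base_channels, config$seed)
  if (!is.null(init_weights)) unet_set_weights(net, init_weights)
  n <- dim(tr$X)[3]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dsc = numeric(0))
  best <- list(weights = unet_get_weights(net), val_dsc = -Inf, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      nb <- length(idx)
      Xb <- array(0, c(dim(tr$X)[1:2], nb))
      Yb <- array(0, c(dim(tr$X)[1:2], nb))
      for (s in seq_len(nb)) {
        a <- augment_pair(tr$X[, , idx[s]], tr$Y[, , idx[s]], config)
        Xb[, , s] <- a$image
        Yb[, , s] <- a$mask
      }
      losses <- c(losses, unet_train_batch(net, Xb, Yb, config$learning_rate))
    }
    val_dsc <- NA_real_
    if (!is.null(va)) {
      probs <- predict_array(net, va$X, config$batch_size)
      val_dsc <- global_dice((probs >= config$binarization_threshold) * 1,
                             va$Y)
      if (val_dsc > best$val_dsc)
        best <- list(weights = unet_get_weights(net), val_dsc = val_dsc,
                     epoch = epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dsc = val_dsc))
    if (verbose)
      message(sprintf("[%s] epoch %d/%d loss %.4f val DSC %s", tr$plane,
                      epoch, config$epochs, mean(losses),
                      ifelse(is.na(val_dsc), "-", sprintf("%.3f", val_dsc))))
  }
  if (is.null(va) || config$epochs == 0)
    best <- list(weights = unet_get_weights(net),
                 val_dsc = NA_real_, epoch = config$epochs)
  if (!is.null(prior_history) && nrow(prior_history) > 0)
    history <- rbind(prior_history,
                     transform(history, epoch = epoch + max(prior_history$epoch)))
  structure(list(plane = tr$plane, weights = best$weights, config = config,
                 history = history, best_epoch = best$epoch,
                 best_val_dsc = best$val_dsc, resolution = dim(tr$X)[1]),
            class = "plane_model")
}

#' Train a single-plane segmentation model
#'
#' Optimizes a compact encoder-decoder network with Adam on a soft-Dice
#' loss, applying random paired augmentation each epoch, and returns the
#' parameter state that maximized validation Dice across epochs (model
#' selection follows the validation-DSC objective). Deterministic given the
#' config seed.
#'
#' @param train_pairs,val_pairs Lists of `list(image = slice_stack,
#'   mask = slice_stack)` pairs from disjoint subject sets, one plane.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `plane_model` with `plane`, `weights`, `config`, per-epoch
#'   `history` (train loss, validation DSC) and `best_epoch`.
#' @export
train <- function(train_pairs, val_pairs = list(), config = train_config(),
                  verbose = FALSE) {
  fit_unet(train_pairs, val_pairs, config, verbose = verbose)
}

#' Continue training from an existing model
#'
#' Resumes optimization from the model's current parameters (no
#' re-initialization) on new data, with the same best-validation-DSC
#' selection rule. With `config$epochs = 0` the parameters are returned
#' unchanged.
#'
#' @param model A trained `plane_model`.
#' @param new_train_pairs,new_val_pairs Stacks for the new cohort.
#' @param config A [train_config()] for the resumed run.
#' @param verbose Print per-epoch progress.
#' @return An updated `plane_model` with history appended.
#' @export
fine_tune <- function(model, new_train_pairs, new_val_pairs = list(),
                      config = model$config, verbose = FALSE) {
  stopifnot(inherits(model, "plane_model"))
  if (config$epochs == 0) {
    model$config <- config
    return(model)
  }
  fit_unet(new_train_pairs, new_val_pairs, config,
           init_weights = model$weights, plane = model$plane,
           prior_history = model$history, verbose = verbose)
}

#' Predict per-slice cavity probabilities
#'
#' Pure at inference: the same slice always yields the same probabilities.
#'
#' @param model A `plane_model`.
#' @param stack A `slice_stack` of the model's plane.
#' @return Array `resolution x resolution x n` of probabilities in \[0, 1\].
#' @export
predict_slices <- function(model, stack) {
  stopifnot(inherits(model, "plane_model"), inherits(stack, "slice_stack"))
  if (!identical(model$plane, stack$plane))
    stop("stack plane (", stack$plane, ") does not match model plane (",
         model$plane, ")")
  net <- unet_create(model$config$encoder_depth, model$config$base_channels,
                     model$config$seed)
  unet_set_weights(net, model$weights)
  predict_array(net, stack$slices, model$config$batch_size)
}

#' Save / load a plane model
#'
#' One file per plane with the config and training history embedded.
#'
#' @param model A `plane_model`.
#' @param path File path.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plane_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "plane_model")) stop("not a plane_model file: ", path)
  model
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> plane=%s, depth=%d, base=%d, best epoch %d (val DSC %s)\n",
              x$plane, x$config$encoder_depth, x$config$base_channels,
              x$best_epoch,
              ifelse(is.na(x$best_val_dsc), "-",
                     sprintf("%.3f", x$best_val_dsc))))
  invisible(x)
}
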