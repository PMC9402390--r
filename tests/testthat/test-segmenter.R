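test_that("subject-level folds follow the 3:1:1 protocol with full coverage", {
  ids <- sprintf("sub-%03d", 1:45)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$test_ids, 9)
    expect_length(f$val_ids, 9)
    expect_length(f$train_ids, 27)
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_length(intersect(f$val_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
  }
  # each subject is held out for testing exactly once across folds
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0)
  # deterministic from the seed
  expect_identical(folds, make_folds(ids, k = 5, seed = 3))
  expect_error(make_folds(ids[1:3], k = 5), "2 <= k")
})

test_that("augmentation applies one transform to both members within bounds", {
  cfg <- train_config()
  # disabled augmentation is the identity
  off <- train_config(augmentation = list(hflip = FALSE, vflip = FALSE,
                                          max_rotation_deg = 0,
                                          max_shift_frac = 0))
  img <- matrix(runif(32 * 32), 32)
  msk <- matrix(0, 32, 32); msk[4:10, 4:10] <- 1
  out <- augment_pair(img, msk, off)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)
  # a pure horizontal flip moves a left-sided cavity right in BOTH members
  flip_cfg <- train_config(augmentation = list(hflip = TRUE, vflip = FALSE,
                                               max_rotation_deg = 0,
                                               max_shift_frac = 0))
  img2 <- matrix(0, 32, 32); img2[10:14, 2:6] <- 0.9
  msk2 <- matrix(0, 32, 32); msk2[10:14, 2:6] <- 1
  set.seed(99)
  repeat {
    out2 <- augment_pair(img2, msk2, flip_cfg)
    if (out2$params$hflip) break
  }
  expect_equal(out2$mask, msk2[, 32:1])
  expect_equal(out2$image, img2[, 32:1])
  # sampled magnitudes respect the configured bounds
  set.seed(100)
  draws <- replicate(300, augment_pair(img, msk, cfg)$params,
                     simplify = FALSE)
  rots <- vapply(draws, `[[`, 0, "rotation_deg")
  shifts <- t(vapply(draws, `[[`, c(0, 0), "shift_frac"))
  expect_lte(max(abs(rots)), 10)
  expect_lte(max(abs(shifts)), 0.10)
  # masks remain binary after warping
  set.seed(101)
  aug <- augment_pair(img, msk, cfg)
  expect_true(all(aug$mask %in% c(0, 1)))
  expect_error(augment_pair(img, msk[1:16, ], cfg), "identical shape")
})

make_pair <- function(ph, plane, res, id) {
  nv <- normalize_intensity(ph$volume)
  list(image = extract_slices(nv, plane, res, subject_id = id),
       mask = extract_slices(ph$mask, plane, res, subject_id = id))
}

test_that("the network can overfit a single slice (capacity sanity)", {
  ph <- generate_phantom(tiny_spec())
  pair <- make_pair(ph, "axial", 32, "s1")
  k <- which.max(apply(pair$mask$slices, 3, sum))
  one <- list(image = pair$image, mask = pair$mask)
  one$image$slices <- pair$image$slices[, , rep(k, 8), drop = FALSE]
  one$mask$slices <- pair$mask$slices[, , rep(k, 8), drop = FALSE]
  one$image$transform_log <- pair$image$transform_log[rep(k, 8)]
  one$image$slice_index_map <- 1:8
  cfg <- train_config(epochs = 150, learning_rate = 1e-3, batch_size = 8,
                      augmentation = list(hflip = FALSE, vflip = FALSE,
                                          max_rotation_deg = 0,
                                          max_shift_frac = 0),
                      seed = 7)
  model <- train(list(one), list(), cfg)
  probs <- predict_slices(model, one$image)
  pred <- (probs[, , 1] >= 0.5) * 1
  truth <- one$mask$slices[, , 1]
  expect_gt(2 * sum(pred * truth) / (sum(pred) + sum(truth)), 0.95)
})

test_that("training records history, selects the best-validation epoch, and is deterministic", {
  ph1 <- generate_phantom(tiny_spec(seed = 31))
  ph2 <- generate_phantom(tiny_spec(seed = 32, cavity_center_frac = c(0.2, 0.25, 0)))
  ph3 <- generate_phantom(tiny_spec(seed = 33, cavity_radius_mm = 4))
  cfg <- train_config(epochs = 3, learning_rate = 1e-3, batch_size = 16,
                      seed = 11)
  tr <- list(make_pair(ph1, "axial", 32, "a"), make_pair(ph2, "axial", 32, "b"))
  va <- list(make_pair(ph3, "axial", 32, "c"))
  m1 <- train(tr, va, cfg)
  expect_equal(nrow(m1$history), 3)
  expect_equal(m1$best_epoch,
               m1$history$epoch[which.max(m1$history$val_dsc)])
  m2 <- train(tr, va, cfg)
  expect_identical(m1$weights, m2$weights)
  # probabilities lie in [0, 1] and prediction is pure
  p1 <- predict_slices(m1, va[[1]]$image)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_slices(m1, va[[1]]$image))
  # plane mismatch and leakage guards
  cor_stack <- make_pair(ph3, "coronal", 32, "c")
  expect_error(predict_slices(m1, cor_stack$image), "plane")
  expect_error(train(tr, list(make_pair(ph1, "axial", 32, "a")), cfg),
               "share subjects")
  expect_error(train(list(), va, cfg), "empty training set")
})

test_that("fine-tuning resumes from existing weights", {
  ph1 <- generate_phantom(tiny_spec(seed = 41))
  ph2 <- generate_phantom(tiny_spec(seed = 42, cavity_center_frac = c(-0.25, -0.2, 0.1)))
  cfg <- train_config(epochs = 25, learning_rate = 1e-3, seed = 12)
  m <- train(list(make_pair(ph1, "axial", 32, "a")), list(), cfg)
  # zero additional epochs leaves parameters untouched
  cfg0 <- cfg; cfg0$epochs <- 0L
  m0 <- fine_tune(m, list(make_pair(ph2, "axial", 32, "b")), list(), cfg0)
  expect_identical(m0$weights, m$weights)
  # resumed training starts from the trained state, not a re-init:
  # first-epoch loss is far below the from-scratch first-epoch loss
  cfg2 <- cfg; cfg2$epochs <- 2L
  mft <- fine_tune(m, list(make_pair(ph1, "axial", 32, "a")), list(), cfg2)
  first_scratch <- m$history$train_loss[1]
  first_resumed <- mft$history$train_loss[nrow(m$history) + 1]
  expect_lt(first_resumed, first_scratch / 2)
  # determinism
  mft2 <- fine_tune(m, list(make_pair(ph1, "axial", 32, "a")), list(), cfg2)
  expect_identical(mft$weights, mft2$weights)
})

test_that("training loss trends downward on an easy fixture", {
  ph <- generate_phantom(tiny_spec(seed = 51))
  cfg <- train_config(epochs = 6, learning_rate = 1e-3, seed = 13)
  m <- train(list(make_pair(ph, "axial", 32, "a")), list(), cfg)
  slope <- coef(lm(train_loss ~ epoch, data = m$history))[["epoch"]]
  expect_lt(slope, 0)
})

test_that("config validation rejects out-of-contract settings", {
  expect_error(train_config(pretrained_encoder = TRUE), "pretrained")
  expect_error(train_config(augmentation = list(max_shift_frac = 0.8)),
               "max_shift_frac")
  expect_error(train_config(binarization_threshold = 1.2), "threshold")
  expect_error(train_config(learning_rate = 0), "learning_rate > 0")
})
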