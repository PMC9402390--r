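cube_mask <- function(dims, from, size) {
  z <- array(0, dims)
  z[from[1]:(from[1] + size[1] - 1), from[2]:(from[2] + size[2] - 1),
    from[3]:(from[3] + size[3] - 1)] <- 1
  binary_mask(z)
}

test_that("Dice follows its closed form on constructed masks", {
  dims <- c(20, 12, 12)
  X <- cube_mask(dims, c(2, 2, 2), c(10, 10, 10))
  expect_equal(dsc(X, X), 1)
  # same cube shifted 5 voxels: overlap 500, sizes 1000 each -> 0.5
  Y <- cube_mask(dims, c(7, 2, 2), c(10, 10, 10))
  expect_equal(dsc(X, Y), 0.5)
  # disjoint masks
  Z <- cube_mask(dims, c(13, 2, 2), c(2, 2, 2))
  expect_equal(dsc(X, Z), 0)
  # empty-mask conventions
  E <- binary_mask(array(0, dims))
  expect_equal(dsc(E, E), 1)
  expect_equal(dsc(X, E), 0)
  expect_error(dsc(X, binary_mask(array(0, c(4, 4, 4)))), "share dimensions")
})

test_that("Dice and HD95 are symmetric and match brute-force oracles", {
  set.seed(71)
  for (rep in 1:12) {
    X <- random_mask(c(4, 4, 4), 0.4)
    Y <- random_mask(c(4, 4, 4), 0.4)
    expect_equal(dsc(X, Y), dsc(Y, X))
    expect_equal(dsc(X, Y), oracle_dsc(X, Y), tolerance = 1e-12)
  }
  for (rep in 1:8) {
    dims <- sample(5:10, 3, replace = TRUE)
    sp <- sample(c(1, 1, 2), 3)
    X <- random_mask(dims, 0.3, spacing = sp)
    Y <- random_mask(dims, 0.3, spacing = sp)
    if (sum(X$data) == 0 || sum(Y$data) == 0) next
    h <- hd95(X, Y)
    expect_equal(h, hd95(Y, X))
    expect_equal(h, oracle_hd95(X, Y), tolerance = 1e-9)
  }
})

test_that("HD95 handles identity, separation, anisotropy and empties", {
  dims <- c(10, 10, 10)
  X <- cube_mask(dims, c(3, 3, 3), c(3, 3, 3))
  expect_equal(hd95(X, X), 0)
  # two single voxels 3 apart at 1 mm isotropic
  a <- array(0, dims); a[2, 2, 2] <- 1
  b <- array(0, dims); b[5, 2, 2] <- 1
  expect_equal(hd95(binary_mask(a), binary_mask(b)), 3)
  # one index apart along a 3 mm axis
  a2 <- binary_mask(a, spacing = c(1, 1, 3))
  b2 <- array(0, dims); b2[2, 2, 3] <- 1
  expect_equal(hd95(a2, binary_mask(b2, spacing = c(1, 1, 3))), 3)
  # empty mask: NA with a warning, not an error
  E <- binary_mask(array(0, dims))
  expect_warning(h <- hd95(X, E), "empty")
  expect_true(is.na(h))
})

test_that("HD95 is translation-invariant and grows with whole-voxel shifts", {
  dims <- c(24, 12, 12)
  X <- cube_mask(dims, c(2, 2, 2), c(4, 4, 4))
  base <- hd95(X, cube_mask(dims, c(4, 2, 2), c(4, 4, 4)))
  # translate both masks identically: distance unchanged
  Xt <- cube_mask(dims, c(6, 5, 5), c(4, 4, 4))
  Yt <- cube_mask(dims, c(8, 5, 5), c(4, 4, 4))
  expect_equal(hd95(Xt, Yt), base)
  # monotone growth as one mask moves farther away
  ds <- vapply(c(2, 6, 10, 14), function(s)
    hd95(X, cube_mask(dims, c(2 + s, 2, 2), c(4, 4, 4))), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("volumes and PVD follow voxel-count arithmetic", {
  z <- array(0, c(12, 12, 12)); z[1:1000] <- 1
  expect_equal(mask_volume_ml(binary_mask(z)), 1.0)
  z5 <- array(0, c(12, 12, 12)); z5[1:500] <- 1
  expect_equal(mask_volume_ml(binary_mask(z5)), 0.5)
  z1 <- array(0, c(6, 6, 6)); z1[1:100] <- 1
  expect_equal(mask_volume_ml(binary_mask(z1, spacing = c(2, 2, 2))), 0.8)
  expect_equal(pvd(100, 100), 0)
  expect_equal(pvd(75, 100), 25)
  expect_equal(pvd(0, 10), 100)
  expect_true(is.na(pvd(5, 0)))
})

test_that("detection outcomes implement the overlap criterion", {
  dims <- c(10, 10, 10)
  truth <- cube_mask(dims, c(2, 2, 2), c(4, 4, 4))
  # a single overlapping voxel is a true positive (not DSC-based)
  graze <- array(0, dims); graze[5, 5, 5] <- 1; graze[8:9, 8:9, 8:9] <- 1
  expect_equal(detection_outcome(binary_mask(graze), truth), "true_positive")
  miss <- cube_mask(dims, c(7, 7, 7), c(3, 3, 3))
  expect_equal(detection_outcome(miss, truth), "false_negative")
  empty <- binary_mask(array(0, dims))
  expect_equal(detection_outcome(empty, NULL), "true_negative")
  big <- cube_mask(dims, c(2, 2, 2), c(9, 9, 8))
  expect_equal(detection_outcome(big, NULL), "false_positive")
})

test_that("cohort summaries aggregate metrics and exclusions correctly", {
  rows <- rbind(
    evaluate_subject(cube_mask(c(10, 10, 10), c(2, 2, 2), c(4, 4, 4)),
                     cube_mask(c(10, 10, 10), c(2, 2, 2), c(4, 4, 4)), "s1"),
    evaluate_subject(cube_mask(c(10, 10, 10), c(3, 3, 3), c(4, 4, 4)),
                     cube_mask(c(10, 10, 10), c(2, 2, 2), c(4, 4, 4)), "s2"))
  s <- summarize_cohort(rows)
  expect_equal(s$n, 2)
  expect_equal(s$dsc_median, median(rows$dsc))
  expect_equal(s$fn_count, 0)
  # perfectly equal volumes: MAE 0 (r undefined for zero-variance series)
  expect_equal(s$volume_mae_ml, mean(abs(rows$vol_pred_ml - rows$vol_true_ml)))
  # hand-built frame: median of {0.8, 0.9} and hd95 exclusion accounting
  df <- data.frame(subject_id = c("a", "b"), dsc = c(0.8, 0.9),
                   hd95_mm = c(2, NA), vol_true_ml = c(10, 20),
                   vol_pred_ml = c(11, 19), pvd_pct = c(10, 5),
                   outcome = "true_positive")
  s2 <- summarize_cohort(df)
  expect_equal(s2$dsc_median, 0.85)
  expect_equal(s2$hd95_n_excluded, 1)
  expect_equal(s2$hd95_median, 2)
  expect_equal(s2$volume_pearson_r, 1)
  expect_equal(s2$volume_mae_ml, 1)
})

test_that("size stratification splits at the threshold and compares groups", {
  df <- data.frame(subject_id = letters[1:6],
                   dsc = c(0.7, 0.75, 0.72, 0.85, 0.9, 0.88),
                   hd95_mm = 2, vol_true_ml = c(4.19, 6, 10, 33.5, 25, 40),
                   vol_pred_ml = c(4, 5, 9, 30, 26, 39),
                   pvd_pct = c(20, 25, 22, 8, 5, 7),
                   outcome = "true_positive")
  st <- stratify_by_size(df, threshold_ml = 17.92)
  expect_equal(st$groups$n, c(3, 3))
  expect_equal(st$groups$mean_dsc[st$groups$group == "large"],
               mean(c(0.85, 0.9, 0.88)))
  expect_true(all(is.finite(st$comparisons$p)))
  # volumes {4.19, 33.5} split into one small and one large subject
  df2 <- df[c(1, 4), ]
  st2 <- stratify_by_size(df2)
  expect_equal(st2$groups$n, c(1, 1))
  expect_true(all(is.na(st2$comparisons$t)))
  # everything below threshold: empty large group, sentinel comparisons
  st3 <- stratify_by_size(df[1:3, ])
  expect_equal(st3$groups$n[st3$groups$group == "large"], 0)
  expect_true(all(is.na(st3$comparisons$t)))
})
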