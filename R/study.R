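#' Run the desk-scale phantom study end to end
#'
#' Generates a phantom cohort, takes the first fold of a subject-level
#' 5-fold 3:1:1 split (so for 25 subjects: 15 train, 5 validation, 5 test),
#' trains one plane model per anatomical plane, segments the held-out test
#' phantoms and a set of control phantoms with the majority-vote ensemble,
#' and evaluates every reported quantity: per-subject DSC, HD95, volumes,
#' PVD and detection outcome; the cohort summary; and the hippocampal
#' remnant comparison between manual (ground-truth) and predicted masks.
#'
#' Default problem sizes are desk scale: 64^3 phantoms at 1 mm isotropic,
#' network resolution 64, a depth-2/width-4 network trained 10 epochs at
#' learning rate 1e-3. See the methods vignette for the rationale.
#'
#' @param n_subjects Cavity subjects in the cohort (split 3:1:1).
#' @param n_controls Control phantoms (no cavity) for false-positive
#'   screening.
#' @param seed Integer seed controlling everything: cohort, splits, weight
#'   init, augmentation, batching.
#' @param epochs,learning_rate,batch_size,base_channels,encoder_depth
#'   Training settings (see [train_config()]).
#' @param grid Voxel grid edge length of the cubic phantoms.
#' @param resolution Network slice resolution.
#' @param radius_range_mm Cavity radius range for the cohort.
#' @param ensemble An [ensemble_config()].
#' @param verbose Print progress.
#' @return List with `models`, `fold`, `results` (per-test-subject metric
#'   rows), `summary` (`cohort_summary`), `control_outcomes`,
#'   `remnant` (hippocampal comparison), and `test_details`.
#' @export
phantom_study <- function(n_subjects = 25L, n_controls = 5L, seed = 1L,
                          epochs = 10L, learning_rate = 1e-3,
                          batch_size = 16L, base_channels = 4L,
                          encoder_depth = 2L, grid = 64L, resolution = 64L,
                          radius_range_mm = c(7, 14),
                          ensemble = ensemble_config(), verbose = FALSE) {
  base_spec <- phantom_spec(grid_shape = rep(grid, 3))
  cohort <- generate_cohort(n_subjects,
                            list(cavity_radius_mm = radius_range_mm),
                            seed = seed, base_spec = base_spec)
  names(cohort) <- vapply(cohort, function(s) s$subject_id, "")
  fold <- make_folds(names(cohort), k = 5L, seed = seed)[[1]]

  config <- train_config(epochs = epochs, learning_rate = learning_rate,
                         batch_size = batch_size,
                         encoder_depth = encoder_depth,
                         base_channels = base_channels,
                         seed = seed + 1000L)
  stack_pairs <- function(ids, plane) {
    lapply(ids, function(id) {
      s <- cohort[[id]]
      nv <- normalize_intensity(s$volume)
      list(image = extract_slices(nv, plane, resolution, subject_id = id),
           mask = extract_slices(s$mask, plane, resolution, subject_id = id))
    })
  }
  models <- lapply(names(PLANES), function(pl) {
    if (verbose) message("training ", pl, " model ...")
    train(stack_pairs(fold$train_ids, pl), stack_pairs(fold$val_ids, pl),
          config, verbose = verbose)
  })
  names(models) <- names(PLANES)

  results <- list()
  test_details <- list()
  for (id in fold$test_ids) {
    s <- cohort[[id]]
    seg <- segment_volume(models, s$volume, ensemble)
    results[[id]] <- evaluate_subject(seg$mask, s$mask, id)
    test_details[[id]] <- list(segmentation = seg, subject = s)
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  control_outcomes <- data.frame(subject_id = character(0),
                                 detected = logical(0),
                                 outcome = character(0))
  for (i in seq_len(n_controls)) {
    cspec <- base_spec
    cspec$seed <- as.integer(seed %% 10000L) * 100000L + 90000L + i
    ctrl <- generate_control(cspec)
    seg <- segment_volume(models, ctrl, ensemble)
    control_outcomes <- rbind(control_outcomes, data.frame(
      subject_id = sprintf("ctrl-%03d", i), detected = seg$detected,
      outcome = detection_outcome(seg$mask)))
  }

  remnant <- compare_remnant_estimates(
    lapply(test_details, function(d) d$subject$parcellation),
    lapply(test_details, function(d) d$subject$mask),
    lapply(test_details, function(d) d$segmentation$mask))

  list(models = models, fold = fold, results = results,
       summary = summarize_cohort(results),
       control_outcomes = control_outcomes, remnant = remnant,
       test_details = test_details, config = config, ensemble = ensemble,
       seed = seed)
}
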