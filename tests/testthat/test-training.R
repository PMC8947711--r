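test_that("stratified k-fold splits partition the indices", {
  for (case in list(list(n = 100, k = 10), list(n = 47, k = 10),
                    list(n = 20, k = 5))) {
    labels <- rep(c("left", "right"), length.out = case$n)
    folds <- kfold_split(case$n, case$k, labels, seed = 13)
    expect_length(folds, case$k)
    all_idx <- sort(unlist(folds))
    expect_equal(all_idx, seq_len(case$n))
    sizes <- lengths(folds)
    expect_lte(max(sizes) - min(sizes), 2)   # at most 1 per class
    # class ratio within one trial of balance in every fold
    for (f in folds) {
      counts <- table(factor(labels[f], levels = c("left", "right")))
      expect_lte(abs(diff(as.integer(counts))), 1)
    }
  }
  expect_identical(kfold_split(40, 10, rep(c("left", "right"), 20), 3),
                   kfold_split(40, 10, rep(c("left", "right"), 20), 3))
  expect_error(kfold_split(5, 10, rep("left", 5), 1), "folds")
})

test_that("Cohen's kappa follows its closed form", {
  # with pe = 0.5, kappa is the affine map 2 * p0 - 1
  p0 <- seq(0, 1, by = 0.05)
  expect_equal(cohen_kappa(p0), 2 * p0 - 1)
  expect_equal(cohen_kappa(0.5), 0)
  expect_equal(cohen_kappa(1), 1)
  expect_equal(round(cohen_kappa(0.813), 2), 0.63)
  expect_equal(cohen_kappa(0.9, pe = 0.2), 0.875)
  expect_error(cohen_kappa(0.9, pe = 1), "pe")
})

test_that("confusion metrics handle perfect, inverted and mixed matrices", {
  perfect <- matrix(c(50, 0, 0, 50), 2, byrow = TRUE)
  m <- confusion_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$recall), c(1, 1))
  expect_equal(unname(m$precision), c(1, 1))

  inverted <- matrix(c(0, 50, 50, 0), 2, byrow = TRUE)
  expect_equal(confusion_metrics(inverted)$accuracy, 0)
  expect_equal(unname(confusion_metrics(inverted)$recall), c(0, 0))

  mixed <- matrix(c(40, 10, 20, 30), 2, byrow = TRUE)
  mm <- confusion_metrics(mixed)
  expect_equal(mm$accuracy, 0.70)
  expect_equal(unname(mm$recall[1]), 0.80)
  expect_equal(unname(mm$precision[1]), 40 / 60)

  degenerate <- matrix(c(3, 0, 2, 0), 2, byrow = TRUE)
  expect_true(is.na(confusion_metrics(degenerate)$precision[2]))
})

test_that("cross-validated training is deterministic under seed and reports
           accuracy consistent with its confusion matrix", {
  cfg <- sim_config(n_trials_per_class = 10, erd_depth = 0.6,
                    noise_amplitude = 0.3, seed = 8)
  prep <- prepare_network_inputs(simulate_dataset(cfg))
  data <- list(eeg = prep$eeg, cwt = prep$cwt, labels = prep$labels)
  tc <- train_config(folds = 3, max_epochs = 8, seed = 21)
  r1 <- run_cv(build_tbtf(), data, tc)
  r2 <- run_cv(build_tbtf(), data, tc)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$pooled_accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  expect_equal(r1$kappa, 2 * r1$accuracy - 1)
  # shape mismatch is rejected before training
  bad <- list(eeg = prep$eeg[, 1:5, , drop = FALSE], cwt = prep$cwt,
              labels = prep$labels)
  expect_error(run_cv(build_tbtf(), bad, tc), "shape")
})

test_that("all three variants solve near-noiseless separable data perfectly", {
  cfg <- sim_config(n_trials_per_class = 20, erd_depth = 0.6,
                    noise_amplitude = 0.02, rhythm_amplitude = 1, seed = 5)
  prep <- prepare_network_inputs(simulate_dataset(cfg))
  tc <- train_config(folds = 5, max_epochs = 60, seed = 3)
  for (spec in list(build_tbtf(), build_single_branch("eeg"),
                    build_single_branch("cwt"))) {
    data <- list(eeg = if (!is.null(spec$eeg_branch)) prep$eeg,
                 cwt = if (!is.null(spec$cwt_branch)) prep$cwt,
                 labels = prep$labels)
    rep <- run_cv(spec, data, tc)
    expect_equal(rep$fold_accuracy, rep(1, 5),
                 label = paste(spec$variant, "fold accuracies"))
  }
})
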