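test_that("classes drawn from one distribution give eigenvalues near 0.5", {
  set.seed(14)
  A <- matrix(c(1, 0.4, 0.2, 0.3, 1.2, 0.1, 0, 0.5, 0.9), 3, 3)
  csp <- fit_csp(mixed_trials(100, A), mixed_trials(100, A), m = 1)
  expect_true(all(abs(csp$eigenvalues - 0.5) < 0.1))
})

test_that("the top filter recovers the brute-force generalized eigenvector", {
  set.seed(15)
  # class A carries 10x variance along a known direction
  v <- c(1, 0.3) / sqrt(1.09)
  v_perp <- c(-0.3, 1) / sqrt(1.09)
  Aa <- cbind(sqrt(10) * v, v_perp)
  Ab <- cbind(v, v_perp)
  ta <- mixed_trials(150, Aa)
  tb <- mixed_trials(150, Ab)
  csp <- fit_csp(ta, tb, m = 1)

  # oracle 1: generalized eigenvector of the true covariances
  Ra_true <- Aa %*% t(Aa); Ra_true <- Ra_true / sum(diag(Ra_true))
  Rb_true <- Ab %*% t(Ab); Rb_true <- Rb_true / sum(diag(Rb_true))
  w_true <- geigen_brute(Ra_true, Rb_true)$vectors[, 1]
  expect_gt(cosine_abs(csp$filters[1, ], w_true), 0.95)

  # oracle 2: brute-force solve on the same empirical covariances must
  # match the whitening route to high precision
  emp <- geigen_brute(avg_norm_cov(ta), avg_norm_cov(tb))
  expect_gt(cosine_abs(csp$filters[1, ], emp$vectors[, 1]), 1 - 1e-8)
  expect_equal(csp$eigenvalues[1], emp$values[1], tolerance = 1e-8)
})

test_that("CSP filters jointly diagonalize both class covariances", {
  set.seed(16)
  Aa <- matrix(c(2, 0.5, 0.3, 1), 2, 2)
  Ab <- matrix(c(1, -0.2, 0.4, 1.5), 2, 2)
  ta <- mixed_trials(120, Aa)
  tb <- mixed_trials(120, Ab)
  csp <- fit_csp(ta, tb, m = 1)       # 2m = C: the full filter matrix
  W <- csp$filters
  Da <- W %*% avg_norm_cov(ta) %*% t(W)
  Db <- W %*% avg_norm_cov(tb) %*% t(W)
  expect_lt(max(abs(Da[row(Da) != col(Da)])), 1e-8)
  expect_lt(max(abs(Db[row(Db) != col(Db)])), 1e-8)
  # eigenvalue complementarity: per filter the two class shares sum to 1
  expect_equal(diag(Da) + diag(Db), rep(1, 2), tolerance = 1e-8)
  expect_equal(unname(diag(Da)), csp$eigenvalues, tolerance = 1e-8)
})

test_that("log-variance features are scale invariant with length 2m", {
  set.seed(17)
  A <- matrix(c(1.5, 0.2, 0.1, 0.9, 1.1, 0, 0.3, 0.2, 1), 3, 3)
  csp <- fit_csp(mixed_trials(40, A), mixed_trials(40, 2 * A), m = 1)
  trial <- matrix(rnorm(3 * 200), 3, 200)
  f <- csp_features(trial, csp)
  expect_length(f, 2)
  expect_equal(csp_features(25 * trial, csp), f, tolerance = 1e-10)
  expect_error(csp_features(trial[1:2, ], csp), "channels")
})

test_that("the Fisher discriminant separates blobs and behaves symmetrically", {
  set.seed(18)
  Xa <- matrix(rnorm(60, mean = 5, sd = 0.5), 30, 2)
  Xb <- matrix(rnorm(60, mean = -5, sd = 0.5), 30, 2)
  X <- rbind(Xa, Xb)
  y <- rep(c("left", "right"), each = 30)
  lda <- fit_lda(X, y)
  expect_equal(predict_lda(X, lda), y)

  # swapping labels flips every prediction
  lda_sw <- fit_lda(X, rev(y))
  expect_equal(predict_lda(X, lda_sw),
               ifelse(predict_lda(X, lda) == "left", "right", "left"))

  # duplicating the training data leaves the model unchanged
  lda_dup <- fit_lda(rbind(X, X), c(y, y))
  expect_equal(lda_dup$w, lda$w, tolerance = 1e-9)
  expect_equal(lda_dup$b, lda$b, tolerance = 1e-9)
  expect_error(fit_lda(Xa, rep("left", 30)), "two classes")
})

test_that("Fisher LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(19)
  X <- rbind(matrix(rnorm(100, 1), 50, 2), matrix(rnorm(100, -1), 50, 2))
  y <- rep(c("left", "right"), each = 50)
  ours <- predict_lda(X, fit_lda(X, y))
  ref <- as.character(stats::predict(MASS::lda(X, grouping = y), X)$class)
  expect_gte(mean(ours == ref), 0.98)
})

test_that("cross-validated CSP-LDA is deterministic, honest on shuffled labels", {
  cfg <- sim_config(n_trials_per_class = 100, erd_depth = 0.6,
                    noise_amplitude = 0.2, rhythm_amplitude = 1, seed = 7)
  prep <- prepare_network_inputs(simulate_dataset(cfg), with_maps = FALSE)
  r1 <- run_csp_lda_cv(prep$epochs, m = 1, folds = 10, seed = 11)
  r2 <- run_csp_lda_cv(prep$epochs, m = 1, folds = 10, seed = 11)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_gte(r1$accuracy, 0.8)

  shuffled <- prep$epochs
  shuffled$labels <- local({
    set.seed(99)
    sample(prep$epochs$labels)
  })
  rs <- run_csp_lda_cv(shuffled, m = 1, folds = 10, seed = 11)
  expect_gte(rs$accuracy, 0.4)
  expect_lte(rs$accuracy, 0.6)
})
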