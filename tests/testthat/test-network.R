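test_that("shape propagation reproduces every architecture-table row", {
  spec <- build_tbtf()
  shp <- propagate_shapes(spec)
  expect_equal(shp$eeg[[1]], c(1, 110, 32))
  expect_equal(shp$eeg[[2]], c(1, 36, 32))
  expect_equal(shp$eeg[[3]], 1152)
  expect_equal(shp$cwt[[1]], c(1, 93, 32))
  expect_equal(shp$cwt[[2]], c(1, 31, 32))
  expect_equal(shp$cwt[[3]], 992)
  expect_equal(shp$concat_width, 2144)
  expect_equal(shp$head[[3]], 2L)
})

test_that("output_shape covers same and valid padding arithmetic", {
  conv_same <- conv2d_spec(32, c(1, 8), c(1, 8), "same", "elu")
  expect_equal(output_shape(conv_same, c(1, 875, 6)), c(1, 110, 32))
  conv_valid <- conv2d_spec(32, c(1, 8), c(1, 8), "valid", "elu")
  expect_equal(output_shape(conv_valid, c(1, 875, 6))[2], 109)
  pool <- maxpool2d_spec(c(1, 3))
  expect_equal(output_shape(pool, c(1, 110, 32)), c(1, 36, 32))
  expect_error(output_shape(conv2d_spec(1, c(10, 1), c(1, 1)), c(4, 4, 1)),
               "kernel")
})

test_that("parameter counting reproduces the printed counts layer by layer", {
  pc <- count_parameters(build_tbtf())
  params <- setNames(pc$layers$params, pc$layers$layer)
  expect_equal(unname(params["eeg_conv2d"]), 1568L)
  expect_equal(unname(params["cwt_conv2d"]), 2080L)
  expect_equal(unname(params[names(params) == "head_dense"]), c(274560L, 258L))
  expect_equal(pc$total, 278466L)
})

test_that("single-branch ablations keep the shared head", {
  eeg <- build_single_branch("eeg")
  cwt <- build_single_branch("cwt")
  expect_equal(propagate_shapes(eeg)$concat_width, 1152)
  expect_equal(propagate_shapes(cwt)$concat_width, 992)
  expect_equal(propagate_shapes(eeg)$head[[3]], 2L)
  expect_equal(propagate_shapes(cwt)$head[[3]], 2L)
  expect_error(build_single_branch("stft"), "unknown variant")
})

test_that("activations follow their definitions", {
  expect_equal(elu(0), 0)
  expect_equal(elu(1.5), 1.5)
  expect_equal(elu(-50, a = 2), 2 * (exp(-50) - 1))
  expect_equal(relu(c(-3, 0, 3)), c(0, 0, 3))
  # continuity and monotonicity of ELU around 0
  eps <- 1e-9
  expect_lt(abs(elu(eps) - elu(-eps)), 1e-8)
  set.seed(11)
  x <- sort(rnorm(200, sd = 3))
  expect_true(all(diff(elu(x)) > 0))
  # softmax: valid distribution, shift invariant
  expect_equal(softmax(c(4, 4)), c(0.5, 0.5))
  y <- matrix(rnorm(50), 10, 5) * 100
  p <- softmax(y)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_equal(softmax(y + 17), p, tolerance = 1e-9)
})

test_that("network specs survive a serialize/parse round trip", {
  for (spec in list(build_tbtf(), build_single_branch("cwt"))) {
    path <- tempfile(fileext = ".json")
    network_spec_write(spec, path)
    expect_identical(network_spec_read(path), spec)
    unlink(path)
  }
})

test_that("built models match the declared parameter counts and emit probabilities", {
  for (spec in list(build_tbtf(), build_single_branch("eeg"),
                    build_single_branch("cwt"))) {
    model <- build_model(spec, seed = 2)
    expect_equal(model_n_parameters(model), count_parameters(spec)$total)
  }
  model <- build_model(build_tbtf(), seed = 2)
  inputs <- list(eeg = array(0, c(3, 6, 875)), cwt = array(0, c(3, 64, 93)))
  p <- predict_proba(model, inputs)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  bad <- list(eeg = array(0, c(3, 6, 800)), cwt = inputs$cwt)
  expect_error(predict_proba(model, bad), "shape")
})

test_that("model initialization is reproducible under a seed", {
  m1 <- build_model(build_tbtf(), seed = 31)
  m2 <- build_model(build_tbtf(), seed = 31)
  m3 <- build_model(build_tbtf(), seed = 32)
  expect_identical(m1$params, m2$params)
  expect_false(isTRUE(all.equal(m1$params$W_d1, m3$params$W_d1)))
})
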