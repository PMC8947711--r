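make_set <- function(n = 2, channels = c("C3", "Cz", "C4"), ns = 1125,
                     fs = 250, fill = 0) {
  raw_trial_set(array(fill, c(n, length(channels), ns)),
                rep(c("left", "right"), length.out = n), fs, channels)
}

test_that("select_channels subsets, reorders and names missing channels", {
  ds <- make_set()
  ds$data[] <- seq_along(ds$data)
  same <- select_channels(ds, c("C3", "Cz", "C4"))
  expect_identical(same$data, ds$data)
  perm <- select_channels(ds, c("C4", "C3"))
  expect_equal(perm$channel_names, c("C4", "C3"))
  expect_identical(perm$data[, 1, ], ds$data[, 3, ])
  expect_identical(perm$data[, 2, ], ds$data[, 1, ])
  expect_error(select_channels(ds, c("C3", "Fz")), "Fz")
})

test_that("Butterworth band-pass attenuates stopband and passes passband tones", {
  fs <- 250
  mid <- 400:700        # steady-state, away from edge transients
  dc <- one_channel_set(rep(1, 1000), fs)
  out <- bandpass(dc, filter_spec(8, 13))
  expect_lte(max(abs(out$data[1, 1, mid])), 0.01)

  tone10 <- one_channel_set(make_tone(10, 4, fs), fs)
  out10 <- bandpass(tone10, filter_spec(8, 13))
  expect_gte(max(out10$data[1, 1, mid]), 0.9)

  tone40 <- one_channel_set(make_tone(40, 4, fs), fs)
  out40 <- bandpass(tone40, filter_spec(17, 30))
  expect_lte(max(abs(out40$data[1, 1, mid])), 0.1)

  expect_error(bandpass(dc, filter_spec(17, 130)), "Nyquist")
})

test_that("filtering is linear", {
  fs <- 250
  set.seed(5)
  x <- rnorm(1000)
  y <- rnorm(1000)
  fx <- bandpass(one_channel_set(x, fs), filter_spec(8, 13))$data[1, 1, ]
  fy <- bandpass(one_channel_set(y, fs), filter_spec(8, 13))$data[1, 1, ]
  fxy <- bandpass(one_channel_set(2 * x - 3 * y, fs), filter_spec(8, 13))$data[1, 1, ]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-5)
})

test_that("a 10 Hz tone keeps far more power in the mu than the beta filter", {
  fs <- 250
  tone <- one_channel_set(make_tone(10, 4, fs), fs)
  mu <- bandpass(tone, filter_spec(8, 13))$data[1, 1, 400:700]
  beta <- bandpass(tone, filter_spec(17, 30))$data[1, 1, 400:700]
  expect_gte(mean(mu^2) / mean(beta^2), 10)
})

test_that("epoch extraction follows the round(t * fs) half-open contract", {
  ds <- make_set(ns = 1125)
  ep <- extract_epoch(ds, 0.5, 4.0)
  expect_equal(dim(ep$data)[3], 875L)
  full <- extract_epoch(ds, 0, 4.5)
  expect_equal(dim(full$data)[3], 1125L)
  one <- extract_epoch(ds, 1.0, 1.004)
  expect_equal(dim(one$data)[3], 1L)
  expect_error(extract_epoch(ds, 0.5, 5.0), "window")
})

test_that("band stacking places mu rows over beta rows and round-trips", {
  mu <- make_set(fill = 1, ns = 100)
  beta <- make_set(fill = 2, ns = 100)
  st <- stack_bands(mu, beta)
  expect_equal(dim(st$data), c(2, 6, 100))
  expect_true(all(st$data[, 1:3, ] == 1))
  expect_true(all(st$data[, 4:6, ] == 2))
  expect_equal(st$row_names,
               c("mu_C3", "mu_Cz", "mu_C4", "beta_C3", "beta_Cz", "beta_C4"))
  back <- unstack_bands(st)
  expect_identical(back$mu$data, mu$data)
  expect_identical(back$beta$data, beta$data)

  beta_bad <- beta
  beta_bad$labels <- rev(beta_bad$labels)
  expect_error(stack_bands(mu, beta_bad), "label")
  expect_error(stack_bands(mu, make_set(n = 3, ns = 100)), "trial count")
})

test_that("row normalization z-scores, zeroes degenerate rows, ignores scale", {
  set.seed(8)
  mu <- make_set(ns = 200)
  mu$data[] <- rnorm(length(mu$data))
  beta <- make_set(ns = 200)
  beta$data[] <- rnorm(length(beta$data))
  st <- stack_bands(mu, beta)
  nz <- normalize_epochs(st, scope = "row")
  for (r in 1:6) {
    expect_lt(abs(mean(nz$data[1, r, ])), 1e-9)
    expect_lt(abs(sd(nz$data[1, r, ]) - 1), 1e-9)
  }
  st10 <- st
  st10$data <- st$data * 10
  expect_equal(normalize_epochs(st10, scope = "row")$data, nz$data,
               tolerance = 1e-12)

  stc <- st
  stc$data[1, 2, ] <- 7          # constant row
  expect_true(all(normalize_epochs(stc, scope = "row")$data[1, 2, ] == 0))
})

test_that("trial-scope normalization preserves between-row amplitude ratios", {
  set.seed(9)
  mu <- make_set(n = 1, ns = 200)
  mu$data[] <- rnorm(length(mu$data))
  mu$data[1, 1, ] <- mu$data[1, 1, ] * 4   # C3 row amplified
  beta <- make_set(n = 1, ns = 200)
  beta$data[] <- rnorm(length(beta$data))
  st <- stack_bands(mu, beta)
  nt <- normalize_epochs(st, scope = "trial")
  before <- var(st$data[1, 1, ]) / var(st$data[1, 3, ])
  after <- var(nt$data[1, 1, ]) / var(nt$data[1, 3, ])
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("the preprocessing chain preserves trial count, labels and shape", {
  cfg <- sim_config(n_trials_per_class = 3, noise_amplitude = 0.3, seed = 12)
  ds <- simulate_dataset(cfg)
  prep <- prepare_network_inputs(ds, with_maps = FALSE)
  expect_equal(dim(prep$eeg), c(6, 6, 875))
  expect_identical(prep$labels, ds$labels)
  expect_equal(dim(prep$epochs$data), c(6, 6, 875))
})
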