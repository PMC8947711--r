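#' Configuration of the Morlet time-frequency map
#'
#' The assembled map is `2 * scales_per_band` rows by
#' `3 * time_bins_per_channel` columns (64 x 93 with the defaults): rows
#' 1-32 are mu-band scales (low to high frequency), rows 33-64 beta-band
#' scales, and each channel (C3, Cz, C4) occupies a contiguous 31-column
#' block along the time axis.
#'
#' @param omega Morlet center frequency (radians per unit time of the
#'   mother wavelet); 6 is the standard admissibility-respecting choice.
#' @param scales_per_band wavelet scales per frequency band.
#' @param mu_band,beta_band frequency intervals in Hz.
#' @param time_bins_per_channel time columns each channel is pooled into.
#' @param power if `TRUE` the map holds `|CWT|^2` instead of `|CWT|`.
#' @return an object of class `cwt_config`.
#' @export
cwt_config <- function(omega = 6, scales_per_band = 32,
                       mu_band = c(8, 13), beta_band = c(17, 30),
                       time_bins_per_channel = 31, power = FALSE) {
  if (omega <= 0) stop("omega must be positive")
  structure(list(omega = omega, scales_per_band = as.integer(scales_per_band),
                 mu_band = mu_band, beta_band = beta_band,
                 time_bins_per_channel = as.integer(time_bins_per_channel),
                 power = isTRUE(power)),
            class = "cwt_config")
}

#' Scaled, translated Morlet wavelet
#'
#' Evaluates `(1/sqrt(alpha)) * exp(i*omega*(t - beta_shift)/alpha) *
#' exp(-(t - beta_shift)^2 / (2*alpha^2))` elementwise. With `alpha = 1`,
#' `beta_shift = 0` this is the mother wavelet
#' `exp(i*omega*t) * exp(-t^2/2)`.
#'
#' @param t numeric time array (same units as `alpha` and `beta_shift`).
#' @param alpha positive scale factor.
#' @param beta_shift time translation.
#' @param omega center frequency in radians per unit time.
#' @return complex array of `length(t)`.
#' @export
morlet_wavelet <- function(t, alpha, beta_shift = 0, omega = 6) {
  if (alpha <= 0) stop("alpha (scale) must be positive")
  u <- (t - beta_shift) / alpha
  (1 / sqrt(alpha)) * exp(1i * omega * u) * exp(-u^2 / 2)
}

#' Convert between physical frequency and Morlet scale
#'
#' A Morlet wavelet of scale `alpha` (in samples) oscillates at
#' `omega / alpha` radians per sample, i.e. `omega * fs / (2 * pi * alpha)`
#' Hz, so `alpha = omega * fs / (2 * pi * f_hz)`. The two functions are
#' exact inverses.
#'
#' @param f_hz frequency in Hz (positive).
#' @param alpha scale in samples (positive).
#' @param omega Morlet center frequency.
#' @param fs sampling rate, Hz.
#' @return the corresponding scale (samples) or frequency (Hz).
#' @export
scale_for_frequency <- function(f_hz, omega = 6, fs = 250) {
  if (any(f_hz <= 0)) stop("frequency must be positive")
  omega * fs / (2 * pi * f_hz)
}

#' @rdname scale_for_frequency
#' @export
frequency_for_scale <- function(alpha, omega = 6, fs = 250) {
  if (any(alpha <= 0)) stop("scale must be positive")
  omega * fs / (2 * pi * alpha)
}

# Geometrically spaced analysis frequencies inside a band (low -> high).
band_frequencies <- function(band, n) {
  exp(seq(log(band[1]), log(band[2]), length.out = n))
}

#' Morlet continuous wavelet transform
#'
#' The coefficient at scale `alpha` (samples) and translation `beta`
#' (sample index) discretizes the wavelet integral as a Riemann sum with
#' `dt = 1/fs`:
#' `CWT(alpha, beta) = (1/sqrt(alpha)) * dt * sum_n f[n] * Phi_{alpha,beta}(n)`
#' where `Phi` is [morlet_wavelet()] (itself carrying `1/sqrt(alpha)`), so
#' the overall envelope normalization is `1/alpha` and a pure tone responds
#' with equal peak magnitude at every scale. No complex conjugation is
#' applied to the wavelet; for real signals this changes only the phase
#' sign, not the magnitude. Computed by FFT cross-correlation with the
#' wavelet truncated at eight envelope standard deviations (tail mass
#' ~1e-14), so it agrees with the direct sum to near machine precision.
#'
#' @param signal finite numeric vector.
#' @param scales positive scales in samples (see [scale_for_frequency()]).
#' @param omega Morlet center frequency.
#' @param fs sampling rate, Hz.
#' @return complex matrix `(length(scales) x length(signal))`.
#' @export
cwt_morlet <- function(signal, scales, omega = 6, fs = 250) {
  n <- length(signal)
  if (n == 0) stop("signal must be nonempty")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (any(scales <= 0)) stop("scales must be positive")
  m2_max <- ceiling(8 * max(scales))
  L <- stats::nextn(n + 2 * m2_max, 2)
  Fp <- stats::fft(c(signal, numeric(L - n)))
  out <- matrix(complex(real = 0), nrow = length(scales), ncol = n)
  for (s in seq_along(scales)) {
    alpha <- scales[s]
    m2 <- ceiling(8 * alpha)
    m <- 0:m2
    hm <- exp(1i * omega * m / alpha) * exp(-m^2 / (2 * alpha^2)) / sqrt(alpha)
    hc <- complex(real = numeric(L))
    # circular kernel hc[d] = h[-d]; h is conjugate-symmetric in m
    hc[1] <- hm[1]
    if (m2 >= 1) {
      hc[1 + seq_len(m2)] <- Conj(hm[1 + seq_len(m2)])
      hc[L + 1 - seq_len(m2)] <- hm[1 + seq_len(m2)]
    }
    y <- stats::fft(Fp * stats::fft(hc), inverse = TRUE) / L
    out[s, ] <- y[seq_len(n)] / (sqrt(alpha) * fs)
  }
  out
}

# Mean-pool the columns of a matrix into `bins` contiguous, near-equal bins.
pool_time <- function(mat, bins) {
  ncols <- ncol(mat)
  if (ncols < bins) stop("cannot pool fewer time samples than bins")
  edges <- round(seq(0, ncols, length.out = bins + 1))
  out <- matrix(0, nrow(mat), bins)
  for (b in seq_len(bins)) {
    out[, b] <- rowMeans(mat[, (edges[b] + 1):edges[b + 1], drop = FALSE])
  }
  out
}

#' Assemble one time-frequency map from per-channel, per-band CWT matrices
#'
#' Takes the six coefficient matrices `{C3, Cz, C4} x {mu, beta}` (in the
#' order mu C3, mu Cz, mu C4, beta C3, beta Cz, beta C4, rows ordered low
#' to high frequency), reduces each to magnitudes (or squared magnitudes),
#' mean-pools the time axis into `time_bins_per_channel` contiguous bins,
#' lays the blocks out as rows 1-32 = mu scales / rows 33-64 = beta scales
#' and columns 1-31 = C3 / 32-62 = Cz / 63-93 = C4, then min-max scales the
#' whole map to `[0, 1]` (a map with zero spread stays all-zero).
#'
#' @param mats list of 6 complex (or numeric) matrices, each
#'   `scales_per_band x T`.
#' @param config a [cwt_config()].
#' @return numeric matrix, 64 x 93 under the defaults, with attributes
#'   `row_band` and `col_channel` describing the layout.
#' @export
assemble_map <- function(mats, config = cwt_config()) {
  if (length(mats) != 6) stop("need exactly 6 matrices ({C3,Cz,C4} x {mu,beta})")
  widths <- vapply(mats, ncol, integer(1))
  if (length(unique(widths)) != 1) stop("all matrices must share the same width")
  spb <- config$scales_per_band
  if (any(vapply(mats, nrow, integer(1)) != spb)) {
    stop(sprintf("each matrix must have scales_per_band = %d rows", spb))
  }
  tb <- config$time_bins_per_channel
  map <- matrix(0, 2 * spb, 3 * tb)
  for (ch in 1:3) {
    for (bd in 1:2) {
      mag <- Mod(mats[[(bd - 1) * 3 + ch]])
      if (config$power) mag <- mag^2
      map[(bd - 1) * spb + seq_len(spb), (ch - 1) * tb + seq_len(tb)] <-
        pool_time(mag, tb)
    }
  }
  rng <- range(map)
  map <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
  attr(map, "row_band") <- rep(c("mu", "beta"), each = spb)
  attr(map, "col_channel") <- rep(c("C3", "Cz", "C4"), each = tb)
  map
}

#' Time-frequency map of one band-stacked trial
#'
#' Transforms the three mu rows with mu-band scales and the three beta rows
#' with beta-band scales (geometrically spaced frequencies within each
#' band), then assembles the 64 x 93 map via [assemble_map()].
#'
#' @param trial numeric matrix `6 x T`, the rows of one
#'   `band_stacked_epochs` trial.
#' @param config a [cwt_config()].
#' @param fs sampling rate, Hz.
#' @return the assembled map (see [assemble_map()]).
#' @export
trial_to_map <- function(trial, config = cwt_config(), fs = 250) {
  if (nrow(trial) != 6) stop("trial must have the 6-row band-stacked layout")
  mu_scales <- scale_for_frequency(
    band_frequencies(config$mu_band, config$scales_per_band), config$omega, fs)
  beta_scales <- scale_for_frequency(
    band_frequencies(config$beta_band, config$scales_per_band), config$omega, fs)
  mats <- vector("list", 6)
  for (ch in 1:3) {
    mats[[ch]] <- cwt_morlet(trial[ch, ], mu_scales, config$omega, fs)
    mats[[3 + ch]] <- cwt_morlet(trial[3 + ch, ], beta_scales, config$omega, fs)
  }
  assemble_map(mats, config)
}

#' Time-frequency maps for every trial of a band-stacked epoch set
#'
#' @param epochs a `band_stacked_epochs`.
#' @param config a [cwt_config()].
#' @return numeric array `(n_trials, 2*scales_per_band, 3*time_bins)`.
#' @export
maps_for_epochs <- function(epochs, config = cwt_config()) {
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], 2 * config$scales_per_band,
                          3 * config$time_bins_per_channel))
  for (i in seq_len(d[1])) {
    out[i, , ] <- trial_to_map(epochs$data[i, , ], config, epochs$fs)
  }
  out
}
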