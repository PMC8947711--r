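#' Configuration for the synthetic motor-imagery EEG simulator
#'
#' Describes 250 Hz three-channel (C3, Cz, C4) recordings in which imagining
#' a hand movement suppresses the mu (8-13 Hz) and beta (17-30 Hz) rhythm
#' amplitude on the channel contralateral to the imagined hand
#' (event-related desynchronization, ERD), on top of 1/f-shaped background
#' noise. Rhythms are sums of a few sinusoids with per-trial random
#' frequencies inside each band and random phases, which keeps their band
#' power analytically checkable.
#'
#' @param fs sampling rate, Hz.
#' @param n_trials_per_class trials generated per class.
#' @param trial_duration_s trial length in seconds; the default 4.5 s covers
#'   the 0.5-4 s analysis window with padding for filter transients.
#' @param channels ordered channel names; must contain `C3` and `C4`.
#' @param mu_band,beta_band rhythm frequency intervals in Hz.
#' @param erd_depth fraction in `[0, 1)` by which the contralateral rhythm
#'   amplitude is reduced inside the imagery window (applies to the mu band).
#' @param erd_depth_beta ERD depth for the beta band; defaults to `erd_depth`.
#' @param ers_gain fractional amplitude gain applied to the ipsilateral
#'   channel during the imagery window (event-related synchronization);
#'   0 disables it.
#' @param mi_window_s two-element interval (seconds) inside the trial where
#'   ERD/ERS apply.
#' @param noise_amplitude standard deviation of the 1/f background noise.
#' @param rhythm_amplitude amplitude scale of each band's oscillation; the
#'   summed oscillators of one band carry power `rhythm_amplitude^2 / 2`.
#' @param n_oscillators sinusoids summed per band and channel.
#' @param seed integer seeding the dataset's random stream; identical config
#'   plus seed reproduces bit-identical data.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(fs = 250, n_trials_per_class = 10, trial_duration_s = 4.5,
                       channels = c("C3", "Cz", "C4"),
                       mu_band = c(8, 13), beta_band = c(17, 30),
                       erd_depth = 0.5, erd_depth_beta = erd_depth, ers_gain = 0,
                       mi_window_s = c(0.5, 4.0),
                       noise_amplitude = 1, rhythm_amplitude = 1,
                       n_oscillators = 3, seed = 1L) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (n_trials_per_class < 1) stop("n_trials_per_class must be >= 1")
  if (erd_depth < 0 || erd_depth >= 1) stop("erd_depth must lie in [0, 1)")
  if (erd_depth_beta < 0 || erd_depth_beta >= 1) stop("erd_depth_beta must lie in [0, 1)")
  if (!all(c("C3", "C4") %in% channels)) {
    stop("channels must include C3 and C4 (lateralized ERD targets)")
  }
  if (mi_window_s[1] < 0 || mi_window_s[2] > trial_duration_s ||
      mi_window_s[1] >= mi_window_s[2]) {
    stop("mi_window_s must be a nonempty interval inside [0, trial_duration_s]")
  }
  structure(
    list(fs = fs, n_trials_per_class = as.integer(n_trials_per_class),
         trial_duration_s = trial_duration_s, channels = channels,
         mu_band = mu_band, beta_band = beta_band,
         erd_depth = erd_depth, erd_depth_beta = erd_depth_beta,
         ers_gain = ers_gain, mi_window_s = mi_window_s,
         noise_amplitude = noise_amplitude, rhythm_amplitude = rhythm_amplitude,
         n_oscillators = as.integer(n_oscillators), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 1/f-shaped (pink) noise of length n, standardized to unit sd, synthesized
# in the frequency domain: complex Gaussian spectrum with amplitude 1/sqrt(f).
pink_noise <- function(n) {
  if (n < 2) return(numeric(n))
  nf <- floor((n - 1) / 2)
  amp <- 1 / sqrt(seq_len(nf))
  pos <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(real = numeric(n))
  spec[1 + seq_len(nf)] <- pos
  spec[n + 1 - seq_len(nf)] <- Conj(pos)
  if (n %% 2 == 0) spec[n / 2 + 1] <- stats::rnorm(1) / sqrt(n / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Sum of `n_osc` sinusoids with random frequencies in `band` and random
# phases, scaled so the summed expected power is amplitude^2 / 2.
rhythm_component <- function(t_s, band, amplitude, n_osc) {
  freqs <- stats::runif(n_osc, band[1], band[2])
  phases <- stats::runif(n_osc, 0, 2 * pi)
  a <- amplitude / sqrt(n_osc)
  sig <- numeric(length(t_s))
  for (j in seq_len(n_osc)) {
    sig <- sig + a * sin(2 * pi * freqs[j] * t_s + phases[j])
  }
  sig
}

#' Simulate one labeled motor-imagery trial
#'
#' Each channel is 1/f noise plus a mu-band and a beta-band oscillation.
#' During the imagery window the rhythm amplitude on the channel
#' contralateral to the imagined hand (right-hand label -> C3, left-hand
#' label -> C4) is multiplied by `1 - erd_depth` (`1 - erd_depth_beta` for
#' the beta band); the ipsilateral channel is multiplied by `1 + ers_gain`;
#' Cz is unchanged. Draws from the current RNG stream: seed the stream (or
#' use [simulate_dataset()]) for reproducibility.
#'
#' @param config a [sim_config()].
#' @param label `"left"` or `"right"`.
#' @return numeric matrix `(n_channels x n_samples)` with channel row names.
#' @export
simulate_trial <- function(config, label) {
  if (!is.character(label) || length(label) != 1 || !label %in% c("left", "right")) {
    stop("label must be \"left\" or \"right\"")
  }
  n <- round(config$trial_duration_s * config$fs)
  t_s <- (seq_len(n) - 1) / config$fs
  gate <- t_s >= config$mi_window_s[1] & t_s < config$mi_window_s[2]
  contra <- if (label == "right") "C3" else "C4"
  ipsi <- if (label == "right") "C4" else "C3"

  out <- matrix(0, nrow = length(config$channels), ncol = n,
                dimnames = list(config$channels, NULL))
  depths <- c(mu = config$erd_depth, beta = config$erd_depth_beta)
  bands <- list(mu = config$mu_band, beta = config$beta_band)
  for (ch in config$channels) {
    sig <- numeric(n)
    for (b in names(bands)) {
      osc <- rhythm_component(t_s, bands[[b]], config$rhythm_amplitude,
                              config$n_oscillators)
      gain <- rep(1, n)
      if (ch == contra) gain[gate] <- 1 - depths[[b]]
      if (ch == ipsi) gain[gate] <- 1 + config$ers_gain
      sig <- sig + gain * osc
    }
    if (config$noise_amplitude > 0) {
      sig <- sig + config$noise_amplitude * pink_noise(n)
    }
    out[ch, ] <- sig
  }
  out
}

#' Simulate a balanced labeled dataset of motor-imagery trials
#'
#' Generates `2 * n_trials_per_class` trials from one stream seeded with
#' `config$seed`; the left/right label order is shuffled deterministically
#' under the same seed. Identical config + seed gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return a [raw_trial_set()].
#' @export
simulate_dataset <- function(config) {
  n_samples <- round(config$trial_duration_s * config$fs)
  with_seed(config$seed, {
    labels <- sample(rep(c("left", "right"), config$n_trials_per_class))
    dat <- array(0, dim = c(length(labels), length(config$channels), n_samples))
    for (i in seq_along(labels)) {
      dat[i, , ] <- simulate_trial(config, labels[i])
    }
    ts <- raw_trial_set(dat, labels, config$fs, config$channels)
    attr(ts, "seed") <- config$seed
    ts
  })
}

#' Band power of a signal
#'
#' Integrated one-sided periodogram over a frequency band: the sum of
#' `2 |X_k|^2 / N^2` over positive-frequency DFT bins whose frequency falls
#' inside `[band[1], band[2]]`. For a unit-amplitude sinusoid inside the
#' band this captures approximately its total power of 0.5 (exactly, when
#' the tone sits on a DFT bin).
#'
#' @param signal numeric vector.
#' @param band two-element Hz interval, strictly inside `(0, fs/2)`.
#' @param fs sampling rate, Hz.
#' @return nonnegative scalar band power (variance units).
#' @export
band_power <- function(signal, band, fs) {
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be an increasing interval")
  if (band[1] <= 0 || band[2] >= fs / 2) {
    stop("band must lie strictly inside (0, fs/2) (Nyquist limit)")
  }
  n <- length(signal)
  if (n < 2) return(0)
  X <- stats::fft(signal)
  k <- seq_len(ceiling(n / 2) - 1)          # positive frequencies below Nyquist
  fk <- k * fs / n
  sel <- fk >= band[1] & fk <= band[2]
  sum(2 * Mod(X[k[sel] + 1])^2 / n^2)
}
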