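# Independent oracles and shared fixtures, built in code at test time.

# Direct discretization of the wavelet integral: the slow double loop the
# fast FFT path must reproduce.
cwt_direct <- function(signal, scales, omega = 6, fs = 250) {
  n <- length(signal)
  out <- matrix(complex(real = 0), length(scales), n)
  for (s in seq_along(scales)) {
    for (b in seq_len(n) - 1) {
      out[s, b + 1] <- (1 / sqrt(scales[s])) * (1 / fs) *
        sum(signal * morlet_wavelet(seq_len(n) - 1, scales[s], b, omega))
    }
  }
  out
}

# Threshold rule on lateralized mu-band power: classify "right" when C3
# power (within the imagery window) is below C4 power. The analytic
# benchmark the learned decoders are measured against.
bandpower_rule_accuracy <- function(trials, band = c(8, 13),
                                    window_s = c(0.5, 4.0)) {
  i0 <- round(window_s[1] * trials$fs)
  i1 <- round(window_s[2] * trials$fs)
  idx <- (i0 + 1):i1
  c3 <- match("C3", trials$channel_names)
  c4 <- match("C4", trials$channel_names)
  pred <- vapply(seq_len(n_trials(trials)), function(i) {
    d <- band_power(trials$data[i, c3, idx], band, trials$fs) -
      band_power(trials$data[i, c4, idx], band, trials$fs)
    if (d < 0) "right" else "left"
  }, character(1))
  mean(pred == trials$labels)
}

# Brute-force generalized eigenvectors of Ra w = lambda (Ra + Rb) w,
# eigenvalues descending. Independent of the whitening route used by
# fit_csp.
geigen_brute <- function(Ra, Rb) {
  M <- solve(Ra + Rb, Ra)
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord], vectors = Re(e$vectors)[, ord, drop = FALSE])
}

cosine_abs <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Trials with a known channel mixing: x = A %*% z, z unit-variance
# independent sources, so the true channel covariance is A %*% t(A).
mixed_trials <- function(n, A, T = 200) {
  C <- nrow(A)
  out <- array(0, c(n, C, T))
  for (i in seq_len(n)) out[i, , ] <- A %*% matrix(rnorm(C * T), C, T)
  out
}

# Averaged trace-normalized class covariance, recomputed independently of
# the package internals.
avg_norm_cov <- function(trials) {
  C <- dim(trials)[2]
  R <- matrix(0, C, C)
  for (i in seq_len(dim(trials)[1])) {
    Ci <- tcrossprod(trials[i, , ])
    R <- R + Ci / sum(diag(Ci))
  }
  R / dim(trials)[1]
}

# Single-trial raw_trial_set around one signal, for filter tests.
one_channel_set <- function(x, fs = 250, channel = "C3") {
  raw_trial_set(array(x, dim = c(1, 1, length(x))), "left", fs, channel)
}

make_tone <- function(f_hz, dur_s = 4, fs = 250, amp = 1) {
  amp * sin(2 * pi * f_hz * (seq_len(round(dur_s * fs)) - 1) / fs)
}
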