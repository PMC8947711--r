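#' Butterworth band-pass filter specification
#'
#' @param low_hz,high_hz passband edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (default 5).
#' @param zero_phase apply forward-backward (zero-phase) filtering; `FALSE`
#'   gives a single causal pass.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 5, zero_phase = TRUE) {
  if (order < 1) stop("order must be >= 1")
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Select and reorder channels of a trial set
#'
#' @param trials a [raw_trial_set()].
#' @param wanted ordered channel names to keep.
#' @return a [raw_trial_set()] restricted to `wanted`, in that order.
#' @export
select_channels <- function(trials, wanted) {
  idx <- match(wanted, trials$channel_names)
  if (anyNA(idx)) {
    stop(sprintf("channel(s) not present: %s",
                 paste(wanted[is.na(idx)], collapse = ", ")))
  }
  raw_trial_set(trials$data[, idx, , drop = FALSE], trials$labels, trials$fs,
                wanted, trials$artifact_flags)
}

#' Band-pass filter every channel of every trial
#'
#' Designs a Butterworth band-pass of the requested order and applies it
#' along the time axis of each channel, zero-phase (forward-backward) by
#' default so the passband waveform is not phase-distorted.
#'
#' @param trials a [raw_trial_set()].
#' @param spec a [filter_spec()].
#' @return a [raw_trial_set()] with the same shape.
#' @export
bandpass <- function(trials, spec) {
  ny <- trials$fs / 2
  if (spec$high_hz >= ny) {
    stop(sprintf("high passband edge %g Hz must be below Nyquist (%g Hz)",
                 spec$high_hz, ny))
  }
  flt <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / ny, type = "pass")
  d <- dim(trials$data)
  out <- trials$data
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      x <- trials$data[i, c, ]
      out[i, c, ] <- if (spec$zero_phase) {
        signal::filtfilt(flt, x)
      } else {
        as.numeric(signal::filter(flt, x))
      }
    }
  }
  raw_trial_set(out, trials$labels, trials$fs, trials$channel_names,
                trials$artifact_flags)
}

#' Extract a fixed epoch window from every trial
#'
#' Sample indexing is 0-based and half-open: samples
#' `round(t_start * fs) .. round(t_end * fs) - 1` are kept, so the 0.5-4 s
#' window at 250 Hz yields exactly 875 samples.
#'
#' @param trials a [raw_trial_set()].
#' @param t_start_s,t_end_s window edges in seconds from trial start.
#' @return a [raw_trial_set()] restricted to the window.
#' @export
extract_epoch <- function(trials, t_start_s = 0.5, t_end_s = 4.0) {
  i0 <- round(t_start_s * trials$fs)
  i1 <- round(t_end_s * trials$fs)
  n <- dim(trials$data)[3]
  if (i1 > n) stop(sprintf("epoch window ends at sample %d but trials have %d samples", i1, n))
  if (i1 <= i0) stop("epoch window must contain at least one sample")
  epoch <- trials$data[, , (i0 + 1):i1, drop = FALSE]
  out <- raw_trial_set(epoch, trials$labels, trials$fs, trials$channel_names,
                       trials$artifact_flags)
  attr(out, "window_s") <- c(t_start_s, t_end_s)
  out
}

#' Stack mu- and beta-filtered epochs into 6-row trial matrices
#'
#' Per trial, rows 1-3 hold the mu-band C3, Cz, C4 signals and rows 4-6 the
#' beta-band C3, Cz, C4 signals, giving the `6 x T` matrix (T = 875 at
#' 250 Hz and the 0.5-4 s window) consumed by the temporal branch of the
#' network and by the CSP baseline.
#'
#' @param mu_trials,beta_trials [raw_trial_set()]s with identical trial
#'   count, labels, sampling rate, sample count and channel order.
#' @return an object of class `band_stacked_epochs` with fields `data`
#'   (`n x 6 x T`), `labels`, `fs`, `row_names`, `channel_names`.
#' @export
stack_bands <- function(mu_trials, beta_trials) {
  if (n_trials(mu_trials) != n_trials(beta_trials)) {
    stop("mu and beta trial sets must have the same trial count")
  }
  if (!identical(mu_trials$labels, beta_trials$labels)) {
    stop("mu and beta trial sets must carry identical label sequences")
  }
  if (!identical(mu_trials$channel_names, beta_trials$channel_names)) {
    stop("mu and beta trial sets must share channel order")
  }
  if (dim(mu_trials$data)[3] != dim(beta_trials$data)[3]) {
    stop("mu and beta trial sets must have the same sample count")
  }
  if (mu_trials$fs != beta_trials$fs) stop("sampling rates differ")
  d <- dim(mu_trials$data)
  dat <- array(0, dim = c(d[1], 2 * d[2], d[3]))
  dat[, seq_len(d[2]), ] <- mu_trials$data
  dat[, d[2] + seq_len(d[2]), ] <- beta_trials$data
  structure(
    list(data = dat, labels = mu_trials$labels, fs = mu_trials$fs,
         channel_names = mu_trials$channel_names,
         row_names = c(paste0("mu_", mu_trials$channel_names),
                       paste0("beta_", beta_trials$channel_names)),
         window_s = attr(mu_trials, "window_s")),
    class = "band_stacked_epochs"
  )
}

#' Recover the mu- and beta-band trial sets from stacked epochs
#'
#' Inverse of [stack_bands()].
#'
#' @param epochs a `band_stacked_epochs`.
#' @return list with elements `mu` and `beta`, each a [raw_trial_set()].
#' @export
unstack_bands <- function(epochs) {
  nc <- length(epochs$channel_names)
  list(
    mu = raw_trial_set(epochs$data[, seq_len(nc), , drop = FALSE],
                       epochs$labels, epochs$fs, epochs$channel_names),
    beta = raw_trial_set(epochs$data[, nc + seq_len(nc), , drop = FALSE],
                         epochs$labels, epochs$fs, epochs$channel_names)
  )
}

#' @export
print.band_stacked_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<band_stacked_epochs> %d trials x %d rows x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  rows:", paste(x$row_names, collapse = ", "), "\n")
  invisible(x)
}

#' Standardize band-stacked epochs
#'
#' `scope = "row"` z-scores each row of each trial independently (mean 0,
#' sd 1; zero-variance rows map to zeros). `scope = "trial"` standardizes
#' each trial by its global mean and sd across all 6 rows, which removes
#' overall scale while preserving the between-row amplitude ratios that
#' carry ERD lateralization (see the package vignette for why the trial
#' scope is what the decoder's temporal branch should consume).
#'
#' @param epochs a `band_stacked_epochs`.
#' @param scope `"row"` or `"trial"`.
#' @return a `band_stacked_epochs` of the same shape.
#' @export
normalize_epochs <- function(epochs, scope = c("row", "trial")) {
  scope <- match.arg(scope)
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1])) {
    if (scope == "row") {
      for (r in seq_len(d[2])) {
        x <- epochs$data[i, r, ]
        s <- stats::sd(x)
        out[i, r, ] <- if (s > 0) (x - mean(x)) / s else 0 * x
      }
    } else {
      x <- epochs$data[i, , ]
      s <- stats::sd(as.numeric(x))
      out[i, , ] <- if (s > 0) (x - mean(x)) / s else 0 * x
    }
  }
  epochs$data <- out
  epochs
}
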