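#' Labeled multi-channel EEG trials
#'
#' The universal container moved between pipeline stages: a numeric array of
#' shape `(n_trials, n_channels, n_samples)` plus per-trial class labels,
#' the sampling rate and ordered channel names.
#'
#' @param data numeric array `(n_trials, n_channels, n_samples)`; all values
#'   must be finite.
#' @param labels character vector, one class label per trial (for two-class
#'   motor imagery these are `"left"` and `"right"`).
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel names, length `n_channels`.
#' @param artifact_flags optional logical vector, one flag per trial, `TRUE`
#'   for trials marked as artifact-contaminated.
#' @return an object of class `raw_trial_set`.
#' @export
raw_trial_set <- function(data, labels, fs, channel_names, artifact_flags = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  d <- dim(data)
  if (d[1] != length(labels)) {
    stop(sprintf("labels length (%d) must equal trial count (%d)", length(labels), d[1]))
  }
  if (d[2] != length(channel_names)) {
    stop(sprintf("channel_names length (%d) must equal channel count (%d)",
                 length(channel_names), d[2]))
  }
  if (d[1] > 0 && any(!is.finite(data))) stop("trial data must contain no NaN/Inf values")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz")
  if (!is.null(artifact_flags) && length(artifact_flags) != d[1]) {
    stop("artifact_flags must have one entry per trial")
  }
  structure(
    list(data = data, labels = as.character(labels), fs = fs,
         channel_names = as.character(channel_names),
         artifact_flags = artifact_flags),
    class = "raw_trial_set"
  )
}

#' @export
print.raw_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (d[1] > 0) {
    tab <- table(x$labels)
    cat("  classes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials in a trial set or epoch set
#' @param x a `raw_trial_set` or `band_stacked_epochs`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]
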