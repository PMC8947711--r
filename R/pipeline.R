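#' Prepare network inputs from raw trials
#'
#' The end-to-end preprocessing chain: select C3/Cz/C4, band-pass filter
#' the full trials into the mu and beta bands (5th-order zero-phase
#' Butterworth), extract the analysis epoch, stack the two bands into
#' 6 x T matrices, and derive both branch inputs -- the standardized
#' band-stacked signal for the temporal branch and the 64 x 93 Morlet maps
#' for the time-frequency branch. Filtering runs on the full trial before
#' epoching so filter transients fall outside the analysis window. The
#' maps are computed from the unstandardized band-stacked signal (each map
#' is min-max scaled on its own), while the temporal input is standardized
#' per trial (`scope`, see [normalize_epochs()]).
#'
#' @param trials a [raw_trial_set()].
#' @param channels channel subset/order for decoding.
#' @param mu_band,beta_band filter passbands in Hz.
#' @param epoch_window analysis window in seconds, default 0.5-4 s.
#' @param filter_order Butterworth order.
#' @param cwt a [cwt_config()].
#' @param scope normalization scope for the temporal input.
#' @param drop_artifacts drop trials whose artifact flag is set.
#' @param with_maps set `FALSE` to skip the (comparatively costly) CWT maps
#'   when only the temporal branch or the CSP baseline is needed.
#' @return list with `eeg` (`n x 6 x T` standardized array), `cwt`
#'   (`n x 64 x 93` array or `NULL`), `labels`, and `epochs` (the
#'   unstandardized `band_stacked_epochs`).
#' @export
prepare_network_inputs <- function(trials, channels = c("C3", "Cz", "C4"),
                                   mu_band = c(8, 13), beta_band = c(17, 30),
                                   epoch_window = c(0.5, 4.0),
                                   filter_order = 5, cwt = cwt_config(),
                                   scope = "trial", drop_artifacts = FALSE,
                                   with_maps = TRUE) {
  if (drop_artifacts && !is.null(trials$artifact_flags)) {
    keep <- which(!trials$artifact_flags)
    trials <- raw_trial_set(trials$data[keep, , , drop = FALSE],
                            trials$labels[keep], trials$fs,
                            trials$channel_names,
                            trials$artifact_flags[keep])
  }
  sel <- select_channels(trials, channels)
  mu <- extract_epoch(bandpass(sel, filter_spec(mu_band[1], mu_band[2], filter_order)),
                      epoch_window[1], epoch_window[2])
  beta <- extract_epoch(bandpass(sel, filter_spec(beta_band[1], beta_band[2], filter_order)),
                        epoch_window[1], epoch_window[2])
  epochs <- stack_bands(mu, beta)
  list(
    eeg = normalize_epochs(epochs, scope = scope)$data,
    cwt = if (with_maps) maps_for_epochs(epochs, cwt),
    labels = epochs$labels,
    epochs = epochs
  )
}
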