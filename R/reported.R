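#' Published reference results on BCI competition IV 2b
#'
#' The per-subject and average classification accuracies (percent) reported
#' for this two-branch architecture and its comparison models on the BCI
#' competition IV 2b benchmark (nine subjects, 10-fold cross-validation).
#' Reproducing them requires the external recordings; the package keeps
#' them as reference inputs for agreement checks such as verifying that
#' the printed average equals the mean of the per-subject values and that
#' the printed kappa values follow from the accuracies via
#' [cohen_kappa()] with `pe = 0.5`.
#'
#' @return list with `tbtf_subject_acc` (named per-subject accuracies, %),
#'   and the averaged accuracies `tbtf_avg`, `eeg_cnn_avg`, `cwt_cnn_avg`,
#'   `csp_lda_avg` (%).
#' @export
reported_bci2b_results <- function() {
  list(
    tbtf_subject_acc = c(S1 = 84.5, S2 = 63.3, S3 = 62.3, S4 = 98.1,
                         S5 = 89.7, S6 = 85.0, S7 = 79.5, S8 = 84.7,
                         S9 = 84.5),
    tbtf_avg = 81.3,
    eeg_cnn_avg = 70.56,
    cwt_cnn_avg = 77.22,
    csp_lda_avg = 71.29
  )
}
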