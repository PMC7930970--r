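#' Bundled per-subject R-wave detection results
#'
#' Per-subject sensitivity, accuracy and positive predictive value (all
#' percent, one decimal) and the number of reference RR-bearing beats
#' (`n_tp_plus_n_fn`) from an eight-subject laboratory evaluation of the
#' in-pillow capacitive-electrode system (2-min resting recordings).
#' Useful as reference input for metric arithmetic: for example, the
#' degraded subject E corresponds to counts `n_tp = 39`, `n_fp = 154`,
#' `n_fn = 79`.
#'
#' @return A data.frame with columns `subject`, `p_sns`, `p_acc`,
#'   `p_ppv`, `n_tp_plus_n_fn`.
#' @export
rwave_validation_metrics <- function() {
  utils::read.csv(system.file("extdata", "rwave_validation_metrics.csv",
                              package = "capsig"),
                  stringsAsFactors = FALSE)
}

#' Bundled per-subject HRV band PSD pairs
#'
#' Per-band PSD values (in units of 1e-4 s^2/Hz) for the reference ECG
#' and the capacitive ECG of the six subjects with 100% detection
#' accuracy, together with the reported per-band error rate in percent.
#' The PSD values are inputs for the error-rate arithmetic
#' ([psd_error_rate()]); the absolute PSDs were produced by a commercial
#' HRV analyzer whose estimator is unpublished, so only the error-rate
#' arithmetic on these pairs is reproducible.
#'
#' @return A data.frame with columns `subject`, `band` (`vlf`, `lf`,
#'   `hf`, `vhf`), `psd_ref`, `psd_cecg`, `error_rate`.
#' @export
hrv_validation_psd <- function() {
  utils::read.csv(system.file("extdata", "hrv_validation_psd.csv",
                              package = "capsig"),
                  stringsAsFactors = FALSE)
}
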