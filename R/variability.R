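#' Coefficient of variation of a waveform
#'
#' The coefficient of variation (CV) is the standard deviation of the signal
#' divided by its mean, expressed in percent of the mean: a scale-free
#' dispersion measure used to quantify how much spontaneous or induced
#' variability a pressure or velocity signal carries. The SD uses the
#' population convention (divisor n); at the 3000+ samples of a 5-minute
#' segment the difference from the sample convention is below 0.02%, but the
#' convention is fixed for exact reproducibility.
#'
#' @param signal Numeric waveform with strictly positive mean (pressures and
#'   velocities are positive; CV is undefined otherwise).
#' @return CV in percent of the mean (>= 0).
#' @examples
#' coefficient_of_variation(100 + 10 * sin(seq(0, 20 * pi, length.out = 4000)))
#' # about 7.07: SD of a sinusoid is amplitude / sqrt(2)
#' @export
coefficient_of_variation <- function(signal) {
  m <- mean(signal)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined: signal mean must be positive")
  }
  n <- length(signal)
  sd_pop <- sqrt(sum((signal - m)^2) / n)
  100 * sd_pop / m
}

#' Band-averaged spectral power
#'
#' Average of the one-sided Welch auto-spectral density over the bins whose
#' center frequency lies in `[f_lo, f_hi)`, used as a frequency-domain
#' measure of signal variability (mmHg^2/Hz for MAP, (cm/s)^2/Hz for MFV).
#' The spectral estimator settings (window, overlap, smoothing) are shared
#' with the transfer-function module so time- and frequency-domain
#' variability read-outs are mutually consistent.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Band edges in Hz, half-open; must lie in `(0, fs/2)`.
#' @param settings Optional [tfa_settings()]; defaults to the standard
#'   settings with `fs` substituted.
#' @return Band-average power spectral density.
#' @export
band_power <- function(signal, fs, f_lo, f_hi, settings = NULL) {
  if (f_lo <= 0 || f_hi > fs / 2 || f_lo >= f_hi) {
    stop("band must satisfy 0 < f_lo < f_hi <= fs/2")
  }
  if (is.null(settings)) settings <- tfa_settings(fs = fs)
  sp <- welch_spectra(signal, signal, settings)
  band_average(sp$Sxx, sp$freqs, f_lo, f_hi)
}

#' Time- and frequency-domain variability of an analysis segment
#'
#' Computes the CV of MAP and MFV and their band-averaged spectral power in
#' the very-low (0.02-0.07 Hz) and low (0.07-0.2 Hz) frequency bands.
#' CV is conventionally computed on the filtered source-rate signals (the
#' time-domain path of [make_segment()]), not on the 10 Hz resampled ones.
#'
#' @param segment A `ca_segment` from [make_segment()].
#' @param bands Band definition data frame as in [tfa_settings()].
#' @return Object of class `variability_result`: `cv_map`, `cv_mfv` (percent)
#'   and `power_map_<band>`, `power_mfv_<band>` entries.
#' @export
variability_summary <- function(segment,
                                bands = tfa_settings()$bands) {
  stopifnot(inherits(segment, "ca_segment"))
  settings <- tfa_settings(fs = segment$fs_out, bands = bands)
  out <- list(cv_map = coefficient_of_variation(segment$map_sig),
              cv_mfv = coefficient_of_variation(segment$mfv_sig))
  sp_map <- welch_spectra(segment$map_sig, segment$map_sig, settings)
  sp_mfv <- welch_spectra(segment$mfv_sig, segment$mfv_sig, settings)
  for (b in seq_len(nrow(bands))) {
    nm <- bands$name[b]
    out[[paste0("power_map_", nm)]] <-
      band_average(sp_map$Sxx, sp_map$freqs, bands$f_lo[b], bands$f_hi[b])
    out[[paste0("power_mfv_", nm)]] <-
      band_average(sp_mfv$Sxx, sp_mfv$freqs, bands$f_lo[b], bands$f_hi[b])
  }
  structure(out, class = "variability_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("<variability_result> CV MAP %.3f%%, CV MFV %.3f%%\n",
              x$cv_map, x$cv_mfv))
  pw <- x[grep("^power_", names(x))]
  if (length(pw)) {
    cat("  band power:",
        paste(sub("^power_", "", names(pw)),
              sprintf("%.3g", unlist(pw)), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
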