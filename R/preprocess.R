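#' Zero-phase low-pass filtering of a waveform
#'
#' Applies a third-order (by default) low-pass Butterworth filter forward and
#' backward, yielding zero phase lag and the squared Butterworth magnitude
#' response. This converts raw ABP/CBFV waveforms into the slow mean-pressure
#' (MAP) and mean-velocity (MFV) signals used for autoregulation analysis:
#' the 0.5 Hz cutoff removes cardiac pulsatility while preserving the
#' very-low and low frequency oscillations of interest.
#'
#' Edges are handled by odd reflection padding of three filter orders plus
#' steady-state initial conditions, so constant signals pass through exactly.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz (default 0.5).
#' @param order Butterworth order (default 3).
#' @return Filtered waveform of the same length.
#' @examples
#' x <- 90 + sin(2 * pi * 1 * (0:1999) / 200)  # 1 Hz pulsation on 90 mmHg
#' y <- lowpass_zero_phase(x, fs = 200)
#' sd(y) < 0.01 * sd(x)
#' @export
lowpass_zero_phase <- function(signal, fs, cutoff = 0.5, order = 3) {
  if (fs <= 2 * cutoff) stop("fs must exceed 2 * cutoff")
  if (length(signal) <= 3 * order) {
    stop("signal too short for zero-phase filtering (need > ", 3 * order,
         " samples)")
  }
  coef <- butter_lowpass(order, cutoff, fs)
  filtfilt_butter(coef$b, coef$a, signal)
}

#' Extract a raw analysis window from a recording
#'
#' @param record A [signal_record()].
#' @param selection A [segment_selection()]; must lie within the record.
#' @return List with numeric vectors `abp` and `cbfv` of exactly
#'   `duration_s * fs` samples.
#' @export
extract_segment <- function(record, selection) {
  stopifnot(inherits(record, "signal_record"),
            inherits(selection, "segment_selection"))
  fs <- record$fs
  n <- length(record$abp)
  i0 <- round(selection$start_s * fs) + 1L
  len <- round(selection$duration_s * fs)
  if (i0 < 1L || i0 + len - 1L > n) {
    stop(sprintf(
      "selection [%g, %g] s out of bounds for a %.1f s record",
      selection$start_s, selection$start_s + selection$duration_s, n / fs))
  }
  idx <- i0:(i0 + len - 1L)
  list(abp = record$abp[idx], cbfv = record$cbfv[idx])
}

#' Resample a band-limited waveform to a lower uniform rate
#'
#' FFT band-limited interpolation (not naive decimation): exact for tones
#' below the output Nyquist frequency and free of phase distortion. Intended
#' for the transfer-function path, where 0.5 Hz low-passed segments are taken
#' to 10 Hz.
#'
#' @param signal Numeric waveform, already low-passed below `fs_out / 2`.
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output sampling rate (Hz, default 10); must not exceed
#'   `fs_in`.
#' @return Waveform of length `round(length(signal) * fs_out / fs_in)`.
#' @export
resample_uniform <- function(signal, fs_in, fs_out = 10) {
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  n_out <- round(length(signal) * fs_out / fs_in)
  if (n_out < 1) stop("output would be empty")
  fft_resample(signal, n_out)
}

#' Build an analysis-ready MAP/MFV segment
#'
#' Chains the preprocessing pipeline: slice the selected window from the raw
#' recording, low-pass both channels to MAP/MFV with [lowpass_zero_phase()],
#' optionally resample to the transfer-function rate, and compute segment
#' means. Per-window mean removal for spectral estimation is deliberately
#' *not* done here; it happens inside [welch_spectra()], keeping the segment
#' means physiologically meaningful.
#'
#' @param record A [signal_record()].
#' @param selection A [segment_selection()] (default: first 300 s).
#' @param for_tfa If `TRUE`, resample the filtered channels to `fs_out`
#'   (transfer-function path); if `FALSE`, keep the source rate (time-domain
#'   path).
#' @param cutoff,order Low-pass settings passed to [lowpass_zero_phase()].
#' @param fs_out Output rate for the transfer-function path (Hz, default 10).
#' @return An object of class `ca_segment` with fields `map_sig`, `mfv_sig`,
#'   `fs_out`, `mean_map`, `mean_mfv`, `duration_s`, `condition`.
#' @export
make_segment <- function(record, selection = segment_selection(),
                         for_tfa = FALSE, cutoff = 0.5, order = 3,
                         fs_out = 10) {
  raw <- extract_segment(record, selection)
  map_sig <- lowpass_zero_phase(raw$abp, record$fs, cutoff, order)
  mfv_sig <- lowpass_zero_phase(raw$cbfv, record$fs, cutoff, order)
  rate <- record$fs
  if (for_tfa) {
    map_sig <- resample_uniform(map_sig, record$fs, fs_out)
    mfv_sig <- resample_uniform(mfv_sig, record$fs, fs_out)
    rate <- fs_out
  }
  condition <- record$meta$condition
  structure(
    list(map_sig = map_sig, mfv_sig = mfv_sig, fs_out = rate,
         mean_map = mean(map_sig), mean_mfv = mean(mfv_sig),
         duration_s = selection$duration_s,
         condition = if (is.null(condition)) NA_character_ else condition),
    class = "ca_segment"
  )
}

#' @export
print.ca_segment <- function(x, ...) {
  cat(sprintf(
    "<ca_segment> %.0f s @ %g Hz%s | mean MAP %.2f mmHg, mean MFV %.2f cm/s\n",
    x$duration_s, x$fs_out,
    if (is.na(x$condition)) "" else paste0(" (", x$condition, ")"),
    x$mean_map, x$mean_mfv))
  invisible(x)
}
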