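#' Non-overlapping block averages of a waveform
#'
#' Averages consecutive, non-overlapping blocks of `block_s` seconds,
#' anchored at the signal start; a trailing partial block is discarded.
#' This is the slow-wave extraction step of the Mx index: 10-second averages
#' suppress pulse and respiratory fluctuations while retaining the slow
#' pressure/flow excursions that autoregulation acts on.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate (Hz); `fs * block_s` must be integral.
#' @param block_s Block length in seconds (default 10).
#' @return Numeric vector of block means (length `floor(n / (fs * block_s))`).
#' @examples
#' block_average(0:299, fs = 1, block_s = 10)  # 4.5, 14.5, ..., 294.5
#' @export
block_average <- function(signal, fs, block_s = 10) {
  bl <- fs * block_s
  if (abs(bl - round(bl)) > 1e-9) stop("fs * block_s must be an integer")
  bl <- as.integer(round(bl))
  n_blocks <- length(signal) %/% bl
  if (n_blocks < 2L) stop("signal shorter than two blocks")
  colMeans(matrix(signal[seq_len(n_blocks * bl)], nrow = bl))
}

#' Mx autoregulation index
#'
#' The mean flow velocity index Mx is the Pearson correlation between
#' 10-second averages of arterial pressure and cerebral blood-flow velocity
#' over an analysis window (conventionally 5 minutes, giving 30 blocks).
#' When autoregulation is intact, slow pressure excursions are buffered and
#' flow decouples from pressure (low or negative Mx); when it is impaired,
#' flow passively follows pressure (high positive Mx). Classification:
#' `mx > cutoff` (default 0.3) is read as impaired (absent) autoregulation,
#' `mx <= cutoff` as intact — high pressure-flow correlation means
#' pressure-passive flow.
#'
#' @param segment A `ca_segment` from [make_segment()] (time-domain path;
#'   block averaging makes the exact rate immaterial, but the source-rate
#'   filtered signals are the convention).
#' @param cutoff Classification threshold (default 0.3).
#' @param block_s Block length in seconds (default 10).
#' @return Object of class `mx_result`: `mx`, `n_blocks`, `classification`
#'   (`"intact"` or `"impaired"`), `cutoff`.
#' @export
compute_mx <- function(segment, cutoff = 0.3, block_s = 10) {
  stopifnot(inherits(segment, "ca_segment"))
  bp <- block_average(segment$map_sig, segment$fs_out, block_s)
  fv <- block_average(segment$mfv_sig, segment$fs_out, block_s)
  if (stats::sd(bp) == 0 || stats::sd(fv) == 0) {
    stop("Mx undefined: constant input")
  }
  mx <- stats::cor(bp, fv)
  structure(list(mx = mx, n_blocks = length(bp),
                 classification = if (mx > cutoff) "impaired" else "intact",
                 cutoff = cutoff),
            class = "mx_result")
}

#' @export
print.mx_result <- function(x, ...) {
  cat(sprintf("<mx_result> Mx = %.4f over %d blocks: %s (cutoff %.2f)\n",
              x$mx, x$n_blocks, x$classification, x$cutoff))
  invisible(x)
}
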