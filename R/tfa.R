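#' Transfer-function analysis settings
#'
#' Bundles the spectral-estimation parameters for MAP-to-MFV transfer
#' function analysis. Defaults follow the standard recommendations for
#' dynamic cerebral autoregulation studies: 100-s Hanning windows with 50%
#' overlap on 10 Hz signals, 3-point triangular spectral smoothing, band
#' averages over VLF (0.02-0.07 Hz) and LF (0.07-0.2 Hz), and a critical
#' coherence of 0.34 below which gain/phase are flagged unreliable (the
#' Monte-Carlo 95% null quantile for five windows with this smoothing; see
#' [critical_coherence()]).
#'
#' @param window_s Welch window length in seconds (default 100).
#' @param overlap_frac Fractional overlap between windows, in (0, 1)
#'   (default 0.5).
#' @param smooth_points Odd width (>= 1) of the triangular moving-average
#'   spectral smoother (default 3; 1 disables smoothing).
#' @param fs Sampling rate of the analyzed segments (Hz, default 10).
#' @param bands Data frame with columns `name`, `f_lo`, `f_hi` (Hz); bands
#'   must be ascending and non-overlapping. Bin membership is by center
#'   frequency, half-open `[f_lo, f_hi)`.
#' @param coherence_cutoff Band-average squared coherence below which
#'   gain/phase are considered unreliable (default 0.34).
#' @return Object of class `tfa_settings`.
#' @export
tfa_settings <- function(window_s = 100, overlap_frac = 0.5,
                         smooth_points = 3, fs = 10,
                         bands = data.frame(
                           name = c("vlf", "lf"),
                           f_lo = c(0.02, 0.07),
                           f_hi = c(0.07, 0.20)),
                         coherence_cutoff = 0.34) {
  if (overlap_frac <= 0 || overlap_frac >= 1) {
    stop("overlap_frac must be in (0, 1)")
  }
  if (smooth_points < 1 || smooth_points %% 2 == 0) {
    stop("smooth_points must be an odd integer >= 1")
  }
  stopifnot(all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo >= bands$f_hi)) stop("each band needs f_lo < f_hi")
  if (nrow(bands) > 1 &&
      any(bands$f_lo[-1] < bands$f_hi[-nrow(bands)])) {
    stop("bands must be ascending and non-overlapping")
  }
  structure(list(window_s = window_s, overlap_frac = overlap_frac,
                 taper = "hanning", smooth_points = as.integer(smooth_points),
                 fs = fs, bands = bands,
                 coherence_cutoff = coherence_cutoff),
            class = "tfa_settings")
}

# Triangular moving average of odd width m (weights 1,2,...,k+1,...,2,1),
# renormalized near the edges; works for real or complex input.
triangular_smooth <- function(v, m) {
  if (m <= 1L) return(v)
  k <- (m - 1L) %/% 2L
  w <- c(seq_len(k + 1L), rev(seq_len(k)))
  n <- length(v)
  conv1 <- function(u) {
    as.numeric(stats::filter(u, w, method = "convolution", sides = 2))
  }
  num <- if (is.complex(v)) {
    complex(real = conv1(Re(v)), imaginary = conv1(Im(v)))
  } else conv1(v)
  out <- num / sum(w)
  # partial windows at the edges, renormalized by the included weights
  for (i in unique(c(seq_len(min(k, n)), seq.int(max(1L, n - k + 1L), n)))) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    ww <- w[(lo - i + k + 1L):(hi - i + k + 1L)]
    out[i] <- sum(v[lo:hi] * ww) / sum(ww)
  }
  out
}

#' Welch auto- and cross-spectra of two waveforms
#'
#' Averaged-periodogram estimation over sliding Hanning-tapered windows with
#' per-window mean removal, power normalization to one-sided spectral
#' density, and triangular spectral smoothing. The cross-spectrum is defined
#' as `conj(FFT(x)) * FFT(y)`, so a positive cross-spectral phase means `y`
#' leads `x`.
#'
#' @param x,y Equal-length numeric waveforms sampled at `settings$fs`
#'   (convention: `x` = input/MAP, `y` = output/MFV).
#' @param settings A [tfa_settings()].
#' @return List with `freqs` (Hz), real vectors `Sxx`, `Syy`, complex `Sxy`
#'   (all smoothed), and `n_windows`.
#' @export
welch_spectra <- function(x, y, settings = tfa_settings()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  W <- round(settings$window_s * settings$fs)
  if (length(x) < W) {
    stop("input shorter than one analysis window (", W, " samples)")
  }
  step <- round(W * (1 - settings$overlap_frac))
  starts <- seq(1L, length(x) - W + 1L, by = step)
  win <- hann_window(W)
  U <- sum(win^2)
  nf <- W %/% 2L + 1L
  idx <- outer(0:(W - 1L), starts, "+")
  Xm <- matrix(x[idx], nrow = W)
  Ym <- matrix(y[idx], nrow = W)
  Xm <- sweep(Xm, 2, colMeans(Xm)) * win
  Ym <- sweep(Ym, 2, colMeans(Ym)) * win
  Fx <- stats::mvfft(Xm)[seq_len(nf), , drop = FALSE]
  Fy <- stats::mvfft(Ym)[seq_len(nf), , drop = FALSE]
  scale <- 2 / (settings$fs * U)         # one-sided density normalization
  Sxx <- rowMeans(Re(Fx * Conj(Fx))) * scale
  Syy <- rowMeans(Re(Fy * Conj(Fy))) * scale
  Sxy <- rowMeans(Conj(Fx) * Fy) * scale
  # DC and (even-W) Nyquist bins are not doubled in a one-sided spectrum
  Sxx[1] <- Sxx[1] / 2; Syy[1] <- Syy[1] / 2; Sxy[1] <- Sxy[1] / 2
  if (W %% 2L == 0L) {
    Sxx[nf] <- Sxx[nf] / 2; Syy[nf] <- Syy[nf] / 2; Sxy[nf] <- Sxy[nf] / 2
  }
  m <- settings$smooth_points
  list(freqs = (0:(nf - 1L)) * settings$fs / W,
       Sxx = triangular_smooth(Sxx, m),
       Syy = triangular_smooth(Syy, m),
       Sxy = triangular_smooth(Sxy, m),
       n_windows = length(starts))
}

#' Coherence, gain and phase from cross-spectra
#'
#' Computes the squared coherence `|Sxy|^2 / (Sxx * Syy)`, the transfer gain
#' `|Sxy| / Sxx` ((cm/s)/mmHg for MAP-to-MFV), and the phase `arg(Sxy)` in
#' degrees, principal value (-180, 180], with positive phase meaning the
#' output (MFV) leads the input (MAP). Bins with a non-positive auto-spectrum
#' are flagged invalid (`NA`) and are excluded from band averages.
#'
#' @param spectra List from [welch_spectra()].
#' @return List with `freqs`, `coherence`, `gain`, `phase_deg`, `valid`
#'   (logical per bin), `n_windows`.
#' @export
transfer_function <- function(spectra) {
  Sxx <- spectra$Sxx; Syy <- spectra$Syy; Sxy <- spectra$Sxy
  valid <- is.finite(Sxx) & is.finite(Syy) & Sxx > 0 & Syy > 0
  coherence <- gain <- phase <- rep(NA_real_, length(Sxx))
  coherence[valid] <- pmin(1, Mod(Sxy[valid])^2 / (Sxx[valid] * Syy[valid]))
  gain[valid] <- Mod(Sxy[valid]) / Sxx[valid]
  phase[valid] <- Arg(Sxy[valid]) * 180 / pi
  list(freqs = spectra$freqs, coherence = coherence, gain = gain,
       phase_deg = phase, valid = valid, n_windows = spectra$n_windows)
}

#' Band average of a per-bin quantity
#'
#' Unweighted arithmetic mean over bins whose center frequency falls in
#' `[f_lo, f_hi)`. For phase values (`circular = TRUE`) the band is first
#' checked for wrap-around at +/-180 degrees and unwrapped before averaging,
#' then mapped back to the principal value.
#'
#' @param values Per-bin numeric vector (possibly containing `NA` for invalid
#'   bins, which are dropped).
#' @param freqs Bin center frequencies (Hz).
#' @param f_lo,f_hi Band edges in Hz, half-open `[f_lo, f_hi)`.
#' @param circular Treat values as angles in degrees.
#' @return Scalar band average.
#' @export
band_average <- function(values, freqs, f_lo, f_hi, circular = FALSE) {
  sel <- freqs >= f_lo & freqs < f_hi & !is.na(values)
  if (!any(sel)) stop(sprintf("empty band [%g, %g) Hz", f_lo, f_hi))
  v <- values[sel]
  if (circular && length(v) > 1L && diff(range(v)) > 180) {
    v <- ifelse(v < 0, v + 360, v)       # unwrap a band straddling +/-180
    m <- mean(v)
    if (m > 180) m <- m - 360
    return(m)
  }
  mean(v)
}

#' Monte-Carlo critical coherence threshold
#'
#' Estimates the null distribution of estimated squared coherence between
#' *independent* signals under a given spectral-estimation configuration, and
#' returns its upper quantile: coherence estimates below this threshold are
#' indistinguishable from no linear coupling, so gain/phase read-outs there
#' are unreliable. Pairs of independent Gaussian white-noise signals of
#' `duration_s` seconds at `settings$fs` are analyzed with the exact
#' [welch_spectra()] settings; the default pools the *per-bin* coherence
#' values over all analysis-band bins, which with five 100-s half-overlapping
#' Hanning windows and 3-point triangular smoothing reproduces the
#' conventional 0.34 threshold. `per_bin = FALSE` instead pools the
#' band-averaged coherences (a stricter null because averaging across bins
#' shrinks the upper tail).
#'
#' @param settings A [tfa_settings()].
#' @param alpha Tail probability (default 0.05 for a 95% threshold).
#' @param n_sim Number of simulated pairs (>= 100; use >= 1000 for a stable
#'   estimate, >= 5000 for calibration work).
#' @param seed Integer RNG seed.
#' @param duration_s Surrogate length in seconds (default 300).
#' @param per_bin Pool per-bin values (default) or band averages.
#' @return The (1 - alpha) quantile of the null coherence distribution.
#' @examples
#' \donttest{
#' critical_coherence(n_sim = 1000, seed = 1)  # approximately 0.34
#' }
#' @export
critical_coherence <- function(settings = tfa_settings(), alpha = 0.05,
                               n_sim = 1000, seed = 1, duration_s = 300,
                               per_bin = TRUE) {
  if (n_sim < 100) stop("n_sim too small for a tail quantile (use >= 100)")
  n <- round(duration_s * settings$fs)
  W <- round(settings$window_s * settings$fs)
  freqs <- (0:(W %/% 2L)) * settings$fs / W
  in_band <- rep(FALSE, length(freqs))
  for (b in seq_len(nrow(settings$bands))) {
    in_band <- in_band | (freqs >= settings$bands$f_lo[b] &
                          freqs < settings$bands$f_hi[b])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    sp <- welch_spectra(stats::rnorm(n), stats::rnorm(n), settings)
    coh <- Mod(sp$Sxy)^2 / (sp$Sxx * sp$Syy)
    if (per_bin) {
      draws[[i]] <- coh[in_band]
    } else {
      draws[[i]] <- vapply(seq_len(nrow(settings$bands)), function(b) {
        band_average(coh, sp$freqs, settings$bands$f_lo[b],
                     settings$bands$f_hi[b])
      }, numeric(1))
    }
  }
  stats::quantile(unlist(draws), probs = 1 - alpha, names = FALSE, type = 7)
}

# Save/restore .Random.seed so seeded helpers do not clobber the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run transfer-function analysis on an analysis segment
#'
#' Full MAP-to-MFV transfer-function analysis: Welch auto/cross spectra,
#' per-bin coherence/gain/phase, and band averages with reliability flags.
#' A band is flagged `reliable` when its average coherence exceeds
#' `settings$coherence_cutoff`; band gain and phase are reported regardless,
#' so callers can reproduce both gated and ungated read-outs.
#'
#' @param segment A `ca_segment` from [make_segment()] with
#'   `fs_out == settings$fs` (the transfer-function path).
#' @param settings A [tfa_settings()].
#' @return Object of class `tfa_result`: per-bin `freqs`, `coherence`,
#'   `gain`, `phase_deg`; `band_results` data frame (one row per band with
#'   `coherence`, `gain`, `phase_deg`, `reliable`); `n_windows`; `settings`.
#' @export
run_tfa <- function(segment, settings = tfa_settings()) {
  stopifnot(inherits(segment, "ca_segment"))
  if (abs(segment$fs_out - settings$fs) > 1e-9) {
    stop("segment rate (", segment$fs_out, " Hz) differs from settings$fs (",
         settings$fs, " Hz); build the segment with for_tfa = TRUE")
  }
  sp <- welch_spectra(segment$map_sig, segment$mfv_sig, settings)
  tf <- transfer_function(sp)
  bands <- settings$bands
  band_results <- data.frame(
    band = bands$name, f_lo = bands$f_lo, f_hi = bands$f_hi,
    coherence = NA_real_, gain = NA_real_, phase_deg = NA_real_,
    reliable = NA)
  for (b in seq_len(nrow(bands))) {
    band_results$coherence[b] <- band_average(tf$coherence, tf$freqs,
                                              bands$f_lo[b], bands$f_hi[b])
    band_results$gain[b] <- band_average(tf$gain, tf$freqs,
                                         bands$f_lo[b], bands$f_hi[b])
    band_results$phase_deg[b] <- band_average(tf$phase_deg, tf$freqs,
                                              bands$f_lo[b], bands$f_hi[b],
                                              circular = TRUE)
    band_results$reliable[b] <-
      band_results$coherence[b] > settings$coherence_cutoff
  }
  structure(list(freqs = tf$freqs, coherence = tf$coherence, gain = tf$gain,
                 phase_deg = tf$phase_deg, valid = tf$valid,
                 band_results = band_results, n_windows = tf$n_windows,
                 settings = settings),
            class = "tfa_result")
}

#' @export
print.tfa_result <- function(x, ...) {
  cat(sprintf("<tfa_result> %d windows, %d frequency bins\n",
              x$n_windows, length(x$freqs)))
  br <- x$band_results
  for (b in seq_len(nrow(br))) {
    cat(sprintf(
      "  %-4s [%.2f, %.2f) Hz: coherence %.3f, gain %.3f (cm/s)/mmHg, phase %7.2f deg%s\n",
      toupper(br$band[b]), br$f_lo[b], br$f_hi[b], br$coherence[b],
      br$gain[b], br$phase_deg[b],
      if (br$reliable[b]) "" else "  [unreliable]"))
  }
  invisible(x)
}
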