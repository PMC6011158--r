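# Minimal IIR/FFT signal-processing primitives (no external DSP dependency).

# Polynomial coefficients (descending powers) from roots, complex-safe.
poly_from_roots <- function(r) {
  co <- 1 + 0i
  for (ri in r) co <- c(co, 0 + 0i) - ri * c(0 + 0i, co)
  co
}

#' Digital low-pass Butterworth coefficients
#'
#' Designs an order-`n` low-pass Butterworth filter by the bilinear transform
#' with frequency pre-warping, returning transfer-function coefficients
#' `b` (numerator) and `a` (denominator) with `a[1] = 1` and unit DC gain.
#'
#' @param order Filter order (>= 1).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz; requires `fs > 2 * cutoff`.
#' @return List with numeric vectors `b` and `a` of length `order + 1`.
#' @keywords internal
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  if (order < 1) stop("order must be >= 1")
  if (fs <= 2 * cutoff) stop("fs must exceed 2 * cutoff")
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p <- p * warped
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)            # bilinear-transformed poles
  gain <- Re(warped^order / prod(fs2 - p))
  b <- Re(gain * poly_from_roots(rep(-1 + 0i, order)))  # zeros at z = -1
  a <- Re(poly_from_roots(pz))
  b <- b / a[1]; a <- a / a[1]
  # enforce exact unit DC gain (guards rounding in the pole product)
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# Linear filtering with steady-state initialization at level x0: equivalent to
# assuming the input sat at x0 for all time before the first sample. Uses
# stats::filter (C implementation) for both the FIR and recursive parts.
lfilter_steady <- function(b, a, x, x0) {
  nb <- length(b)
  xx <- c(rep(x0, nb - 1), x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xx)]
  y0 <- x0 * sum(b) / sum(a)
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = rep(y0, length(a) - 1)))
  }
  v
}

# Zero-phase forward-backward filtering with odd-reflection edge padding of
# 3 x filter order. Steady-state initial conditions suppress start-up
# transients; the effective magnitude response is |H|^2 with zero phase.
filtfilt_butter <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * (length(a) - 1L)
  if (n <= padlen) stop("signal too short for zero-phase filtering (need > ",
                        padlen, " samples)")
  head_pad <- 2 * x[1] - x[(padlen + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(head_pad, x, tail_pad)
  y <- lfilter_steady(b, a, ext, ext[1])
  y <- rev(lfilter_steady(b, a, rev(y), y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

# Symmetric Hann taper of length n.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# FFT band-limited resampling of a real signal to n_out samples over the same
# duration. A linear trend through the endpoints is removed first so the
# periodic extension implied by the DFT has no large wrap-around jump, then
# re-added at the output sample times.
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  slope <- if (n_in > 1L) (x[n_in] - x[1]) / (n_in - 1) else 0
  trend_in <- x[1] + slope * (0:(n_in - 1))
  d <- x - trend_in
  X <- stats::fft(d)
  Y <- complex(n_out)
  h <- min(n_in, n_out) %/% 2          # half-bandwidth kept
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h >= 1) Y[(n_out - h + 1):n_out] <- X[(n_in - h + 1):n_in]
  if (min(n_in, n_out) %% 2 == 0) {
    # shared Nyquist bin: keep it real to preserve a real output
    Y[h + 1] <- Re(Y[h + 1])
    if (n_out > n_in) Y[n_out - h + 1] <- Re(X[h + 1])
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n_in
  step <- n_in / n_out                   # output spacing in input-sample units
  y + x[1] + slope * (0:(n_out - 1)) * step
}

# 1/f ("pink") noise of length n, unit variance, via spectral shaping of
# Gaussian white noise. Deterministic given the RNG state.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  k <- 0:(n - 1)
  fidx <- pmin(k, n - k)                 # two-sided frequency index, symmetric
  fidx[1] <- 1                           # placeholder; DC is zeroed below
  X <- X / sqrt(fidx)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}
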