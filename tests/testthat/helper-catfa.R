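# Build a ca_segment directly from two channels (bypasses preprocessing; used
# where a test needs exact control over the analyzed signals).
segment_from <- function(map_sig, mfv_sig, fs, condition = NA_character_) {
  structure(list(map_sig = map_sig, mfv_sig = mfv_sig, fs_out = fs,
                 mean_map = mean(map_sig), mean_mfv = mean(mfv_sig),
                 duration_s = length(map_sig) / fs, condition = condition),
            class = "ca_segment")
}

# Least-squares amplitude and phase (degrees) of a known-frequency tone.
fit_tone <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  amp <- sqrt(co[2]^2 + co[3]^2)
  list(amp = unname(amp), phase_deg = unname(atan2(co[3], co[2]) * 180 / pi))
}

# A small synthetic two-channel record: slow sinusoids on physiologic means.
toy_record <- function(duration_s = 330, fs = 25, condition = "baseline",
                       seed = 1) {
  set.seed(seed)
  t <- (0:(duration_s * fs - 1)) / fs
  abp <- 90 + 2 * sin(2 * pi * 0.03 * t) + 1.2 * sin(2 * pi * 0.1 * t) +
    0.5 * rnorm(length(t))
  cbfv <- 40 + 0.9 * sin(2 * pi * 0.03 * t + 0.6) +
    0.6 * sin(2 * pi * 0.1 * t + 0.3) + 0.3 * rnorm(length(t))
  signal_record(abp, cbfv, fs, meta = list(condition = condition))
}
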