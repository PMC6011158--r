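test_that("settings are validated", {
  expect_error(tfa_settings(overlap_frac = 0), "overlap_frac")
  expect_error(tfa_settings(smooth_points = 2), "odd")
  expect_error(tfa_settings(bands = data.frame(name = c("a", "b"),
                                               f_lo = c(0.02, 0.05),
                                               f_hi = c(0.07, 0.2))),
               "non-overlapping")
})

test_that("Welch windowing arithmetic and self-spectrum identity hold", {
  set.seed(5)
  x <- rnorm(3000)
  sp <- welch_spectra(x, x, tfa_settings())
  expect_equal(sp$n_windows, 5)            # (3000 - 1000) / 500 + 1
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.01)
  # x = y: cross-spectrum equals (real) auto-spectrum, coherence exactly 1
  expect_lt(max(Mod(sp$Sxy - sp$Sxx)), 1e-12)
  coh <- Mod(sp$Sxy)^2 / (sp$Sxx * sp$Syy)
  expect_equal(max(abs(coh - 1)), 0, tolerance = 1e-10)
  expect_error(welch_spectra(rnorm(500), rnorm(500), tfa_settings()),
               "shorter than one analysis window")
})

test_that("one-sided tone power integrates to A^2/2 (Parseval)", {
  fs <- 10
  x <- sin(2 * pi * 0.1 * (0:2999) / fs)
  sp <- welch_spectra(x, x, tfa_settings())
  df <- sp$freqs[2] - sp$freqs[1]
  expect_equal(sum(sp$Sxx) * df, 0.5, tolerance = 0.05)
})

test_that("transfer function recovers scaling, delay and incoherence", {
  set.seed(6)
  fs <- 10
  x <- rnorm(3000)
  st <- tfa_settings()

  # pure scaling: gain 2, phase 0, coherence 1 on all valid bins
  tf <- transfer_function(welch_spectra(x, 2 * x, st))
  inband <- tf$freqs >= 0.02 & tf$freqs < 0.2
  expect_equal(max(abs(tf$gain[inband] - 2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(tf$phase_deg[inband])), 0, tolerance = 1e-9)
  expect_equal(min(tf$coherence[inband]), 1, tolerance = 1e-9)

  # 1-s delay: phase = -360 * f degrees; gain 1 for a tone
  t <- (0:2999) / fs
  xd <- sin(2 * pi * 0.1 * t)
  yd <- sin(2 * pi * 0.1 * (t - 1))
  tfd <- transfer_function(welch_spectra(xd, yd, st))
  i <- which.min(abs(tfd$freqs - 0.1))
  expect_equal(tfd$phase_deg[i], -36, tolerance = 0.5)
  expect_equal(tfd$gain[i], 1, tolerance = 0.01)
})

test_that("band averages handle constants, ramps and phase wrap", {
  freqs <- seq(0, 0.5, by = 0.01)
  vals <- rep(3, length(freqs))
  expect_equal(band_average(vals, freqs, 0.02, 0.07), 3)
  # linear ramp over bins -> midpoint value
  ramp <- freqs * 10
  expect_equal(band_average(ramp, freqs, 0.02, 0.07),
               mean(c(0.02, 0.03, 0.04, 0.05, 0.06) * 10))
  # single bin
  expect_equal(band_average(ramp, freqs, 0.07, 0.08), 0.7)
  # phase wrap at +/-180: mean of 179 and -179 is 180, not 0
  ph <- rep(NA_real_, length(freqs))
  ph[freqs >= 0.02 & freqs < 0.04] <- c(179, -179)
  expect_equal(band_average(ph, freqs, 0.02, 0.04, circular = TRUE), 180)
  expect_error(band_average(ph, freqs, 0.3, 0.4), "empty band")
})

test_that("run_tfa on identical channels gives the trivial transfer function", {
  x <- 90 + cumsum(rnorm(3000)) * 0.02
  seg <- segment_from(x, x, fs = 10)
  res <- run_tfa(seg)
  expect_equal(res$band_results$coherence, c(1, 1), tolerance = 1e-9)
  expect_equal(res$band_results$gain, c(1, 1), tolerance = 1e-9)
  expect_equal(res$band_results$phase_deg, c(0, 0), tolerance = 1e-7)
  expect_true(all(res$band_results$reliable))
  expect_error(run_tfa(segment_from(x, x, fs = 20)), "differs from settings")
})

test_that("gain scales with the output channel; phase and coherence do not", {
  set.seed(7)
  x <- rnorm(3000)
  y <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  y[is.na(y)] <- 0
  y <- as.numeric(y) + 0.1 * rnorm(3000)
  r1 <- run_tfa(segment_from(x, y, fs = 10))
  r2 <- run_tfa(segment_from(x, 3 * y, fs = 10))
  expect_equal(r2$band_results$gain, 3 * r1$band_results$gain,
               tolerance = 1e-9)
  expect_equal(r2$band_results$phase_deg, r1$band_results$phase_deg,
               tolerance = 1e-9)
  expect_equal(r2$band_results$coherence, r1$band_results$coherence,
               tolerance = 1e-9)
  # positive scaling of the input leaves phase untouched too
  r3 <- run_tfa(segment_from(2 * x, y, fs = 10))
  expect_equal(r3$band_results$phase_deg, r1$band_results$phase_deg,
               tolerance = 1e-9)
})

test_that("swapping input and output inverts gain and negates phase", {
  cfg <- synthetic_config(seed = 12, model = autoreg_model(noise_cv = 0))
  abp <- generate_abp(cfg, "intervention")
  cbfv <- as.numeric(generate_cbfv(abp, cfg))
  rec <- signal_record(abp, cbfv, cfg$fs)
  fwd <- run_tfa(make_segment(rec, segment_selection(30, 300), for_tfa = TRUE))
  rev_rec <- signal_record(cbfv, abp, cfg$fs)
  bwd <- run_tfa(make_segment(rev_rec, segment_selection(30, 300),
                              for_tfa = TRUE))
  expect_equal(bwd$band_results$gain * fwd$band_results$gain, c(1, 1),
               tolerance = 0.05)
  expect_equal(bwd$band_results$phase_deg, -fwd$band_results$phase_deg,
               tolerance = 1)
})

test_that("critical coherence behaves as an estimator-null quantile", {
  st <- tfa_settings()
  # degenerate: one window, no smoothing -> coherence identically 1
  thr1 <- critical_coherence(tfa_settings(smooth_points = 1), n_sim = 100,
                             seed = 2, duration_s = 100)
  expect_gt(thr1, 0.999)
  # more windows -> lower threshold (estimator bias shrinks with averaging)
  thr5 <- critical_coherence(st, n_sim = 300, seed = 3, duration_s = 300)
  thr29 <- critical_coherence(st, n_sim = 300, seed = 3, duration_s = 1500)
  expect_lt(thr29, thr5)
  # more smoothing -> lower threshold
  thr_smooth5 <- critical_coherence(tfa_settings(smooth_points = 5),
                                    n_sim = 300, seed = 3, duration_s = 300)
  expect_lt(thr_smooth5, thr5)
  # band-averaged null is stricter than per-bin
  thr_band <- critical_coherence(st, n_sim = 300, seed = 3, per_bin = FALSE)
  expect_lt(thr_band, thr5)
  expect_error(critical_coherence(n_sim = 50), "n_sim")
})
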