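test_that("tilt wave has the protocol's structure", {
  p <- tilt_protocol()
  expect_equal(p$total_s, 360)
  fs <- 10
  w <- generate_tilt_wave(p, fs)
  expect_length(w, 360 * fs)
  runs <- rle(as.vector(w))
  expect_equal(sum(runs$values == -30 & runs$lengths > 1), 3)
  expect_equal(sum(runs$values == 30 & runs$lengths > 1), 3)
  expect_true(w[1] == -30)                      # starts in Trendelenburg
  expect_true(all(abs(w) <= 30))
  # fundamental period = one cycle = 120 s
  expect_equal(w[1:(240 * fs)], w[(120 * fs + 1):(360 * fs)])
  expect_false(isTRUE(all.equal(w[1:(60 * fs)], w[(60 * fs + 1):(120 * fs)])))

  one <- generate_tilt_wave(tilt_protocol(n_cycles = 1), fs)
  expect_length(one, 120 * fs)
  r1 <- rle(as.vector(one))
  expect_equal(sum(r1$values == -30 & r1$lengths > 1), 1)
  expect_equal(sum(r1$values == 30 & r1$lengths > 1), 1)
})

test_that("generated ABP hits the stated CV calibration windows", {
  cfg <- synthetic_config(seed = 1)
  base <- generate_abp(cfg, "baseline")
  intv <- generate_abp(cfg, "intervention")
  rec_b <- signal_record(base, base, cfg$fs)
  rec_i <- signal_record(intv, intv, cfg$fs)
  cv_b <- coefficient_of_variation(
    make_segment(rec_b, segment_selection(30, 300))$map_sig)
  cv_i <- coefficient_of_variation(
    make_segment(rec_i, segment_selection(30, 300))$map_sig)
  expect_gt(cv_b, 2.75); expect_lt(cv_b, 3.36)   # within 10% of 3.056
  expect_gt(cv_i, 7.40); expect_lt(cv_i, 9.10)   # within 10% of 8.238
  expect_gt(cv_i, cv_b)
})

test_that("generator is deterministic and handles degenerate/unattainable configs", {
  cfg <- synthetic_config(seed = 42, fs = 50)
  expect_identical(generate_abp(cfg, "intervention"),
                   generate_abp(cfg, "intervention"))
  zero <- synthetic_config(
    seed = 1, fs = 50,
    oscillations = data.frame(freq = 0.03, amp = 0, phase = 0),
    resp_amp = 0, cardiac_amp = 0, pink_sd = 0)
  flat <- generate_abp(zero, "baseline")
  expect_equal(flat, rep(90, length(flat)))
  expect_equal(coefficient_of_variation(flat), 0)
  big <- synthetic_config(seed = 1, fs = 50, baseline_cv_target = 60,
                          intervention_cv_target = 80)
  expect_error(generate_abp(big, "baseline"), "unattainable")
  expect_error(synthetic_config(baseline_cv_target = 8,
                                intervention_cv_target = 3))
})

test_that("identity autoregulation model reproduces the pressure channel", {
  cfg <- synthetic_config(
    seed = 9, fs = 50, mean_map = 90, mean_mfv = 90,
    model = autoreg_model(band_gain = c(vlf = 1, lf = 1),
                          band_phase_deg = c(vlf = 0, lf = 0),
                          noise_cv = 0))
  abp <- generate_abp(cfg, "baseline")
  cbfv <- generate_cbfv(abp, cfg)
  # affine copy: identical fluctuation, mean set to mean_mfv
  expect_equal(as.numeric(cbfv) - mean(cbfv), abp - mean(abp),
               tolerance = 1e-8)
  expect_equal(mean(cbfv), 90, tolerance = 1e-9)
  rec <- signal_record(abp, as.numeric(cbfv), cfg$fs)
  seg <- make_segment(rec, segment_selection(30, 300))
  expect_equal(compute_mx(seg)$mx, 1.0, tolerance = 1e-6)
  tfa <- run_tfa(make_segment(rec, segment_selection(30, 300), for_tfa = TRUE))
  expect_equal(tfa$band_results$coherence, c(1, 1), tolerance = 1e-6)
  expect_equal(tfa$band_results$gain, c(1, 1), tolerance = 1e-4)
})

test_that("ground truth is stored and impaired models are pressure-passive", {
  cfg <- synthetic_config(seed = 3, fs = 50)
  abp <- generate_abp(cfg, "intervention")
  gt <- attr(generate_cbfv(abp, cfg), "ground_truth")
  expect_equal(gt$band, c("vlf", "lf"))
  # VLF bins (0.02-0.06 on the 0.01 Hz grid) all sit on the model plateau;
  # the first LF bin (0.07) sits on the band-edge blend, its 12 neighbours on
  # the LF plateau
  expect_equal(gt$gain, c(0.35, ((0.35 + 0.55) / 2 + 12 * 0.55) / 13),
               tolerance = 1e-9)
  expect_equal(gt$phase_deg, c(50, ((50 + 25) / 2 + 12 * 25) / 13),
               tolerance = 1e-9)

  cfg_imp <- synthetic_config(seed = 3, fs = 50,
                              model = autoreg_model(impaired = TRUE))
  gti <- attr(generate_cbfv(abp, cfg_imp), "ground_truth")
  expect_equal(gti$gain, rep(40 / 90, 2), tolerance = 1e-9)
  expect_equal(gti$phase_deg, c(0, 0))
})

test_that("added flow noise monotonically degrades recovered coherence", {
  cohs <- vapply(c(0, 3, 8), function(nc) {
    cfg <- synthetic_config(seed = 5, fs = 50,
                            model = autoreg_model(noise_cv = nc))
    abp <- generate_abp(cfg, "intervention")
    cbfv <- as.numeric(generate_cbfv(abp, cfg))
    rec <- signal_record(abp, cbfv, cfg$fs)
    tfa <- run_tfa(make_segment(rec, segment_selection(30, 300),
                                for_tfa = TRUE))
    mean(tfa$band_results$coherence)
  }, numeric(1))
  expect_true(all(diff(cohs) < 0))
})

test_that("cohorts have the right shape, mixture and pairing direction", {
  cfg <- synthetic_config(fs = 25)
  pairs <- generate_cohort(n_subjects = 3, n_timepoints = 2, mix = 0,
                           seed = 7, config = cfg)
  expect_length(pairs, 6)
  expect_named(pairs[[1]], c("baseline", "intervention"))
  expect_true(all(!vapply(pairs, function(p) p$baseline$meta$impaired,
                          logical(1))))
  # 13 subjects x 4 timepoints -> 52 pairs = 104 records
  expect_length(generate_cohort(2, 2, seed = 1,
                                config = synthetic_config(fs = 5,
                                                          cardiac_amp = 0)),
                4)
  # determinism
  p1 <- generate_cohort(2, 1, mix = 0.5, seed = 11, config = cfg)
  p2 <- generate_cohort(2, 1, mix = 0.5, seed = 11, config = cfg)
  expect_identical(p1[[1]]$intervention$abp, p2[[1]]$intervention$abp)
  # every pair: intervention CV above baseline CV (structural invariant)
  for (p in pairs[1:3]) {
    cv <- vapply(p, function(rec) {
      coefficient_of_variation(
        make_segment(rec, segment_selection(30, 300))$map_sig)
    }, numeric(1))
    expect_gt(cv[["intervention"]], cv[["baseline"]])
  }
})
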