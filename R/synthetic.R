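#' Bed-tilt intervention protocol
#'
#' Describes the repeated Trendelenburg / anti-Trendelenburg bed-tilting
#' protocol used to induce slow blood-pressure oscillations: the bed is moved
#' over `transition_s` seconds between head-down (-`angle_deg`) and head-up
#' (+`angle_deg`) positions and held for `hold_s` seconds in each, for
#' `n_cycles` full cycles. The default (3 cycles of 15 s transitions and 45 s
#' holds at 30 degrees) spans 360 s with a fundamental period of 120 s
#' (~0.0083 Hz), driving pressure power into the very-low-frequency range.
#'
#' @param n_cycles Number of full tilt cycles (default 3).
#' @param transition_s Transition duration in seconds (default 15).
#' @param hold_s Plateau duration in seconds (default 45).
#' @param angle_deg Tilt amplitude in degrees (default 30).
#' @return Object of class `tilt_protocol` including the derived `total_s`.
#' @export
tilt_protocol <- function(n_cycles = 3, transition_s = 15, hold_s = 45,
                          angle_deg = 30) {
  stopifnot(n_cycles >= 1, transition_s > 0, hold_s > 0, angle_deg > 0)
  structure(list(n_cycles = n_cycles, transition_s = transition_s,
                 hold_s = hold_s, angle_deg = angle_deg,
                 total_s = n_cycles * 2 * (transition_s + hold_s)),
            class = "tilt_protocol")
}

#' Tilt-angle waveform of a bed-tilt protocol
#'
#' Trapezoidal bed-angle trace in degrees: the trace starts on the
#' Trendelenburg plateau (-`angle_deg`), ramps linearly to +`angle_deg` over
#' `transition_s`, holds, and ramps back, repeated `n_cycles` times — exactly
#' `n_cycles` head-down and `n_cycles` head-up plateaus.
#'
#' @param protocol A [tilt_protocol()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of length `protocol$total_s * fs` (degrees).
#' @export
generate_tilt_wave <- function(protocol, fs) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  h <- protocol$hold_s; tr <- protocol$transition_s; A <- protocol$angle_deg
  cycle_s <- 2 * (h + tr)
  n <- round(protocol$total_s * fs)
  t <- (0:(n - 1)) / fs
  tc <- t %% cycle_s
  angle <- numeric(n)
  angle[tc < h] <- -A
  ramp_up <- tc >= h & tc < h + tr
  angle[ramp_up] <- -A + 2 * A * (tc[ramp_up] - h) / tr
  angle[tc >= h + tr & tc < 2 * h + tr] <- A
  ramp_dn <- tc >= 2 * h + tr
  angle[ramp_dn] <- A - 2 * A * (tc[ramp_dn] - 2 * h - tr) / tr
  angle
}

#' Ground-truth autoregulation model for the generator
#'
#' Parameterizes the linear pressure-to-flow transfer used to synthesize a
#' CBFV channel from a generated ABP channel. An intact model has reduced
#' gain and a phase lead in the autoregulatory bands (flow counter-regulates
#' slow pressure swings, with more phase lead and less gain in VLF than LF);
#' an impaired model is pressure-passive — flat gain at the mean flow/pressure
#' ratio with zero phase, so flow simply tracks pressure.
#'
#' @param band_gain Named vector of band gains in (cm/s)/mmHg,
#'   names matching the analysis bands (default `c(vlf = 0.35, lf = 0.55)`).
#' @param band_phase_deg Named vector of band phases in degrees, positive =
#'   flow leads pressure (default `c(vlf = 50, lf = 25)`).
#' @param impaired If `TRUE`, the model is pressure-passive and
#'   `band_gain`/`band_phase_deg` are ignored at synthesis time.
#' @param noise_cv Independent colored (1/f) noise added to the flow channel,
#'   as percent of mean MFV (default 3).
#' @return Object of class `autoreg_model`.
#' @export
autoreg_model <- function(band_gain = c(vlf = 0.35, lf = 0.55),
                          band_phase_deg = c(vlf = 50, lf = 25),
                          impaired = FALSE, noise_cv = 3) {
  if (any(band_gain <= 0)) stop("band gains must be positive")
  if (any(abs(band_phase_deg) >= 180)) stop("band phases must be within (-180, 180)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(band_gain = band_gain, band_phase_deg = band_phase_deg,
                 impaired = impaired, noise_cv = noise_cv),
            class = "autoreg_model")
}

#' Full parameterization of the synthetic ABP/CBFV generator
#'
#' The stated world the generator emulates: ICU recordings with mean arterial
#' pressure held near 90 mmHg, low spontaneous baseline variability
#' (CV of filtered MAP ~ 3.06%), and a bed-tilt intervention that raises it
#' to ~ 8.24% by injecting slow oscillations. Spontaneous variability is
#' built from fixed-frequency VLF/LF sinusoids (0.03 and 0.1 Hz), a
#' respiratory (0.25 Hz) and a cardiac (1 Hz) component, and 1/f noise; the
#' whole fluctuation is auto-scaled so the post-filter CV hits the target
#' exactly.
#'
#' @param mean_map Mean arterial pressure (mmHg, default 90).
#' @param mean_mfv Mean flow velocity (cm/s, default 40).
#' @param baseline_cv_target Post-filter CV target at baseline (percent,
#'   default 3.056).
#' @param intervention_cv_target Post-filter CV target during the tilt
#'   intervention (percent, default 8.238).
#' @param oscillations Data frame `freq` (Hz), `amp` (relative), `phase`
#'   (rad) of spontaneous slow sinusoids.
#' @param resp_amp,cardiac_amp Relative amplitudes of the respiratory
#'   (0.25 Hz) and cardiac (1 Hz) components.
#' @param pink_sd Relative SD of the 1/f noise component.
#' @param tilt A [tilt_protocol()].
#' @param tilt_gain_mmhg_per_deg Pressure response to bed angle
#'   (mmHg/degree, default 0.25) before CV rescaling.
#' @param tilt_lag_s First-order lag of the pressure response to tilt
#'   (seconds, default 5).
#' @param tilt_vlf_amp Relative amplitude of the additional VLF (0.03 Hz)
#'   oscillation amplified by the intervention.
#' @param model An [autoreg_model()].
#' @param fs Sampling rate (Hz, default 200).
#' @param duration_s Record duration (s, default `tilt$total_s` = 360).
#' @param seed Integer seed fixing the full realization.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(mean_map = 90, mean_mfv = 40,
                             baseline_cv_target = 3.056,
                             intervention_cv_target = 8.238,
                             oscillations = data.frame(
                               freq = c(0.03, 0.10),
                               amp = c(1.0, 0.6),
                               phase = c(0, 0)),
                             resp_amp = 1.5, cardiac_amp = 12, pink_sd = 0.8,
                             tilt = tilt_protocol(),
                             tilt_gain_mmhg_per_deg = 0.25, tilt_lag_s = 5,
                             tilt_vlf_amp = 0.4,
                             model = autoreg_model(),
                             fs = 200, duration_s = NULL, seed = 1) {
  if (is.null(duration_s)) duration_s <- tilt$total_s
  stopifnot(mean_map > 0, mean_mfv > 0, fs > 0, duration_s > 0,
            baseline_cv_target > 0,
            intervention_cv_target > baseline_cv_target,
            all(oscillations$amp >= 0), resp_amp >= 0, cardiac_amp >= 0,
            pink_sd >= 0, tilt_vlf_amp >= 0)
  structure(list(mean_map = mean_map, mean_mfv = mean_mfv,
                 baseline_cv_target = baseline_cv_target,
                 intervention_cv_target = intervention_cv_target,
                 oscillations = oscillations, resp_amp = resp_amp,
                 cardiac_amp = cardiac_amp, pink_sd = pink_sd, tilt = tilt,
                 tilt_gain_mmhg_per_deg = tilt_gain_mmhg_per_deg,
                 tilt_lag_s = tilt_lag_s, tilt_vlf_amp = tilt_vlf_amp,
                 model = model, fs = fs, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# population variance / covariance (divisor n), matching the CV convention
var_pop <- function(x) mean((x - mean(x))^2)
cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Generate a synthetic arterial blood pressure channel
#'
#' Builds the fluctuation mix described in [synthetic_config()], low-passes
#' it with the standard 0.5 Hz zero-phase filter, and rescales so the
#' post-filter CV equals the condition's target exactly (the filter is
#' linear, so one rescale suffices). For the intervention, the tilt-driven
#' pressure perturbation (first-order-lagged bed angle times
#' `tilt_gain_mmhg_per_deg`, plus the amplified VLF oscillation) is scaled on
#' top of the unchanged baseline fluctuation to reach the intervention CV
#' target, solving the resulting quadratic in the tilt scale factor.
#'
#' @param config A [synthetic_config()].
#' @param condition `"baseline"` or `"intervention"`.
#' @return Numeric ABP waveform (mmHg) of `duration_s * fs` samples,
#'   deterministic given `config$seed`.
#' @export
generate_abp <- function(config, condition = c("baseline", "intervention")) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (0:(n - 1)) / fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- numeric(n)
  osc <- config$oscillations
  for (i in seq_len(nrow(osc))) {
    d <- d + osc$amp[i] * sin(2 * pi * osc$freq[i] * t + osc$phase[i])
  }
  d <- d + config$resp_amp * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
  d <- d + config$cardiac_amp * sin(2 * pi * 1.0 * t + stats::runif(1, 0, 2 * pi))
  if (config$pink_sd > 0) d <- d + config$pink_sd * pink_noise(n)
  fd <- lowpass_zero_phase(d, fs)
  target_sd <- config$baseline_cv_target / 100 * config$mean_map
  vfd <- var_pop(fd)
  if (vfd == 0 && condition == "baseline") {
    # zero-amplitude configuration: nothing to calibrate, constant pressure
    return(rep(config$mean_map, n))
  }
  k <- if (vfd == 0) 0 else target_sd / sqrt(vfd)
  if (k * max(abs(d)) >= config$mean_map) {
    stop("unattainable CV target: required fluctuation amplitude exceeds the mean")
  }
  d_base <- k * d
  if (condition == "baseline") {
    return(config$mean_map + d_base)
  }
  angle <- generate_tilt_wave(config$tilt, fs)
  angle <- rep_len(angle, n)
  dt <- 1 / fs
  alpha <- dt / (config$tilt_lag_s + dt)
  lagged <- lfilter_steady(alpha, c(1, -(1 - alpha)), angle, angle[1])
  d_tilt <- config$tilt_gain_mmhg_per_deg * lagged +
    config$tilt_vlf_amp * sin(2 * pi * 0.03 * t + stats::runif(1, 0, 2 * pi))
  fb <- k * fd
  ft <- lowpass_zero_phase(d_tilt, fs)
  vb <- var_pop(fb); vt <- var_pop(ft); cbt <- cov_pop(fb, ft)
  t2 <- (config$intervention_cv_target / 100 * config$mean_map)^2
  if (t2 <= vb || vt <= 0) {
    stop("unattainable CV target: intervention target does not exceed baseline variability")
  }
  k2 <- (-cbt + sqrt(cbt^2 + vt * (t2 - vb))) / vt
  abp <- config$mean_map + d_base + k2 * d_tilt
  if (any(abp <= 0)) {
    stop("unattainable CV target: pressure would become non-positive")
  }
  abp
}

#' Synthesize a cerebral blood-flow velocity channel from a pressure channel
#'
#' Applies the [autoreg_model()] as a frequency-domain linear filter to the
#' ABP fluctuation: band gain/phase anchors (placed at the band centers, with
#' zero phase at DC, a pressure-passive response above the analysis bands,
#' and a real response at Nyquist) are linearly interpolated across
#' frequency, giving a smooth complex response applied by FFT. The mean is
#' set to `mean_mfv` and independent 1/f noise at `noise_cv` percent of the
#' mean is added. The exact band-averaged responses over the standard Welch
#' frequency grid are attached as attribute `"ground_truth"`.
#'
#' @param abp Numeric ABP waveform from [generate_abp()].
#' @param config A [synthetic_config()].
#' @param settings A [tfa_settings()] defining the bands and the frequency
#'   grid on which the ground truth is recorded.
#' @return Numeric CBFV waveform (cm/s) with attribute `ground_truth`, a data
#'   frame with one row per band (`band`, `gain`, `phase_deg`).
#' @export
generate_cbfv <- function(abp, config, settings = tfa_settings()) {
  stopifnot(inherits(config, "synthetic_config"))
  model <- config$model
  n <- length(abp)
  fs <- config$fs
  nyq <- fs / 2
  g_pass <- config$mean_mfv / config$mean_map
  bands <- settings$bands
  if (model$impaired) {
    gains <- rep(g_pass, nrow(bands))
    phases <- rep(0, nrow(bands))
  } else {
    gains <- unname(model$band_gain[bands$name])
    phases <- unname(model$band_phase_deg[bands$name])
    if (anyNA(gains) || anyNA(phases)) {
      stop("model band names must match settings band names")
    }
  }
  # plateau per band with short linear transitions at the edges: keeps the
  # response essentially constant across each analysis band (so band-averaged
  # estimates are comparable to the stored truth) while the phase still goes
  # to zero at DC (real response) and above the autoregulatory range
  eps <- 0.005
  f_above <- min(2 * max(bands$f_hi), nyq)
  anchor_f <- c(0, min(bands$f_lo) / 5,
                as.vector(rbind(bands$f_lo + eps, bands$f_hi - eps)),
                f_above, nyq)
  anchor_g <- c(gains[1], gains[1], rep(gains, each = 2), g_pass, g_pass)
  anchor_p <- c(0, phases[1], rep(phases, each = 2), 0, 0)
  gain_of <- function(f) stats::approx(anchor_f, anchor_g, xout = f, rule = 2)$y
  phase_of <- function(f) stats::approx(anchor_f, anchor_p, xout = f, rule = 2)$y
  k <- 0:(n - 1)
  fphys <- ifelse(k <= n / 2, k, k - n) * fs / n
  H <- gain_of(abs(fphys)) *
    exp(1i * sign(fphys) * phase_of(abs(fphys)) * pi / 180)
  d <- abp - mean(abp)
  y <- Re(stats::fft(stats::fft(d) * H, inverse = TRUE)) / n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1000003L)
  noise <- if (model$noise_cv > 0) {
    model$noise_cv / 100 * config$mean_mfv * pink_noise(n)
  } else 0
  cbfv <- config$mean_mfv + y + noise
  # exact band responses on the Welch frequency grid, for recovery checks
  W <- round(settings$window_s * settings$fs)
  grid <- (0:(W %/% 2L)) * settings$fs / W
  gt <- data.frame(band = bands$name, gain = NA_real_, phase_deg = NA_real_)
  for (b in seq_len(nrow(bands))) {
    sel <- grid >= bands$f_lo[b] & grid < bands$f_hi[b]
    gt$gain[b] <- mean(gain_of(grid[sel]))
    gt$phase_deg[b] <- mean(phase_of(grid[sel]))
  }
  attr(cbfv, "ground_truth") <- gt
  cbfv
}

#' Generate a paired baseline/intervention recording
#'
#' Convenience wrapper producing the two [signal_record()]s of one
#' measurement session: baseline and tilt intervention share the same seed
#' (hence the same spontaneous fluctuation) and the same autoregulation
#' model.
#'
#' @param config A [synthetic_config()].
#' @param meta Extra metadata merged into both records (e.g. subject id).
#' @return List with elements `baseline` and `intervention`, each a
#'   `signal_record` whose meta carries `condition` and the generator ground
#'   truth (`ground_truth`, a data frame).
#' @export
generate_record_pair <- function(config, meta = list()) {
  out <- list()
  for (cond in c("baseline", "intervention")) {
    abp <- generate_abp(config, cond)
    cbfv <- generate_cbfv(abp, config)
    m <- meta
    m$condition <- cond
    m$impaired <- config$model$impaired
    m$seed <- config$seed
    m$ground_truth <- attr(cbfv, "ground_truth")
    out[[cond]] <- signal_record(abp = abp, cbfv = as.numeric(cbfv),
                                 fs = config$fs, meta = m)
  }
  out
}

#' Generate a synthetic measurement cohort
#'
#' Emulates a multi-timepoint ICU cohort: per subject, an autoregulation
#' state (impaired with probability `mix`) fixed across timepoints, and per
#' subject-timepoint a baseline/intervention record pair. Per-measurement CV
#' targets are drawn from the cohort-level moments of the emulated
#' population (baseline 3.056 +/- 1.464 %, intervention 8.238 +/- 2.646 %),
#' truncated so every intervention target exceeds its paired baseline
#' target. Fully reproducible given `seed`.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param n_timepoints Timepoints per subject (default 4).
#' @param mix Fraction of subjects with impaired autoregulation (default 0.5).
#' @param seed Integer root seed.
#' @param config Template [synthetic_config()]; per-record seed and CV
#'   targets are overridden.
#' @param cv_moments List with `baseline = c(mean, sd)` and
#'   `intervention = c(mean, sd)` for the per-measurement CV target draws.
#' @return List of `n_subjects * n_timepoints` record pairs (as from
#'   [generate_record_pair()]), each with `subject` and `timepoint` metadata.
#' @export
generate_cohort <- function(n_subjects = 13, n_timepoints = 4, mix = 0.5,
                            seed = 1, config = synthetic_config(),
                            cv_moments = list(
                              baseline = c(3.056, 1.464),
                              intervention = c(8.238, 2.646))) {
  stopifnot(n_subjects >= 1, n_timepoints >= 1, mix >= 0, mix <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  impaired <- stats::runif(n_subjects) < mix
  rec_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_subjects * n_timepoints)
  pairs <- vector("list", n_subjects * n_timepoints)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    model <- config$model
    model$impaired <- impaired[s]
    for (tp in seq_len(n_timepoints)) {
      idx <- idx + 1L
      cv_b <- max(1.0, stats::rnorm(1, cv_moments$baseline[1],
                                    cv_moments$baseline[2]))
      cv_i <- max(1.3 * cv_b, stats::rnorm(1, cv_moments$intervention[1],
                                           cv_moments$intervention[2]))
      cfg <- config
      cfg$model <- model
      cfg$baseline_cv_target <- cv_b
      cfg$intervention_cv_target <- cv_i
      cfg$seed <- rec_seeds[idx]
      pairs[[idx]] <- generate_record_pair(
        cfg, meta = list(subject = s, timepoint = tp))
    }
  }
  pairs
}
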