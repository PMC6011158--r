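---
title: "Methods: dynamic cerebral autoregulation metrics and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic cerebral autoregulation metrics and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfa)
```

## The problem

Dynamic cerebral autoregulation (CA) metrics — the Mx correlation index and
transfer function analysis (TFA) — infer how well the cerebral vasculature
buffers slow arterial pressure swings from the *spontaneous* covariation of
arterial blood pressure (ABP) and transcranial Doppler blood-flow velocity
(CBFV). Both metrics are only as good as the input variability they feed on.
In deeply sedated ICU patients the spontaneous variability of mean arterial
pressure can be a few percent of the mean, and interventions that induce
pressure oscillations (cyclic bed tilting) change the metrics' read-outs
even when the underlying physiology is unchanged within a session. `catfa`
implements the full analysis chain plus a controlled synthetic generator, so
that this sensitivity can be quantified against known ground truth.

## The analysis model

**Preprocessing.** Raw ABP/CBFV waveforms (conventionally 200 Hz) are
low-passed with a third-order Butterworth filter at 0.5 Hz applied forward
and backward (zero phase, squared magnitude response), yielding MAP and MFV
signals. Analysis uses 300-s windows. For the spectral path the filtered
channels are resampled to 10 Hz by FFT band-limited interpolation; a linear
trend through the window endpoints is removed and re-added around the FFT
step so the periodicity assumption does not leak energy into the slow bands.
Zero-phase filtering uses odd-reflection edge padding of three filter orders
with steady-state initial conditions; residual edge transients decay within
a few seconds and the analysis windows of interest sit inside multi-minute
records, away from the edges.

**Time domain.** The coefficient of variation CV = 100·σ/μ (population σ,
divisor *n*; at n ≥ 3000 the distinction from the sample convention is
below 0.02 % but is fixed for reproducibility) quantifies variability of
the filtered source-rate signals. The Mx index is the Pearson correlation
between 10-s block averages of MAP and MFV over the window (30 blocks for
300 s); blocks are non-overlapping and anchored at the window start.
Mx > 0.3 is classified as impaired (pressure-passive) autoregulation. The
direction of that reading follows the Mx literature: high positive
pressure–flow correlation means flow passively tracks pressure.

**Frequency domain.** Auto- and cross-spectra are Welch estimates over
100-s Hanning-tapered windows at 50 % overlap (5 windows per 300-s
segment), with per-window mean removal and one-sided density normalization,
followed by a 3-point triangular moving average across frequency applied to
all three spectra (the complex cross-spectrum included). Squared coherence,
gain `|Sxy|/Sxx` ((cm/s)/mmHg, absolute units), and phase `arg(Sxy)`
(degrees, positive = flow leads pressure, with the cross-spectrum defined
as `conj(FFT(MAP))·FFT(MFV)`) are averaged over the very-low (0.02–0.07 Hz)
and low (0.07–0.2 Hz) frequency bands; bin membership is by center
frequency, half-open `[lo, hi)`, so every bin belongs to exactly one band.
Band phase averaging checks for wrap-around at ±180° and unwraps within the
band first. Band gain and phase are always computed but flagged unreliable
when band coherence does not exceed the critical coherence threshold.

## The critical coherence threshold

Estimated coherence between two *independent* signals is biased above zero;
with only five averaged windows the null 95th percentile is large. The
conventional cutoff 0.34 for this window configuration is reproduced here
by direct Monte-Carlo: pairs of independent Gaussian white-noise signals
(300 s at 10 Hz) are pushed through the exact spectral estimator, and the
95th percentile of the null coherence over the VLF+LF analysis bins is
returned.

Two calibration facts drove design decisions:

- Without spectral smoothing, the per-bin null 95th percentile is ≈ 0.54,
  matching the classical closed form `1 − α^{1/(K−1)}` for K = 5 windows.
  With the minimal (3-point) triangular smoother it drops to ≈ 0.34.
  The smoother width is not uniquely fixed by convention; 3 is the minimal
  nontrivial width and is the value consistent with the 0.34 cutoff, so it
  is the default (`tfa_settings(smooth_points = 3)`), exposed in settings.
- The 0.34 value is a *per-bin* null quantile. Pooling *band-averaged*
  coherence instead (averaging across 5–13 partially independent bins
  shrinks the upper tail) gives ≈ 0.23. `critical_coherence()` therefore
  defaults to per-bin pooling (`per_bin = TRUE`), which reproduces the
  printed threshold; the band-averaged variant is available as an option
  for sensitivity analyses. The reliability *gate* in `run_tfa()` follows
  reporting practice: the band-averaged coherence is compared against the
  0.34 cutoff.

## The synthetic world

The generator emulates the stated recording conditions, not waveform
morphology:

- mean MAP 90 mmHg (management target 80–100 mmHg), mean MFV 40 cm/s;
- spontaneous fluctuation = sinusoids at 0.03 Hz (VLF) and 0.10 Hz (LF),
  a respiratory (0.25 Hz) and cardiac (1 Hz) component, plus 1/f noise —
  controllable second-order statistics rather than a baroreflex model;
- the whole fluctuation is rescaled once (the filter is linear) so the
  post-filter CV of MAP hits the baseline target, default 3.056 %;
- the intervention adds a pressure response to the tilt protocol
  (3 cycles of 15-s transitions / 45-s holds at ±30°, 360 s total,
  fundamental 1/120 Hz): the trapezoidal angle trace, first-order-lagged
  with a 5-s time constant and scaled at 0.25 mmHg/deg, plus an amplified
  0.03 Hz oscillation; this added component is scaled (solving the
  quadratic that the variance of a sum satisfies) so the post-filter CV
  hits the intervention target, default 8.238 %. The intervention target
  always exceeding the baseline target makes the "intervention CV is higher
  in every pair" direction structural rather than statistical.
- the flow channel is the pressure fluctuation passed through a
  frequency-domain filter: per-band gain/phase plateaus with short linear
  transitions at the band edges, zero phase at DC (real response), and a
  pressure-passive response (gain = mean MFV / mean MAP, phase 0) above
  0.4 Hz; "impaired" sets the passive response everywhere. Independent 1/f
  noise at `noise_cv` percent of mean MFV (default 3 %) is added. The exact
  band responses on the Welch frequency grid are stored with the record as
  ground truth. The phase transition toward DC is placed below the tilt
  fundamental (at one fifth of the lowest band edge) so that leakage from
  the strong tilt line carries in-band phase; with transitions inside the
  analyzed bands the recovered VLF phase was biased by several degrees.
- cohorts (default 13 subjects × 4 timepoints) draw per-measurement CV
  targets from the cohort-level moments 3.056 ± 1.464 % and
  8.238 ± 2.646 %, truncated to keep targets positive and ordered, and fix
  each subject's autoregulation state (impaired with probability `mix`)
  across timepoints. All randomness descends from one root seed.

What a green test does **not** establish: the generator has no beat-level
waveform morphology, no CO₂ or intracranial pressure dynamics, no
measurement artifacts (the hydrostatic transducer offset of tilting is
deliberately not simulated), and its "physiology" is a fixed linear
time-invariant transfer — so parameter-recovery results validate the
estimator chain, not any claim about real patients. Note also that an
"intact" ground-truth model does not force Mx below 0.3: the tilt drive
concentrates power near 1/120 Hz where even an intact model's phase lead
is partial, so block-averaged correlation can stay high. Only the impaired
direction (pressure-passive ⇒ Mx > 0.3) is a generator guarantee.

## Cohort statistics

Paired baseline/intervention comparisons use a Kolmogorov–Smirnov normality
gate on the pairwise differences (sample mean/SD plugged in — the
Lilliefors caveat applies and is accepted as the field convention;
α = 0.05): paired t-test when normal, Wilcoxon signed-rank otherwise. With
fewer than five pairs the gate cannot run and the rank test is used. Each
arm is presented by its own normality flag (mean ± SD or median [Q1–Q3]),
mirroring mixed presentation in clinical tables. All-zero differences are
reported as "no difference" (p = 1) since neither statistic is defined.
No multiple-testing correction is applied. Flip tables count crossings of
a classification cutoff between conditions (Mx at 0.3, band coherence at
0.34).

## Numerical choices and degenerate inputs

- Butterworth design by bilinear transform with pre-warping; coefficients
  agree with standard DSP references to machine precision, and DC gain is
  renormalized to exactly 1 so constants pass unchanged.
- `stats::filter` (compiled) implements both filter passes; steady-state
  initialization means a constant signal is a fixed point of the filter.
- A zero-amplitude generator configuration returns a constant trace
  (nothing to calibrate); unattainable CV targets (fluctuation amplitude
  reaching the mean, or an intervention target not exceeding realized
  baseline variability) raise errors rather than clipping.
- Spectral bins with non-positive auto-spectra are flagged invalid and
  excluded from band averages; empty bands are errors, not NA.
- Welch window count follows `floor((L − W)/(W/2)) + 1`; a trailing
  remainder shorter than half a window is discarded.
- Mx on constant block series is an error ("Mx undefined"), not NA, since
  a constant channel means the recording cannot support the metric.

## Scaled-down defaults in the test suite

The acceptance test suite runs the Monte-Carlo calibration at 2000
surrogate pairs (the standalone acceptance script uses 5000) and generates
cohort replications at 50 Hz instead of 200 Hz: every generated component
sits below 1.1 Hz, so the post-filter statistics are rate-invariant, and
the stated 200 Hz is retained in the single-cohort and calibration-window
tests.

## Known limitations

- The resampler assumes the input is already band-limited (true after the
  0.5 Hz low-pass); it is not an anti-aliasing decimator for raw signals.
- The KS normality gate is conservative with estimated parameters; with
  small n it has little power, which matches clinical practice but means
  the t-test branch is chosen liberally.
- `critical_coherence` assumes Gaussian white-noise surrogates; colored
  nulls would shift the threshold slightly and are not implemented.
- The CLI reads JSON configurations only.
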