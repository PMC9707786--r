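---
title: "Methods: glottovibrogram analysis of excised-larynx trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glottovibrogram analysis of excised-larynx trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glottovib)
```

## The measurement problem

Excised-larynx experiments drive an isolated larynx with controlled
bronchial pressure while recording three synchronized modalities:
high-speed video of the glottis (10,000–250,000 fps), calibrated sound
pressure (Pa) and bronchial pressure (kPa), both sampled at 250 kHz. In
bats, two laryngeal oscillators are of interest: the ventricular ("false")
folds, which vibrate at low fundamental frequencies (1–5 kHz) and are
optically opaque, and the micrometer-thin vocal membranes, which vibrate
at 10–20 kHz and are translucent. Three questions drive the analysis:

1. **What does the tissue do?** Extract the glottal opening width as a
   function of time and anterior–posterior (AP) position — the
   *glottovibrogram* (GVG) — and estimate the fundamental frequency of the
   opening waveform.
2. **Does the vibration produce the sound?** Regress the sound fundamental
   on the vibration fundamental over time-aligned analysis frames; slope 1
   with high r² establishes the source.
3. **When does phonation start?** Measure the phonation threshold pressure
   (PTP) and the rate of pressure change at onset (S_ptp), defined as the
   filtered bronchial pressure and its derivative at the time the sound
   amplitude crosses 0.2 mPa.

No public recordings accompany this problem, so the package ships a
synthetic-trial generator with exact ground truth; every pipeline stage is
validated against it.

## Segmentation: two paths for two tissues

**Threshold path (opaque structures).** The glottis is all pixels strictly
below a manually chosen gray threshold (recorded in the trial metadata; an
Otsu-based `suggest_threshold()` exists for operator guidance but is never
applied silently). The binary image is dilated with a 2-pixel line
horizontally then vertically, holes are filled, and the largest connected
component is kept (exact ties go to the darker component). The "2-pixel
line" is interpreted as a two-element structuring element applied in the
order the phrase suggests — horizontal then vertical; with the element
origin on its first pixel this enlarges the region by exactly one pixel in
each direction. That margin is *measured* on a calibration fixture by
`dilation_margin()` (it is 1 px) and subtracted explicitly in
`gvg_from_threshold()`, never silently inside the segmentation itself.
Width per AP row is the count of mask pixels in the row times the pixel
scale; the alternative reading (horizontal extent right−left) is what the
edge-tracking path computes, and the two agree within 1.5 px on opaque
fixtures — a cross-path oracle the test suite enforces.

**Edge-tracking path (translucent membranes).** Thresholding fails on
vocal membranes: the membrane lies over tissue of nearly the same gray, so
a fixed threshold sees only the dark core of the aperture and
systematically under-reports its width. The original analysis solved this
with a learned pose estimator detecting where the membrane edges cross 8–10
superimposed horizontal lines; this package substitutes a deterministic
scan-line tracker honoring the same output contract (per line and frame:
left/right edge x, fixed to the line's row, with a confidence score).
On each line the tracker forms a lightly smoothed horizontal gray
gradient and searches a tracking gate (±6 px) around the previous frame's
positions. Within the gate it takes the **outermost** opposite-signed
local extremum exceeding a contrast floor — not the strongest: the inner
membrane–glottis transition is *stronger* than the true outer membrane
edge, and a strongest-extremum rule demonstrably captures the track the
moment the aperture widens fast enough to bring the inner edge into the
gate. Positions are refined by a parabolic fit to the gradient (an
integer-positioned edge lands on the half-integer pixel boundary, exactly
where the rendering convention puts it). Lines that lose contrast keep
their predicted position at confidence 0; more than 3 consecutive lost
frames flag a gap. The gate default of 6 px covers the fastest per-frame
edge motion the generator's study conditions produce (~4.5 px at
125,000 fps with 12 px amplitude); the outermost rule, not the gate width,
is what rejects the inner edge.

External detections (e.g. from a learned model) can be ingested through
`edge_tracks_from_csv()`, which produces the same structure.

## Glottovibrogram and the opening waveform

`build_gvg()` assembles either path into a time × AP matrix of widths
(mm). Edge-track dropouts of at most 3 frames are linearly interpolated
and counted; longer gaps abort with the offending frame ranges — short
gaps interpolated silently would be harmless, but long interpolations can
halve apparent pitch and must fail loudly. The analysis position is the AP
index of maximal time-mean opening (ties → anterior-most, a deterministic
rule), and the opening waveform is the GVG slice there, demeaned before
pitch analysis (the estimator is offset-invariant on periodic signals;
demeaning only removes the DC term from the power gate).

## Fundamental frequency: yin below fs/4, ridge above

`yin_f0()` implements the difference-function pitch estimator: per frame,
`d(tau)` is computed exactly (FFT cross-correlation plus cumulative energy
terms; lags 1..window/2 with integration length window/2, so the
precondition is window ≥ 2·fs/f0_min), normalized to the cumulative-mean
difference (CMND), and the lag is the smallest-lag local CMND minimum
whose *interpolated* dip value falls below the aperiodicity threshold
(default 0.1). Two numerical choices matter and are deliberate:

* the dip-vs-threshold test uses the parabolically interpolated minimum,
  because when the true period falls between integer lags the sampled CMND
  straddles the dip and can sit above the threshold while a period
  *multiple* lands near an integer lag and dips below — the classic
  octave-down failure;
* the final lag is refined by a parabola on the raw difference function,
  not the CMND, whose cumulative normalization is asymmetric around minima
  and biases the refinement by several Hz per kHz at ~10 samples per
  period.

A frame is valid when its power reaches the power floor, its aperiodicity
is at or below the threshold, and the estimate does not exceed a quarter
of the sampling rate — the estimator is unreliable above fs/4, which is
why `select_engine()` switches to spectrogram ridge tracking for expected
ranges above that boundary (the boundary itself selects yin). The floors
and thresholds are calibrated on the synthetic noise conditions and are
config-exposed; they are not claims about any particular laboratory's
settings. For opening waveforms the hop is 10 video frames, the
frame-synchronous convention used throughout.

`ridge_f0()` computes a spectrogram (nfft 2048, 50% overlap, Hamming) and
extracts the path maximizing summed log-magnitude minus a per-column jump
penalty (0.5 log-units per bin, jumps capped at 64 bins), solved exactly
by dynamic programming and refined to sub-bin precision by a parabolic fit
across adjacent bins. The penalty was chosen once so that a 20–70 kHz
linear sweep is recovered within 2% RMS and two equal-power tones 1 kHz
apart do not make the ridge oscillate; spectrogram columns are
timestamped at window centers (the underlying routine stamps window
starts, which would bias a sweep by ~0.3%).

## Synchronization, identity regression, call statistics

Physiological signals are brought to the video frame rate by
`resample_to_framerate()`, an exact band-limited spectral resampler: odd
reflection extension at both ends, FFT, ideal anti-aliasing truncation at
the output Nyquist, inverse FFT on a grid whose spacing is exactly 1/fps
and whose samples land exactly on `t0 + k/fps`. DC gain is exactly 1 — a
constant resamples to the same constant — and a mid-band tone is preserved
to better than 0.5%. This replaces the polyphase-FIR formulation with an
equivalent band-limited interpolation because the available FIR-based
resampler exhibits percent-level gain errors.

`identity_regression()` pairs analysis frames valid in both tracks by
nearest time (within half a hop) and fits ordinary least squares *with*
intercept — the reference figure draws a dotted identity line, but the fit
itself is not forced through the origin, and reporting the intercept is
itself a diagnostic. Constant-f0 trials make this regression degenerate,
so the built-in trial recipes give f0 a modest sweep after onset,
emulating the f0 rise that accompanies still-increasing drive pressure.
`fo_range_summary()` uses linear interpolation between closest order
statistics (type-7 quantiles) and reports full-range whiskers with no
outlier trimming. `segment_calls()` extracts intervals where the running
RMS exceeds a floor, merging across gaps shorter than `min_gap_s`; the
floor and gap are configuration values standing in for what was a manual
selection step.

## Pressure filtering and phonation onset

The bronchial pressure is low-pass filtered at 500 Hz with a 6th-order
Butterworth applied forward and backward (zero phase): a causal single
pass would delay the trace and bias the pressure read off at onset. Two
implementation details:

* the filter runs as a cascade of three zero-phase biquads
  (second-order sections). At 250 kHz the normalized cutoff is 0.004 of
  Nyquist and the direct-form order-6 recursion is numerically unstable in
  double precision — on a 1 kPa/s ramp its "derivative" oscillates between
  0.04 and 1.9 kPa/s, while the SOS cascade returns exactly 1;
* signal ends are extended by odd reflection before filtering, so
  constants pass through unchanged to ~1e-11 and a step's half-amplitude
  crossing stays within the filter's settling half-width of its true
  location (measured in the tests).

Pressure speed is the first difference times the acquisition rate,
timestamped at sample midpoints. Sound onset is the first time the running
RMS (1 ms centered window) crosses 0.2 mPa and stays above for 2 ms — the
hold rejects isolated clicks. The criterion is interpreted as an RMS
amplitude (the stated mPa units imply an amplitude-scale quantity); window
and hold are config-exposed since no published values exist. With the
1 ms window the RMS at the detected onset of a linearly growing tone
matches the criterion to within the window bias (envelope slope × window),
which the acceptance tests compute rather than assume. PTP is the filtered
pressure interpolated at onset; S_ptp the speed at the nearest midpoint.

## The synthetic-trial generator

The generator is first-class, tested code that fixes the study conditions:

* **Pressure protocols** — a slow linear ramp 0→6 kPa at exactly 1 kPa/s
  (optionally starting at 3 kPa) and trains of 4 trapezoidal 300 ms pulses
  between 0 and 4 kPa with a 30 ms rise (133 kPa/s, recorded as ground
  truth).
* **Onset rule** — oscillation can only *start* where pressure ≥ ptp_true
  and, when a rate gate is set, pressure speed ≥ the gate; it persists
  while pressure stays above threshold. A 50 kPa/s gate under a 1 kPa/s
  ramp is never satisfied: the trial stays silent, which is a valid
  result, not an error. This reproduces, at synthetic scale, the
  two-condition onset contrast between slow ramps and fast pulses.
* **Kinematics** — prescribed motion, not self-oscillation: each of 9 AP
  lines opens as `slit + A_i (1 − cos φ(t)) · env(t)` with φ integrating
  the f0 profile from onset, amplitudes peaking at the middle line
  (raised-cosine AP profile) and a small AP phase lag (0.3π total) giving
  the GVG a mucosal-wave-like tilt. The phase relation along the AP axis
  is a generator choice, not a claim about any animal. A 3-cycle onset
  envelope starts oscillation smoothly from closed. Construction refuses
  fps < 4 × max f0.
* **Rendering** — 8-bit grayscale, default 48×96 px at 0.02 mm/px in the
  recipes, gray levels 160 (fold) / 40 (glottis), additive Gaussian noise
  (sd 2) clipped to range. Opaque mode renders the whole aperture dark, so
  thresholding is exact up to pixel quantization. Translucent mode renders
  a 6 px membrane band inside each true edge at gray 158 — within the
  noise of the fold gray, so thresholding cannot see it and under-reports
  width by construction — plus a 2 px rim at gray 100 marking the membrane
  edge itself, emulating the edge-on darkening of a thin tissue margin.
  The rim is what a gradient tracker can lock onto; without some physical
  edge cue no deterministic detector (nor a learned one) could localize an
  edge that is optically identical to its background.
* **Sound** — a harmonic series (3 harmonics, amplitudes 1/h, truncated
  below Nyquist) integrating the *same* f0 profile from the *same* onset
  as the kinematics, so vibration and sound share their fundamental by
  construction; 20 mPa peak with a 50 ms linear attack and 0.02 mPa sensor
  noise. The ~0.13 ms microphone propagation delay of a real 44 mm setup
  is ignored by default and available as `delay_s` for robustness tests.
* **Determinism** — one `(recipe, seed)` pair produces byte-identical
  trial directories (8-bit TIFF, CSV, JSON), which the tests verify
  literally.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: tissue self-oscillation and its bifurcations,
collision/contact dynamics, out-of-plane motion, illumination gradients
and specularities, camera vignetting, and realistic membrane texture.
The generator validates the *measurement chain*, not laryngeal physics.

## Problem sizes and defaults

The built-in recipes use 0.1 s of video at 20,000 fps (ventricular,
2,000 frames) and 0.05 s at 125,000 fps (membrane, 6,250 frames) with full
6 s (slow ramp) or 2.1 s (pulse train) pressure/sound records at 250 kHz —
large enough that every estimator operates in its intended regime (about
200 and 600 f0 analysis frames per trial) while a complete end-to-end
trial builds and analyzes in seconds. PTP recovery is exercised over 20
seeded ramps with thresholds drawn uniformly from 2–6 kPa.

## Known limitations

* The scan-line tracker needs a detectable gradient at the membrane edge;
  with heavy sensor noise (sd ≳ 8 gray levels against a 60-level rim) its
  per-frame error grows beyond a pixel. A learned detector remains the
  right tool for hard real footage; the adapter interface accepts its
  output.
* `resample_to_framerate()` requires the rate ratio to be rational with a
  moderate denominator — always true for integer acquisition rates.
* The ridge tracker follows the strongest spectral path; it does not
  verify that the path is the *fundamental*. For sounds whose second
  harmonic outweighs the fundamental it will track the harmonic; restrict
  `fmin`/`fmax` to the expected octave in such cases (as `run_pipeline()`
  does from the trial metadata).
* Pixel quantization bounds both segmentation paths at ±0.5 px per edge;
  widths inherit up to 1 px of quantization error independent of noise.
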