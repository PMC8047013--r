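---
title: "Quantifying CSD experiments: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CSD experiments: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdquant)
```

## The measurement problem

A cortical spreading depolarization (CSD) evoked by topical KCl produces
three families of signals that this package quantifies jointly:

1. a **widefield calcium wave** — a near-saturating ΔF/F transient
   (~200%) that crosses the cortex at a few mm/min, followed by tens of
   minutes of suppressed slow-wave (0.5–2 Hz UP/DOWN state) activity;
2. **cellular-scale astrocyte activity** — aberrant somatic and gliopil
   Ca²⁺ events in the minutes after wave passage, quantified by a
   per-pixel-per-frame exceedance probability and by pairwise soma
   correlations;
3. **electrode signals** — the extracellular potassium transient read by
   a Nernstian ion-selective barrel against a reference LFP barrel, and
   whisker-evoked LFP deflections whose amplitude tracks functional
   recovery.

No raw recordings ship with the package. Instead, seeded generators
render each signal family with known ground truth, and the test suite
demonstrates that every estimator recovers the planted parameters. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## Widefield pipeline

**ΔF/F.** The baseline F is the mean intensity over the 40-s window
ending 20 s before KCl application (`[kcl − 60, kcl − 20)`), computed per
ROI trace; all windows in the package are half-open. F is computed once,
pre-KCl, and not re-baselined after the post-CSD baseline decrement; the
decrement therefore appears as a genuine negative ΔF/F offset, which is
what an experimenter would see.

**Detection.** An event begins at the first upward crossing of
`baseline mean + 5·SD` and ends when the signal falls below half of that
event's peak. The +5 SD rule is applied to the *unfiltered* ΔF/F trace
with statistics from the same 40-s baseline window used for F (the
alternative — post-filter detection — is not used because filtering is
only defined for the amplitude pipeline). Threshold crossings inside an
ongoing event are not new events, and a fresh event additionally
requires a crossing at least 10 s after the previous event's end; 10 s
is more than an order of magnitude below the shortest reported
inter-CSD interval (~280 s), so the guard cannot merge genuine events.
Onsets are linearly interpolated between samples.

**Peaks and half-maximum times.** The peak is refined by a cubic
interpolating spline (`splinefun`, FMM end conditions, exact for
polynomials up to cubic) on a ±2 s window around the discrete maximum —
long enough at 10 Hz to span the peak, short enough to exclude flanking
dynamics; a window truncated by the trace edge falls back to the
discrete maximum with a warning. Arrival and passage are the half-peak
crossings by linear interpolation; their difference is the wave
duration. Ordering `onset ≤ arrival ≤ peak ≤ passage` is asserted
across all suites.

**Speed.** Waves detected at a near ROI (centered 0.5 mm from the KCl
origin) and a far ROI 2 mm anterior are matched by rank order; speed is
separation over the half-max arrival difference, in mm/min. ROI sizes
are 5×5 binned pixels — the reported protocols state the separation but
not the ROI size. Arrival times, being half-max based, are invariant to
uniform intensity scaling, and the estimator recovers speeds across the
physiological 2–6 mm/min range with median error below 3%. One caveat
found during validation: for *onset-interval* measurements a compact
(single-pixel) probe ROI is preferable, because across a staggered
multi-pixel ROI the earliest rising pixel dominates the threshold
crossing with one fifth of the full ramp slope, amplifying slow-wave
phase error about fivefold.

**Amplitude and recovery.** Slow-wave amplitude is the RMS of the
band-passed (0.1–3 Hz) trace over consecutive 5-min windows. The filter
is a second-order Butterworth applied forward and backward (zero phase,
so event timing elsewhere is unaffected); the trace is padded by odd
reflection over three periods of the low band edge before filtering,
because unpadded forward–backward recursion leaves start-up transients
of several percent in the first window. At 1 Hz the squared passband
gain is within 0.1% of unity, so a sinusoid of amplitude A yields
A/√2 within the 2% band used in the tests. Recovery curves divide each
windowed amplitude by the mean over the 10 min preceding KCl.

## Two-photon pipeline

Per-pixel ΔF/F uses each pixel's pre-CSD temporal mean as F; pixels with
non-positive baseline are masked and reported. The high-Ca²⁺ rule marks
pixel-frames above the pixel's reference-window mean + 4 SD. The
statistics are **per pixel** — the natural companion of pixel-wise
ΔF/F — and the reference window is the pre-CSD period by default (the
alternative, whole-recording statistics, would absorb the post-CSD
events into the threshold). `P(High Ca²⁺)` divides the high pixel-frame
count by pixels × frames, per soma or pooled over the entire non-soma
ROI; both per-soma values and their mean are available, since group
statistics may aggregate either way.

Gliopil ROIs are selected as non-soma pixels showing at least one
supra-threshold frame during reference periods (pre-CSD or inter-wave),
with the same 4 SD rule used for scoring — the selection rule is not
defined separately anywhere, so reusing the scoring rule is the
parsimonious choice. An empty selection falls back to the whole
non-soma region, flagged.

Soma traces are pixel means per frame; correlation is Pearson (the
convention for continuous ΔF/F signals), with the per-recording mean
taken over the upper triangle of the correlation matrix.

## Electrode pipeline

Calibration regresses measured voltage on **log₁₀ concentration** over
the six standards (3.5, 4.5, 10, 20, 50, 100 mM). A single linear slope
in raw mM cannot describe a valinomycin electrode across a 30-fold
concentration span — the ionophore response is Nernstian (~58 mV per
decade near body temperature) — so the log regression is the default; a
raw-linear mode exists for comparison. Conversion to concentration
inverts the fitted curve after resampling to 10 Hz. Resampling averages
each block of input samples (a moving-average anti-alias low-pass,
output timestamped at block centers): on clearance-scale signals this
is accurate to below 1e-5 relative, whereas recursive low-pass filters
at the very low normalized cutoffs involved (0.008 at 1 kHz input)
leave percent-scale edge transients. Samples converting outside the
calibrated range are flagged per sample, never clamped — clamping would
silently bias the post-CSD peak.

Evoked LFP amplitude is the baseline-to-extremum magnitude within
100 ms of the stimulus, with the 50-ms pre-stimulus mean as baseline;
the deflection polarity is auto-detected from the mean pre-KCl response
and then held fixed, so post-CSD noise cannot flip the measured sign.
Amplitudes are binned, normalized to the pre-KCl mean, and paired with
10-min [K⁺]ₑ medians by nearest-bin matching for the rank-correlation
summary.

## Synthetic generators

The generators emulate the *structure* of the study signals, not their
biophysics: no ion diffusion, optics, or hemodynamics.

- **Widefield** (`simulate_widefield`): a radial (or planar, for clean
  speed tests) wavefront expanding at constant speed from the KCl
  origin; each pixel receives a trapezoid pulse rising linearly over
  2 s to the peak ΔF/F (default 2.0), holding, and falling over 2 s so
  the supra-half-max duration equals the requested wave duration
  (default 50 s). The pulse shape is the open choice — only the
  duration above half-maximum is constrained by reported values — and a
  trapezoid makes the half-max crossings analytic; other shapes would
  only shift passage-time tests. The slow-wave is a single sinusoid
  (default 1 Hz, RMS 3% ΔF/F) — a simplification of UP/DOWN dynamics
  sufficient for amplitude and recovery estimators — multiplicatively
  gated off at each wave's local passage with exponential recovery
  (default τ = 900 s; the reported recovery spans tens of minutes
  without a stated functional form, and an exponential is the simplest
  monotone form with one recoverable parameter). The baseline drops by
  a step (default 10%) at passage, relaxing on the same time scale.
  Defaults: 12.8 mm field on a 64×64 grid at 10 Hz, KCl window
  [0, 600) s, two waves 281.1 s apart at 4.4 mm/min.
- **Two-photon** (`simulate_twophoton`): soma i receives
  `amp·(√ρ·s + √(1−ρ)·nᵢ)` with s, nᵢ independent filtered Poisson
  processes (exponential kernel) standardized to unit variance over the
  post-CSD window, so the expected pairwise Pearson correlation equals
  ρ *by construction*; soma events exist only post-CSD, the pre window
  is noise-only. Gliopil patches carry independent trains over the
  whole recording (the event-based gliopil ROI selection needs events
  in pre/inter-wave reference periods) with a fixed per-event amplitude
  (default 2.0 ΔF/F) large against pixel noise. The pixel noise default
  (0.35 ΔF/F SD at 30 Hz) was set so that the default scenario's
  post-CSD soma P(High Ca²⁺) lands in the reported ~0.09 regime.
- **Ephys** (`simulate_ephys`): [K⁺]ₑ ramps from 3.5 to 30 mM across
  the KCl window and decays exponentially (default τ = 900 s, leaving
  [K⁺]ₑ still elevated ~1 h later, as observed); the ion barrel reads
  offset + 58·log₁₀[K⁺] plus the common-mode LFP, the reference barrel
  the common mode alone. Spontaneous LFP amplitude is gated by
  baseline/[K⁺] (spontaneous activity is low while potassium is high);
  evoked deflections every 30 s are attenuated by 50% after KCl and
  recover exponentially. The native rate defaults to 1 kHz — full
  acquisition rates add nothing to desk-scale validation — while the
  conversion path still exercises decimation to 10 Hz.

All generators take explicit integer seeds, produce bit-identical output
per seed, and restore the caller's RNG stream.

What passing these tests does *not* show: robustness to motion,
vascular artifacts, photobleaching, non-sinusoidal UP/DOWN statistics,
electrode drift beyond the common mode, or non-exponential clearance.
Those belong to preprocessing and are out of scope here.

## Numerical choices and degenerate inputs

- Missing acquisition metadata (frame rate, pixel pitch, trace rate or
  unit) is always an error, never defaulted — a silently guessed frame
  rate corrupts every downstream timing estimate.
- Zero-variance baselines (threshold undefined), non-positive baseline
  F, empty ROIs, two-point calibrations, and misaligned electrode pairs
  are errors; zero-variance pixels and traces are excluded *and
  counted*; stimuli too close to trace edges are skipped with warnings.
- Binning is block **mean**, not sum: ΔF/F is invariant to the choice,
  and means keep intensities comparable across binning factors.
- Wave matching across ROIs is by rank order; non-positive transit
  times leave the wave unmatched and flagged rather than dropped.
- Spearman p values at n < 10 come from full permutation enumeration;
  larger n uses the asymptotic t approximation.
- Events still above half-maximum at the trace end get `NA` passage and
  a warning rather than a fabricated crossing.

## Problem sizes used in validation

The test suite validates at desk scale, chosen once: 64×64 widefield
grids at 10 Hz (minutes of recording), 48×48 two-photon grids at 30 Hz
with 20 somata and 30 seeds for the correlation recovery, 1 kHz
electrode traces over ~80 min equivalents. Detection specificity is
checked on one hundred 10-min noise traces; the +5 SD threshold admits
a per-study expected false-positive count well below one, and the
suite's fixed-seed run records zero.
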