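---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphenostim)
```

This vignette documents the measurement models the package implements, the
parameters that matter (with units and defaults), what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
underlying experimental description left the design open.

## Conventions

Pixel coordinates are 0-based and row-major — `(row = y, col = x)` with
`(0, 0)` the top-left pixel — in every module. Time is 0 at the first
sample/frame of a recording; `t0_s` aligns recordings to a stimulation
schedule whose own clock starts at the first ON set. Doppler flow is in
arbitrary units (only percent changes are meaningful), ECoG in µV, ROI
intensities in arbitrary intensity units (iu).

## Stimulation schedule

`stim_protocol()` defaults to the acute protocol: 12 trains, each two 60-s
sets of 10-Hz pulses separated by a 12-s gap, followed by 13.6 min OFF.
`expand_schedule()` derives the ON intervals purely from these per-train
parameters, which yields a 189.6-min span; the protocol's nominal "total
treatment time" (180 min as conventionally stated for this protocol) is
arithmetically inconsistent with that expansion, so it is carried only as
optional metadata (`total_treatment_min`) and never recomputed or
reconciled.

## Vessel morphometry

**Segmentation** (`segment_vessels()`) is a fixed four-step recipe: median
denoise (radius 2 px) → local-mean adaptive threshold → morphological hole
filling → removal of components under `min_object_px` (50 px). The frame is
first normalized to its own dynamic range, so the mask — and everything
downstream — is invariant to affine intensity rescaling. The adaptive
threshold is the mean over a `threshold_window` square (default 51 px) plus
`threshold_offset` (default 0.02 of the dynamic range), with a polarity flag
for bright- vs dark-vessel imaging. Local-mean thresholding is the simplest
operator meeting the requirement of an adaptive threshold; fancier methods
(Sauvola, hysteresis) were deliberately avoided since the recovery tests do
not need them. **The window must exceed the widest vessel diameter in
pixels** — inside a vessel wider than the window the local mean saturates at
the vessel's own level and the mask hollows out; tests with 50-px vessels
use a 101-px window for this reason.

**Diameter** (`measure_diameter()`) is the perpendicular-chord definition —
the count of contiguous foreground pixels across the vessel — rather than
twice the distance transform, matching how diameters are conventionally
read off binary masks of pial vessels. The query point snaps to the nearest
skeleton pixel (Zhang–Suen thinning; ties broken by distance, then lowest
row, then lowest column, making the result deterministic), the local
tangent is the principal axis of skeleton pixels within a ±3-px window, and
the chord is traced perpendicular to it on the bilinearly interpolated mask
at 0.1-px steps, with the half-coverage (0.5) crossing located by linear
interpolation. The sub-pixel crossing is what keeps the estimate rotation-
invariant to within ±1 px at 0°/45°/90°.

**Time courses** (`diameter_timeseries()`) normalize each point to its own
baseline mean before averaging across points (normalize-then-average);
averaging raw diameters first would let wide points dominate the percent
change. The baseline window should cover the minute before the first
stimulation ON interval. Frames where a point cannot be measured are kept
as missing — never interpolated — and points missing in more than 20% of
frames are flagged in the trace's provenance.

## Angiography kinetics

`roi_intensity_curve()` reduces each frame to the ROI's mean intensity.
Baseline is the mean of the first 10 frames (pre-arrival window at 30
frames/s); the curve is smoothed with a centered 5-frame moving average for
peak detection, taking the earliest frame on ties so transit intervals are
conservative and deterministic. The peak is *located* on the smoothed curve
but *refined* to the raw-curve maximum within the smoothing half-window:
the smoothed maximum of an asymmetric bolus (fast rise, slow exponential
washout) is biased toward the washout side by up to half the window, which
would alone exceed a one-frame accuracy budget. The arrival criterion for
`slope_to_max()` is the first crossing of baseline + 10% of the excursion,
interpolated between frames on the smoothed curve (the raw/smoothed choice
is recorded; smoothed was chosen because the 10% crossing is the noise-
sensitive quantity, while the peak value is not once refined). Both the
peak-to-peak interval and the slope are invariant to intensity offsets and
time shifts by construction, and these invariances are tested.

## Doppler rCBF

`normalize_rcbf()` is the pure percent-change transform
`100·(x − x̄_b)/x̄_b`; no detrending or filtering is applied by default
because the measurement protocol prescribes none, and an optional smoothing
would silently bias epoch means. The conventional baseline is ≥ 15 min of
pre-stimulation recording; shorter windows (used throughout the synthetic
tests, which run on minutes-long traces) must be opted into with
`allow_short_baseline = TRUE`. A non-positive baseline mean is an error:
arbitrary-unit Doppler flow is positive, so a non-positive mean indicates a
broken trace rather than biology.

## ECoG

**Filtering.** `bandpass_zero_phase()` applies a 4th-order Butterworth
band-pass forward and backward (zero net phase, verified on pure tones by
zero cross-correlation lag), with odd-reflection padding of three filter
lengths at each end to control edge transients.

**Band power.** Spectra are averaged magnitude-squared Fourier transforms
over non-overlapping 10-s Hann-tapered windows; bin powers are scaled so
their sum estimates the signal variance (Parseval, held to 5% in tests),
and bands collect bins with `lo ≤ f < hi`. The five analysis bands are
2–4, 5–10, 11–45, 46–70 and 71–90 Hz. `per_session` normalization divides
by the total power over the five analyzed bands — not over the whole 2–90 Hz
range — so that the reported powers sum to exactly 1; the bands leave small
gaps (4–5, 10–11, 45–46, 70–71 Hz) and dividing by the full-range total
would make the unit-sum property quietly false. `to_day1` divides each band
by the same band's raw power in the animal's day-1 reference, giving fold
changes.

**Seizure-like events.** The event definition conjoins two criteria judged
against the day-1 baseline: high amplitude (> `k_sd` = 3 × the SD of the
2–90 Hz day-1 signal) and concurrent fast activity (71–90 Hz band envelope
> 3 × the day-1 SD of that band's envelope). Two numerical choices matter:

1. *Amplitude is an envelope, not a sample value.* An 80-Hz oscillation
   crosses any fixed level only for sub-millisecond runs, so thresholding
   `|x|` directly can never produce the seconds-long runs the duration
   filter requires; the Hilbert envelope is the oscillation's amplitude and
   is the quantity the "> 3 SD" criterion meaningfully applies to.
2. *Envelopes are smoothed to the episode time scale* (0.25-s moving
   average) before thresholding. Seizure-like events are seconds long;
   smoothing keeps a sustained event from fragmenting on within-event
   envelope dips, and makes chance background excursions (tens of ms) far
   too brief to survive the 1-s minimum duration. With this choice the
   detector shows no false events on event-free pink-noise background
   across seeded hour-scale runs, while recovering 5×SD bursts with onset
   errors well under 0.5 s.

Candidate runs shorter than `min_dur_s` (1 s) are dropped first, then runs
separated by less than `merge_gap_s` (0.5 s) are merged; both constants are
package choices consistent with seconds-long events. The AND combination of
the two criteria is the default; an OR mode exists for sensitivity
analysis. Burden is `3600 · Σ duration / recording length` (s/h), and the
whole detector is amplitude-scale equivariant: scaling signal and baseline
together leaves the event list unchanged (tested).

## Histology

`quantify_evans_blue()` averages the blue channel over the whole treated-
hemisphere mask (not only supra-threshold pixels — the alternative reading
was rejected as it confounds the two reported quantities) and reports the
percentage of treated-hemisphere pixels above a fixed threshold. The
threshold has **no default**: its value is an operator choice that the
original protocol does not pin down, so the caller must state it and it is
recorded in the result. Hemisphere and cortex masks are inputs, drawn or
generated — no auto-segmentation rule exists for them.

`cortical_volume_change()` compares ipsilateral and contralateral cortex
pixel counts per section and aggregates by pooled pixel sums. Pooling areas
is an area-weighted volume proxy justified by equal 40-µm section
thickness; the aggregate always lies between the per-section extremes
(tested), and a recomputation check ties the aggregate to the per-section
table.

## Group statistics

`mann_whitney_u()` computes U from midranks; p-values use the exact
permutation distribution for `min(n, m) ≤ 8` without ties (two-sided by
doubling the smaller tail, capped at 1 — the standard deterministic
convention) and a tie- and continuity-corrected normal approximation
otherwise. The exact path is verified in the tests against a full
enumeration of every rank split for all `n, m ≤ 6`. No multiple-testing
correction is applied, matching the original single-endpoint analyses;
users comparing many endpoints should correct downstream.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic given (spec, seed), restores the caller's
RNG state, and returns the programmed truth alongside the rendered data, so
downstream scoring never re-derives truth from the rendering.

- **Vessels** are top-hat (rectangular cross-section) ridges with a 1-px
  anti-aliased border and additive Gaussian noise. The top-hat makes "true
  diameter" unambiguous; a Gaussian-profile vessel has no convention-free
  width and is therefore not used for recovery scoring. One rasterization
  subtlety is worth stating: a top-hat of non-integer pixel width cannot be
  represented exactly on the grid (a 22.4-px programmed width thresholds to
  22 px), so recovery fixtures program widths that are even and centered on
  a pixel boundary (e.g. 50 → 56 px for a +12% dilation); this isolates the
  property under test — segmentation and measurement error under noise —
  from fixture round-off. Real vessels are curved, tapered, pulsatile and
  subject to motion; none of that is simulated, so passing recovery tests
  demonstrates correctness of the measurement chain, not robustness to
  motion artifacts.
- **Angiography** ROIs follow baseline → ramp (linear or gamma-variate) →
  exponential washout, with per-pixel Gaussian noise. Physiological
  pulsatility, dye recirculation and spatial transit gradients within an
  ROI are out of scope.
- **ECoG** background shapes white noise to a band-limited `f^{-α}`
  spectrum (defaults α = 1, RMS 50 µV, 2–90 Hz — resembling rodent epidural
  ECoG) and rescales to the target RMS exactly; events are raised-cosine-
  tapered sinusoidal bursts whose envelope peaks at a programmed multiple
  of the background SD. Real seizure-like events are broadband and
  non-stationary; the single-carrier burst is the minimal signal that
  exercises both detection criteria independently.
- **Histology** images program exact pixel counts (blob fraction, per-
  section ipsilateral area), so closed-form cases (0%, 25%, 50%, 37.1%)
  are recovered to rounding. Staining gradients, section damage and
  mask-drawing variability are not simulated.

## The demo pipeline

`demo_config()` encodes the four chronic treatment groups with group sizes
(8/9/8/6) and effect levels mirroring the chronic experiment: mean
cortical-volume loss 37.1% (RB), 20.6% (RB-SPG-15 min), 17.9% (RB-SPG-24 h)
and 0 (Sham), with 5-point between-animal jitter; Evans-blue extravasation
fractions 0.25/0.10/0.10/0.01; and seizure-like-event counts 8/2/2/0 per
recording. Recording durations are desk-scale — 300-s ECoG sessions with
120-s day-1 baselines rather than 3-h telemetry days — a deliberate problem
size that exercises every code path (band powers, event detection, burden,
group comparison) while keeping a full simulate–analyze–compare run in
tens of seconds. Per-animal seeds derive arithmetically from the master
seed, so a rerun with the same config is byte-identical; the group means
printed by the demo are therefore reproducible but, with these small n and
short sessions, carry visible sampling error around the programmed levels.

## Known limitations

- Segmentation assumes a single dominant vessel scale; the threshold window
  must be chosen against the widest vessel of interest.
- Diameter measurement needs a locally straight skeleton over ±3 px;
  bifurcation points and sharply curved segments will bias the tangent.
- The event detector's thresholds are calibrated implicitly by the day-1
  baseline; a contaminated baseline (movement artifacts, electrical noise)
  shifts both criteria.
- Lesion volumetry is an equal-thickness area proxy, not a cavity-aware
  volume reconstruction.
- The Mann-Whitney exact path requires tie-free data; heavily tied
  percent-change data fall back to the corrected normal approximation.
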