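---
title: "Estimating tidal volume and respiratory rate from depth video: methods and design"
author: "respdepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tidal volume and respiratory rate from depth video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A seated person breathing quietly moves their chest and abdominal wall by a
few millimetres per breath.  A time-of-flight depth camera a metre away
records that motion as a per-pixel distance map, so the average depth over a
well-chosen body region is, up to sign and scale, a respiratory displacement
signal.  Two quantities are read off it per breath:

* **Respiratory rate (RR)** — the reciprocal of the interval between
  consecutive end-inspiration peaks, in breaths per minute.
* **Tidal volume (TV)** — the litres of air moved per breath.  Displacement
  amplitude is proportional to displaced chest-wall volume, so a single
  linear regression against a reference spirometer, fitted once per stratum
  (e.g. sex or clothing condition), converts millimetres of amplitude into
  litres.

The two instruments run on separate clocks; a trigger channel recorded in
the reference trace at the instant the camera starts ties the time axes
together (`align_by_trigger()`).

## Adaptive region of interest

How much of the TV signal lives in the rib cage versus the abdomen differs
between people, so a fixed rectangle is wasteful for some subjects and
noisy for others.  The ROI is therefore determined adaptively, once, at the
start of a recording:

1. **Upper body.**  The default detector thresholds the depth frame
   (subject nearer than `max_subject_depth_mm`, default 2 m) and keeps the
   largest connected component.  An external pretrained upper-body detector
   can be plugged in as a function; none is assumed to exist.
2. **Shoulders.**  The silhouette contour is polygon-approximated
   (Ramer–Douglas–Peucker, tolerance 2 % of the silhouette height — scale
   invariant, suppresses pixel jaggies while keeping true corners).  On
   each side, the shoulder is the most convex vertex (largest turn angle)
   within the lateral third of the upper-body box; ties go to the vertex
   nearer the head.  The turn-angle rule is this package's choice: with a
   seated subject and lowered arms the shoulder tip is the one place the
   contour turns from the near-vertical arm line to the near-horizontal
   shoulder run.
3. **Tentative rectangle.**  Top at the lower shoulder; sides trimmed
   inside each shoulder by an approximate arm width (default 15 % of the
   shoulder distance, configurable — the protocol literature gives no
   number); bottom provisionally at the image edge.
4. **Unit grid.**  The rectangle is tiled with 19 × 19 px unit areas slid
   every 10 px; the mean depth of each unit suppresses sensor noise, which
   is correlated only between close pixels.  Units with more than 50 %
   invalid pixels in more than 10 % of frames are flagged invalid rather
   than silently zeroed.
5. **Row amplitude ratio.**  Unit waveforms are averaged per grid row; the
   per-breath excursion (max − min inside each breath window) of each row
   waveform, averaged over breaths and normalised across rows, gives the
   row's share of the total breathing motion.  Breath windows come from
   one global segmentation of the tentative-ROI mean signal — per-row peak
   detection is unstable for the weak bottom rows, which is the very thing
   being measured.
6. **Final bottom.**  The ratio is accumulated from the top row; the first
   row where the running sum *reaches* 90 % (first crossing, `>=`) closes
   the ROI at that row's lower unit edge.  Everything below — lap, thighs,
   chair — is discarded.

Two conditioning details matter in practice.  Row waveforms are smoothed
with the same 0.5 s zero-phase moving average as the main signal before
excursions are measured: a unit straddling the torso/background depth edge
otherwise turns isolated dropout pixels into multi-millimetre spikes
("flying pixels") and hands the bottom rows amplitude they do not have.
And rows with no valid unit are dropped before normalisation and reported,
never imputed.

## Signal processing and breath segmentation

The final-ROI mean depth is negated (inspiration positive), mean-removed,
linearly resampled to a uniform 30 Hz clock, and smoothed by a 0.5 s
zero-phase moving average — wide enough to suppress jitter, narrow enough
to pass the sub-1 Hz respiratory band.  Peaks are local maxima with
topographic prominence at least `max(0.5 mm, 20 %` of the median
peak-to-trough excursion`)` and spacing at least 1.5 s (bounding RR at 40
breaths/min); the adaptive threshold admits quiet and deep breathing with
one rule.  Between consecutive peaks the global minimum is the valley.  A
leading minimum before the first peak counts as a valley only when it is
interior; a boundary minimum means the recording started mid-breath, and
that partial breath is dropped — only complete valley-to-peak pairs yield
amplitudes.  Peak/valley alternation is asserted on every output.

The reference volume trace is processed with the same resampling, the same
smoothing and the same detector (prominence floor 0.05 L), so the two
instruments receive identical treatment.  Estimated and reference breaths
are paired greedily by nearest peak time within 2 s, each breath used at
most once and unmatched breaths counted; the regression of reference TV on
depth amplitude includes an intercept by default (a zero-intercept fit is a
flag away; the source procedure does not say which it used).  Negative TV
predictions are unphysical and are clipped to zero with a warning count.

## Agreement statistics

`agreement_report()` computes, on matched pairs: the mean absolute
relative error of TV (percent); the Bland–Altman mean difference with a
t-based 95 % confidence interval (small-sample correct) and 1.96 · SD
limits of agreement; proportional bias as the Pearson correlation of
difference against pair mean with its two-sided p-value at a 5 % level;
and the count of breaths whose RR difference strictly exceeds 1 breath/min.
All formulas are checked in the test suite against an independent
plain-sum implementation to 1e-9.

## The synthetic torso

No recordings accompany the method, so validation rests on a simulator
that renders what the camera would see:

* a silhouette (head ellipse, neck, trapezoidal torso) at 1 m against a
  3 m backdrop, orthographically projected at the pitch implied by a
  70.6° field of view;
* disjoint chest and abdomen masks moving as `(1 - cos)/2` sinusoids
  between end-expiration and their amplitudes, with an optional phase lag
  (thoracoabdominal asynchrony);
* a static surface relief — transverse body curvature plus a gentle
  corrugation.  This is not decoration: a perfectly flat surface under a
  uniform displacement quantises to whole millimetres in the rendered
  integer depth, and per-breath amplitudes inherit the quantisation.  On
  a curved surface the rounding dithers out under 19 × 19 averaging,
  exactly as on a real torso;
* sensor degradation: Gaussian pixel noise (default SD 1.5 mm) and
  dropout to the 0-value (default 0.5 %) — plausible ToF figures, as the
  source procedure states none; slow whole-body depth sway (default
  period 60 s, postural drift); optional vertical sway; and a Gaussian
  blur of the displacement field standing in for clothing smoothing.

Ground truth carries the instantaneous displaced volume (the surface
integral of the displacement field), per-breath TV and peak times in
closed form, the programmed rate, and the shoulder pixels.  The
spirometer emulation samples that volume on its own clock with the
trigger raised at a configurable lag.

`make_cohort()` draws subject presets with chest circumference centred on
published elderly reference means (103.5 cm male, 87.4 cm female), quiet
amplitudes of 4–6 mm (chest) and 3–5 mm (abdomen), rates of 10–16
breaths/min, and a deep phase at 2.5 × amplitude and 0.6 × rate for five
breaths.  The within-stratum circumference SD is deliberately 3 cm, well
below the clinical spread: the amplitude-to-volume slope scales with torso
size, so population-level heterogeneity inflates pooled-calibration error
regardless of algorithm quality.  A tight cohort makes the held-out error
measure the pipeline, not the population; the consequence of realistic
heterogeneity is visible in the clinical error range and is not what the
synthetic study is for.

What the simulator does **not** emulate — garment dynamics, perspective
distortion, IR shading, posture changes mid-recording, imbalanced
left/right thoracic motion — bounds what passing tests show: they
demonstrate correctness of the measurement chain under the stated physics,
not clinical performance.

## Numerical choices and problem sizes

* Depth is integer millimetres, 0 reserved for "no reading"; the on-disk
  container is a directory of 16-bit grayscale TIFF frames plus a
  timestamps CSV, round-tripping bit-exactly.
* Unit averaging precedes the 30 Hz resampling (the source wording is
  ambiguous; averaging per native frame is the order that does not
  interpolate across invalid pixels).
* The cumulative-ratio comparison is `>=` the cutoff ("reached" read as
  attainment); ties in shoulder convexity go to the vertex nearer the
  head; equal-size foreground components tie toward the leftmost.
* Moving-average windows are forced odd and shrink symmetrically at the
  edges, so smoothing is zero-phase and constants are fixed points.
* Validation runs use 212 × 256 px frames (half the sensor grid) rendered
  at 15 fps (30 fps for the rate-recovery run), 40 s of quiet breathing
  plus five deep breaths per subject, and a 10-subject cohort — sizes
  chosen so the whole validation suite completes in minutes on one core
  while every stage still operates far from its degenerate limits.
* Held-out evaluation splits breaths alternately within each recording:
  odd breaths train the per-stratum regression, even breaths are scored.

## Known limitations

The ROI is fixed after the initial frame; large trunk motion during deep
breathing violates that assumption, and the simulator's sway mechanism
reproduces the resulting underestimation directionally.  Subjects with
markedly asymmetric thoracic motion are outside the model.  The breath
detector assumes rates below 40 breaths/min and will merge faster
breathing.  Calibration transfers across recordings only insofar as the
subject-camera geometry is unchanged.
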