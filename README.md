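# respdepth

Non-contact estimation of **tidal volume (TV)** and **respiratory rate
(RR)** from depth-camera recordings of a seated person.

Home monitoring of breathing matters for people with heart failure —
respiratory rate and breathing depth change before an exacerbation — but
spirometers and plethysmographs are obtrusive and alter the very breathing
they measure. A time-of-flight depth camera a metre in front of a chair
sees the chest and abdominal wall move by millimetres per breath; averaged
over the right body region, that motion *is* a respiratory signal.

`respdepth` implements the full measurement chain in R:

1. **Landmarks** — silhouette segmentation of the depth frame, shoulder
   detection as the most convex vertices of the polygon-approximated
   contour.
2. **Adaptive ROI** — a rectangle below the shoulders, tiled with
   19 × 19 px unit areas every 10 px; each grid row's share of the
   per-breath depth excursion (its *amplitude ratio*) is accumulated from
   the top, and the ROI bottom is closed where the running sum reaches
   90 %, discarding lap and chair rows that carry no breathing motion.
3. **Signal** — ROI-mean depth, inspiration-positive, resampled to 30 Hz,
   smoothed by a 0.5 s zero-phase moving average; breaths segmented by
   prominence-based peak/valley detection.
4. **Calibration** — per-breath displacement amplitude *a* (mm) regressed
   against reference spirometer tidal volume: `TV = slope · a + intercept`
   (single linear regression, one model per stratum), with the two
   instruments synchronised through a trigger channel.
5. **Agreement** — mean absolute relative TV error, Bland–Altman fixed
   bias (t-based 95 % CI) and proportional bias (Pearson r of difference
   vs pair mean), limits of agreement, and counts of breaths whose RR
   error exceeds 1 breath/min.
6. **Synthetic torso** — a ground-truthed simulator (compartmental
   chest/abdomen motion, postural sway, clothing smoothing, ToF noise and
   dropout) so every stage is testable without any recording.

## Worked example

Simulate a calibration session (40 s quiet breathing, then five deep
breaths) with sensor noise and 2 mm postural sway, calibrate against the
synthetic spirometer trace, and evaluate agreement:

```r
library(respdepth)

scene <- torso_scene(212, 256)                      # seated torso at 1 m
quiet <- breathing_program("normal", rr_bpm = 14, duration_s = 40)
deep  <- breathing_program("deep",   rr_bpm = 8.4, n_breaths = 5)
rec <- render_session(scene, list(quiet, deep),
                      noise_model(sway_amp_mm = 2), fps = 15)
ref <- synth_reference_trace(rec$truth, sample_rate = 100,
                             trigger_lag_s = 1.5)

model <- run_calibrate(rec$seq, ref, label = "demo")
print(model)
#> Tidal-volume calibration (single linear regression)
#>   stratum : demo
#>   TV [L] = 0.1582 * amplitude [mm] +0.1230
#>   r-squared = 0.9416 on n = 13 breaths

est <- run_estimate(rec$seq, calibration = model)
print(est)
#> respdepth estimate
#>   shoulders: left (53, 101), right (53, 154)
#>   ROI: rows [53, 192), cols [109, 146) (tentative bottom 212)
#>   breaths: 14, mean amplitude 5.86 mm, mean RR 11.87 BPM

refseg <- segment_reference(ref, align_by_trigger(rec$seq, ref))
report <- run_evaluate(est$breaths, refseg$breaths)
print(report)
#> Agreement report
#>   matched breaths      : 13 (unmatched est 1, ref 1)
#>   TV MARE              : 7.36 %
#>   TV bias              : 0.0000 L (95% CI -0.0762 to 0.0762) -> no fixed bias
#>   limits of agreement  : -0.2472 to 0.2472 L
#>   proportional bias    : r = -0.124, p = 0.688 -> absent
#>   RR errors (>1 BPM)   : 1 / 12 breaths
```

Reading the output: the regression slope says each millimetre of ROI-mean
displacement moves ≈ 0.16 L of air for this torso geometry; the mean
absolute relative TV error across held breaths is 7.4 %; the bias CI
includes zero (no fixed bias) and the difference–mean correlation is not
significant (no proportional bias); one breath's rate disagreed with the
reference by more than 1 breath/min.

Recordings can also be exchanged on disk — a directory of 16-bit TIFF
depth frames plus `timestamps.csv` (`read_depth_sequence()` /
`write_depth_sequence()`) and a `time_s,volume_L,trigger` CSV for the
reference (`read_reference_trace()`) — and driven from the shell via
`inst/cli/respdepth` (subcommands `simulate`, `estimate`, `calibrate`,
`evaluate`).

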