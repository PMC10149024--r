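---
title: "Methods: ankle-IMU gait analysis for the six-minute walk test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ankle-IMU gait analysis for the six-minute walk test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsci)
```

This vignette documents the model behind `gaitsci`, the defaults of every
tunable parameter and why they were chosen, the scope and deliberate limits
of the synthetic generator, and the resolutions of the methodological
questions the pipeline had to settle.

## 1. Measurement model

Each ankle carries one IMU: a tri-axial accelerometer (±16 g span) and a
tri-axial gyroscope (±2000 °/s), nominally sampled at 200 Hz. Canonical
internal units are seconds, m/s² and rad/s; `read_recording()` converts `g`
and `deg/s` on ingestion, and g = 9.80665 m/s² throughout.

During walking, the dominant rotation of the shank is about the lateral
(medio-lateral) axis — the axis perpendicular to the sagittal plane. Its
angular velocity trace has a stereotyped shape per stride: a large positive
peak at mid-swing flanked by two negative troughs, one just after initial
contact (heel strike) and one around final contact (toe off). Nearly all
event detection in this package reads that one channel.

- **Channel selection** (`sagittal_gyro`): the gyroscope column with the
  largest variance. Strap orientation in the field is not guaranteed, so the
  sign is flipped when the 0.1%/99.9% quantile magnitudes say the big peaks
  point down. Extreme quantiles (rather than, say, 2%/98%) are used because
  the IC/FC troughs of slow, cautious gait can rival the mid-swing peak in
  area — only the very tip heights separate the two polarities reliably.
- **Rest segmentation** (`walking_mask`): 2 s moving variance of the
  sagittal channel below 0.01 (rad/s)² marks rest. The window must cover at
  least one stride (typical stride durations are 1–2 s after iSCI), and the
  threshold sits two orders of magnitude under walking-level variance while
  staying above sensor noise (0.05 rad/s white noise gives 0.0025 (rad/s)²).

## 2. Stride and event detection

1. **Cadence** (`estimate_cadence`): FFT magnitude of the demeaned walking
   segments, zero-padded to ≥ 32768 points (frequency resolution ≤ 0.006 Hz
   at 200 Hz). The largest magnitude in 0.3–1.5 Hz is the stride frequency;
   the band spans severely slowed (18 strides/min) to brisk (90 strides/min)
   walking and excludes the step frequency at twice the stride rate.
2. **Mid-swing peaks** (`detect_strides`): local maxima above
   `max(0.2 × q95(|ω_z|), 0.5 rad/s)`, separated by at least 0.6 stride
   periods. Both terms adapt: the amplitude term scales with the walker's
   own signal, the distance term with their cadence; the 0.5 rad/s floor
   keeps rest-period noise from producing peaks at all.
3. **Initial/final contacts** (`detect_gait_events`): between consecutive
   mid-swing peaks at `p` and `np` (interval `T`), the IC is the gyro
   minimum in `[p + 0.08 T, p + 0.45 T]` and the FC the minimum in
   `[np − 0.40 T, np − 0.06 T]`. The windows bracket where the troughs live
   across gait speeds while never overlapping the mid-swing peaks
   themselves. Mid-swing intervals longer than 1.8× the median are rest
   gaps and yield no events. An accelerometer-magnitude peak within ±50 ms
   of each IC is recorded as a corroboration *flag* (`ic_corroborated`),
   not used for rejection: an impact transient is evidence for a contact,
   but its absence (soft, cautious contact; low-bandwidth sensing) is not
   evidence against one.
4. **Temporal parameters** (`compute_temporal_params`): stride duration
   (consecutive same-side ICs), step duration (to the next contralateral
   IC), swing% (`(next IC − FC)/stride × 100`), and double-support% as the
   measured sum of the two bilateral-stance intervals inside the stride.

## 3. Orientation and trajectory reconstruction

Orientation (`estimate_orientation`) is strapdown gyro integration on unit
quaternions, corrected toward the accelerometer's gravity direction by a
complementary filter with gain 0.01 per sample (≈ 0.5 s time constant at
200 Hz). The correction is applied only on quasi-static samples, where the
specific-force magnitude is within 1 m/s² of g. Without this standard gate,
swing-phase movement acceleration — tens of m/s² at the ankle — would be
interpreted as gravity and corrupt the tilt estimate; with it, each stance
phase supplies a short burst of reliable inclination evidence, which is
exactly what the filter needs to cancel the gyro-bias drift between stances.
Heading is deliberately unobserved (no magnetometer: indoor clinical
environments are magnetically hostile); it is neutralised later.

Trajectories (`reconstruct_strides`) use the zero-velocity-update (ZUPT)
scheme: the mid-stance anchor of each stride is the minimum of the smoothed
gyro norm within the central 20–80% of stance — the instant the foot is
flattest and stillest. Between consecutive anchors the globally-rotated,
gravity-subtracted acceleration is integrated to velocity (trapezoidal),
the velocity is forced to zero at both anchors by removing the linear trend
(first-order drift is precisely what integrated white noise plus a small
residual gravity leak produce), and integrated again to displacement. The
horizontal axes are then rotated per stride so the net displacement defines
"forward", which simultaneously removes the free heading. Stride length is
the net horizontal displacement, height the maximal vertical excursion,
width the maximal absolute lateral excursion; strides displacing less than
0.2 m are flagged as turns and excluded from spatial statistics (a 6MWT on
a 30 m track forces a 180° turn roughly every 30–40 strides).

## 4. The gait parameter set

`extract_gait_parameters()` produces a fixed, named vector
(`speed_mean` + 7 base parameters × up to 4 statistics + cyclogram,
smoothness and change metrics). Side-specific entries come from the *more
impaired* side — the leg with the lower lower-extremity motor score (LEMS);
healthy controls and LEMS ties use the right side, a fixed convention that
keeps the choice deterministic.

- **cov** = sd/mean × 100 (sample sd, n − 1): stride-to-stride variability.
- **asym** = |L − R| / (0.5 (L + R)) × 100: symmetric index, 0–200%.
  It is computed for all base parameters except stride length, whose
  left/right difference is already captured by step-level measures and
  whose side means are strongly coupled through common forward progression.
- **d2r** = (X − X_ref(v)) / X_ref(v) × 100: difference to a healthy
  reference *at matched speed* v, because almost every temporal parameter
  varies lawfully with walking speed; comparing a slow patient to
  full-speed norms would conflate slowness with abnormality. The reference
  (`build_reference`) interpolates control values piecewise-linearly over
  speed, requires ≥ 3 control trials spanning ≥ 0.3 m/s, and clamps (and
  flags) queries outside the covered range rather than extrapolating.
- **Cyclograms** (`compute_cyclogram`): each non-turn stride's trajectory
  is projected to the side (forward–vertical) or top (forward–lateral)
  plane, resampled to 100 points uniformly in normalized stride time,
  centred at its centroid and scaled to unit RMS radius — shape, free of
  size and offset. SSD is the summed squared pointwise distance to a
  reference shape; ACC is the mean circular resultant length of the
  per-segment direction angles across cycles (100% = every cycle traces the
  same direction sequence); area is the absolute shoelace area.
- **Smoothness** (`compute_smoothness`): modified spectral arc length of
  the sagittal angular velocity — the negated arc length of the
  max-normalized magnitude spectrum up to an adaptive cutoff (largest
  frequency ≤ 20 Hz where the normalized magnitude still reaches 0.05),
  with the frequency axis scaled by the cutoff. The adaptive cutoff keeps
  the measure from rewarding slow walkers merely for having narrow spectra.
- **Change/fatigue** (`compute_change`): per-stride speed, stride length
  and cadence are regressed on stride mid-time; the change is
  slope/intercept (fractional change per second). It requires ≥ 10 strides
  spanning ≥ 120 s — shorter spans measure bout-to-bout noise, not fatigue.
  `speed_inconsistency` is |change of speed|.

## 5. Cohort analyses

**Clustering** (`identify_gait_clusters`): features are standardized and
projected by PCA; the number of retained components is the smallest
reaching 65% cumulative explained variance — enough to keep the dominant
gait dimensions while discarding noise axes that would dilute cluster
structure. The number of clusters k is chosen on the Ward (`ward.D2`)
dendrogram as the k maximising the relative drop in merge height between
k − 1 and k clusters (ties to the smaller k); k-means with 50 restarts then
produces the final assignment, and labels are re-indexed by decreasing mean
6MWT distance so cluster 1 always denotes the best walkers. Core
discriminative parameters are the union of the 5 largest-|loading| features
per retained PC, filtered by Kruskal–Wallis p < 0.05 across clusters, with
one of each feature pair correlated above |r| = 0.9 removed (the one with
the larger p). Group comparisons use Kruskal–Wallis (continuous), Fisher's
exact test (categorical; Monte-Carlo p with B = 10000 above 2×2), and
pairwise Dunn post-hoc z tests with tie correction (Holm-adjusted p
reported alongside the unadjusted values).

**Improvement prediction** (`loso_cv`): consecutive 6MWT pairs within a
subject form observations, labelled *improved* when the later distance
exceeds the earlier by strictly more than 16.5 m — the standard error of
measurement of the 6MWT in this population, so "improvement" means a change
beyond test–retest noise. Subjects whose first test falls beyond day 365
post-injury are shifted so it sits at day 365: once chronic, additional
elapsed time carries no further prognostic information, and the shift stops
extreme day counts from dominating the standardized predictor. Feature
set 1 = {present distance, days since injury, days until next test};
set 2 adds the gait parameters. Classification is a 500-tree random forest
under leave-one-subject-out cross-validation; by default standardization,
|r| > 0.9 redundancy removal and importance-based top-10 selection are
re-fit inside every training fold (no leakage). The non-nested mode
(`nested = FALSE`) is available for comparison. Results are reported per
observation (a subject with three tests contributes two observations, which
may fall in different classes).

## 6. The synthetic generator: scope and limits

`simulate_trial()` is the package's ground-truth instrument, not a
biomechanical simulator. Its contract: every quantity the pipeline is
supposed to estimate is *planted exactly*, and the sensor streams are
*physically consistent* with those planted quantities.

Per stride, the ankle endpoint follows a C² closed-form path: quintic
smoothstep forward progression (zero velocity and acceleration at both
ends) and cubic-squared bumps for the vertical and lateral excursions, all
supported entirely on the swing phase — the foot is exactly stationary
throughout stance, which is what gives the mid-stance ZUPT anchors their
meaning. The accelerometer is the analytic second derivative of that path
plus gravity, expressed in a sensor frame that pitches with the shank; the
sagittal gyro channel is a sum of Gaussian lobes (positive at mid-swing,
negative troughs at IC and FC with amplitudes balanced so the net rotation
per stride is zero and the shank angle stays bounded). Stride durations and
lengths are lognormal with mean-1 multipliers (so planted means are exact),
speed drift multiplies stride length linearly in time, asymmetry factors
scale the left side, and rest breaks interrupt the timeline at stride
boundaries. Noise is white Gaussian per channel plus a constant gyro bias;
a seed makes every trial bit-reproducible via a local RNG that restores the
caller's state.

Deliberate limits: no soft-tissue artefact, no impact transients at heel
strike (contacts are C², which is why IC corroboration is a flag), no
magnetic disturbance (no magnetometer is modelled), no slopes or stairs,
and turns are not synthesized (the turn-exclusion logic is exercised by its
displacement threshold instead). One physical constraint is enforced rather
than configurable: in any alternating bipedal gait the total double-support
fraction is identically `1 − 2 × swing fraction` — both feet are on the
ground exactly when neither is in swing — so `gait_profile()` derives the
double-support fraction and rejects inconsistent pairs instead of silently
planting an impossible gait.

Defaults (stride 1.1 s and 1.2 m, height 0.12 m, width 0.05 m, swing 40%,
cov 3%, 360 s at 200 Hz) describe a mildly slowed adult walker over a
six-minute test; they are study conditions, fixed before any pipeline
tuning, not calibration targets.

## 7. Numerical choices

- Trapezoidal integration everywhere (`cumtrapz`); exact for the piecewise
  linear signals of the ZUPT detrending and second-order accurate
  elsewhere, which is sufficient at 200 Hz.
- FFT sizes are powers of two with a 32768 floor (cadence) / 16384 floor
  (smoothness) so frequency resolution, not signal length, limits accuracy.
- Peak finding tolerates plateaus (first sample of a flat top) and resolves
  spacing conflicts greedily by descending height, earliest first — a
  deterministic rule with no RNG involvement.
- All stochastic routines (`simulate_*`, k-means restarts, Monte-Carlo
  Fisher, random forests) take explicit seeds and run under a local RNG
  scope, so identical inputs give bit-identical outputs and the session's
  random stream is never disturbed.
- Problem sizes in examples and tests (e.g. 60-row cluster tables, 23
  subjects with a 10/9/4 repeat structure giving 40 observations) are the
  package's own desk-scale choices: large enough for the statistics to be
  meaningful, small enough that the whole suite runs in minutes.

## 8. Resolved design questions

- **Double support as a free parameter?** No — derived from swing (see §6);
  supplying an inconsistent value is an error, not a warning.
- **Reject strides without accelerometer IC corroboration?** No — flag
  only (§2.3).
- **Orientation filter gain under dynamic acceleration?** Keep the 0.01
  gain but gate the correction to quasi-static samples (§3); an ungated
  filter at this gain visibly corrupts tilt during swing.
- **d2r outside the control speed range?** Clamp to the nearest covered
  speed and flag `extrapolated`, never extrapolate a linear fit beyond data.
- **Ward elbow ties / degenerate heights?** Ties resolve to the smaller k;
  zero or non-finite relative drops count as no elbow.
- **Same-subject observations on both sides of the improvement label?**
  Allowed; cross-validation folds are split by subject, so the labels of a
  held-out subject never inform its own prediction.
- **Nested vs. global feature selection in cross-validation?** Both
  implemented; nested is the default because global selection leaks the
  held-out subject's distribution into the feature ranking.
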