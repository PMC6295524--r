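---
title: "Multi-camera arena tracking and spatial coding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-camera arena tracking and spatial coding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenatrack)
```

Recording freely moving rodents in arenas larger than a single camera's
useful field of view forces three coupled problems: stitching several
overhead views into one metric coordinate frame, keeping every camera's
frame clock on the acquisition system's timeline, and quantifying how the
residual imperfections (registration error, frame-timing jitter, occlusion)
propagate into downstream spatial-coding statistics such as place-field
maps and spatial information. `arenatrack` implements that full chain, plus
a synthetic-data generator with exact ground truth so every stage can be
validated quantitatively without recording hardware.

This vignette explains the model behind each stage, why the default
parameters are what they are, and where we made judgement calls.

## 1. Geometry: planar homographies

All cameras look down on a planar arena, so the map from arena coordinates
(cm) to each camera's pixel plane is a projective homography, a 3x3 matrix
acting on homogeneous coordinates with 8 degrees of freedom. This is exact
for a true plane and an ideal pinhole; we deliberately do not model lens
distortion (see section 6).

`fit_homography()` implements the normalized direct linear transform:
points in each set are translated to their centroid and isotropically
scaled to mean distance sqrt(2) before building the 2n x 9 design matrix,
whose smallest right singular vector is the homography. The normalization
is not cosmetic — without it the DLT system's conditioning degrades by
several orders of magnitude at typical pixel scales.

Because automatic feature matching produces outliers,
`estimate_homography_ransac()` wraps the DLT in RANSAC: minimal 4-point
samples, inlier classification at a pixel threshold (default 2 px),
adaptive iteration count from the current best inlier ratio, and a final
least-squares refit on the consensus set. `build_canvas()` then chains
pairwise homographies over a spanning tree of camera-overlap links to
express every camera in a reference camera's frame, and converts pixels to
centimetres with a single known landmark distance. With noiseless
correspondences the whole chain recovers ground-truth homographies to
relative errors near machine precision; with 0.5 px feature noise the
cross-camera projection error of the default eight-camera rig over a
5.5 m x 3 m arena stays well under the bin size used for rate maps.

Registration quality is summarized by `projection_error()`: points seen by
several cameras are warped onto the canvas and each observation's distance
to the per-point mean is reported. This measures internal consistency,
which is what matters for merging detections; absolute scale accuracy is
set by the landmark.

```{r, eval = FALSE}
arena <- arena_spec(550, 300)
rig <- make_camera_rig(arena, nx = 4, ny = 2, overlap_frac = 0.25,
                       rotations = seq(-2, 2, length.out = 8))
scene <- generate_calibration_scene(rig, n_features = 260, seed = 1)
canvas <- build_canvas(scene$frames, seed = 1)
```

## 2. Time: TTL synchronization and frame-interval jitter

Each camera timestamps frames on its own clock, which differs from the
acquisition (DAQ) clock by an offset and a slow drift. A shared TTL pulse
train is recorded by both sides; `build_clock_map()` pairs pulses by index
and `align_timestamps()` maps camera time to DAQ time by piecewise-linear
interpolation between pulse pairs. For clocks that are affine in the DAQ
clock (offset + drift), two pulse pairs already make the correction exact;
outside the pulsed span we extrapolate with a constant offset rather than
trusting the outermost slope.

`ifi_report()` diagnoses frame-timing quality from the interframe
intervals (IFIs): deviations from the nominal interval are reported
verbatim, and an IFI within 25% of k times the nominal interval (k >= 2)
is counted as k - 1 dropped frames. The deviation thresholds (1 ms, 7 ms)
bracket the two camera classes we model: hardware-triggered camera modules
whose IFIs vary by a few microseconds, and consumer webcams whose IFIs
commonly deviate by several milliseconds.

`inject_jitter()` lets us impose one camera's timing distribution on
another session: IFIs are resampled with replacement from an empirical
pool and rescaled so the jittered session spans exactly the original
recording. The resulting timestamp displacement behaves like a Brownian
bridge with scale sd * sqrt(n)/2, which is why millisecond-scale IFI noise
can displace timestamps by tens of milliseconds mid-session — the
mechanism behind the degradation results below.

## 3. Tracking: two LEDs, many cameras

Position and head direction come from a red (anterior) and green
(posterior) LED. Per frame and per camera, `detect_leds()` masks pixels
whose maximum RGB channel exceeds an intensity threshold (default 50 of
255), converts to HSV on OpenCV-style scales (H 0-180, S/V 0-255), gates
by colour (red H 0-10 or 160-180, S 100-255, V 50-255; green H 50-70,
S 50-255, V 100-255), and takes the centroid of the largest 8-connected
component of at least 3 px. Per-camera detections are warped to the canvas
and merged by averaging (`merge_positions()`); a camera that does not see
an LED simply contributes nothing, which is what makes occlusion handling
seamless — if only one camera sees the animal, the merged position *is*
that camera's warped detection.

Because cameras are not synchronized frame-to-frame, each camera's frames
are first aligned to the DAQ clock and then associated to the reference
timeline nearest-neighbour within half an expected IFI. Gaps where no
camera saw an LED are linearly interpolated up to `max_gap` frames
(default 5); longer gaps stay missing rather than invent data. Head
direction is the angle of the green-to-red vector; speed is a
central-difference estimate over a short window used to filter immobile
samples from rate maps (threshold 2 cm/s).

## 4. Spatial coding metrics

Rate maps (`compute_rate_map()`) bin position at 2 or 4 cm, keep samples
above the speed filter, and require 0.4 s occupancy per bin. Smoothing is
a Gaussian kernel (sigma = 1.25 bins) renormalized over the valid-bin
mask, so arena edges and occupancy holes are not dragged toward zero.
`adaptive_rate_map()` implements adaptive binning: around each bin the
radius grows until spikes exceed alpha / (n_samples^2 r^2) with
alpha = 1e6, trading spatial resolution for rate stability in
poorly-sampled regions — this is the estimator used for the
shuffle-significance "adaptive" method.

Spatial information is the Skaggs estimator,
sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda) in bits/spike.
Significance uses a cyclic time shuffle: spike times are rotated by a
random offset in [30 s, T - 30 s] (preserving the spike train's temporal
structure while breaking its position coupling) 1000 times, and the
p-value is the fraction of shuffles with information at or above the
observed value. On 500 spatially untuned Poisson cells this test's
false-positive rate at p < 0.01 lands at 1% within sampling error, which
is the calibration property the cyclic shuffle is chosen for.

Place fields are segmented by descending local maxima: from each
unclaimed peak, the 4-connected region above 15% of that field's peak is
grown; regions need at least 7 bins and a peak above 25% of the map peak.
Head-direction tuning uses 5 degree bins, circular smoothing and an
interpolated full width at half maximum. Theta phase is assigned by
linear interpolation between consecutive theta peaks; phase precession is
a least-squares phase-versus-position line whose inversion yields the
positional scatter d_p = (phase - intercept)/slope - position.

## 5. The synthetic generator

Trajectories are an Ornstein-Uhlenbeck walk in velocity with reflecting
walls; the velocity scale is set so the mean *speed* (not velocity
component sd) matches the requested value, via sd_v = mean_speed /
sqrt(pi/2). Video is rendered lazily — frames are functions, not arrays —
so multi-minute multi-camera sessions fit in memory; each frame draws the
two LED discs through the camera homography. Spikes are inhomogeneous
Poisson by thinning against Gaussian place fields, von Mises
head-direction tuning, or phase-precessing fields whose spikes are
repositioned within the theta cycle. Empirical IFI pools model the two
camera classes: a "commercial webcam" pool (normal, sd approximately
1.19 ms, truncated at +-7 ms, so roughly 40% of deviations exceed 1 ms)
and a "camera module" pool (sd approximately 1.2 microseconds, truncated
at +-25 microseconds).

The degradation experiment (`run_benchmark()`, criterion-style) simulates
20 place cells over a 20-minute session, analyses each cell against the
native 30 Hz timeline and against the same timeline with webcam IFIs
injected, and compares spatial information, peak rate and field size with
paired Wilcoxon signed-rank tests. Webcam-scale jitter reliably lowers
spatial information and peak rate; module-scale jitter leaves the
continuous metrics unchanged to well under 1%. Field size, an integer bin
count, is dominated by occupancy-threshold granularity at this session
length and does not move reliably in either direction (see section 6).

## 6. Judgement calls and known limits

* **No lens distortion model.** Homographies assume rectilinear optics.
  For the wide-angle lenses this matters for, undistort first; adding
  distortion estimation would couple registration to per-camera intrinsics
  and is out of scope.
* **Index-paired TTL pulses.** We pair pulses by order, trimming to the
  shorter log with a warning, rather than solving a correspondence
  problem. With a shared pulse train this is correct unless a side drops
  pulses mid-session, which the trim warning surfaces.
* **Mean merging across cameras.** Detections are averaged unweighted.
  Weighting by blob size or view angle was considered and rejected: with
  sub-centimetre per-camera error the mean is already unbiased, and
  weights would add tunables without measurable benefit in the rig QC.
* **Raw IFI deviations include dropped frames.** The jitter range reports
  deviations verbatim, so a dropped frame shows up as a large positive
  deviation as well as in the drop count. Separating them would hide the
  fact that a drop *is* a timing error for any consumer of the series.
* **Field size granularity.** Place-field sizes are integer bin counts;
  at a approximately 80-bin median field, one bin is 1.25%. Sub-percent
  stability claims are therefore only meaningful for the continuous
  metrics (information, peak rate), and cohort medians of small samples
  (20 cells) can move by a full order-statistic gap under negligible
  perturbations. The package's own benchmark pools cells across seeds
  before comparing medians for exactly this reason.
* **Occupancy thresholds on a regular synthetic clock.** With a perfectly
  regular simulated frame rate, a marginal bin's occupancy is an exact
  lattice multiple of the frame interval and can equal the 0.4 s threshold
  exactly (12 x 1/30 s). The comparison uses a small numeric tolerance so
  float roundoff cannot flip validity, but any *physical* timing jitter,
  however small, still genuinely moves about half of those bins below
  threshold. Real cameras never have an exactly regular clock, so this
  discontinuity is a property of idealized synthetic timelines; bin-count
  metrics (field size) are the ones it bites.
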