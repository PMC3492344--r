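---
title: "Assigning genetic identity in mixed fly groups from fluorescence metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning genetic identity in mixed fly groups from fluorescence metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorid)
```

## The model

`fluorid` assigns each tracked fly in a group one of two labels — GFP
(carrying a thoracic fluorescent transgene) or non-GFP — from a handful of
fluorescence images taken before and/or after a behavioral recording. The
method rests on three assumptions:

1. **Registered tracking.** The tracker supplies, per fly per frame, a
   centroid, a head-ward body-axis orientation, and body-ellipse semi-axes,
   in the same pixel coordinates as the fluorescence images. Head/tail
   disambiguation is the tracker's job; a global orientation flip can be
   applied at import if a rig's convention differs.
2. **Spatial contrast, not absolute intensity.** Thoracic transgene signal
   is concentrated in the anterior body half, while autofluorescence is
   strongest in the abdomen (plus, in the worst case, small bright eye
   markers from other transgenes). Absolute intensities vary with
   excitation, expression level and optics, so all metrics are
   dimensionless.
3. **Stable identity within a track.** Identity is assigned per trajectory;
   repairing tracking breaks is out of scope.

### Per-fly metrics

For each fly and image, an oriented rectangle (the Total ROI) is centered
on the tracked centroid with half-extents `length_scale * a` by
`width_scale * b` (default scale 1.2 — the box encloses the fitted ellipse
with a small margin; the figure-level appearance of published overlays does
not pin the exact factor, so it is a parameter). The box is split
perpendicular to the body axis into a Front half (head + thorax) and a Rear
half (abdomen). The split fraction defaults to 0.5 (the anatomical boundary
between thorax and abdomen is near mid-body at this box scale) and is a
recorded parameter, not a constant.

Two metrics are computed:

- **Max 5% Ratio** (Front vs Rear): mean of the brightest 5% of pixels in
  the Front ROI over the brightest 5% in the Rear ROI. Time averaging is
  *ratio-of-averages*: numerator and denominator are each averaged across
  the selected images before dividing, so single-image outliers in the
  denominator cannot blow up the ratio.
- **Skewness** (Total ROI): the biased third standardized moment
  `m3 / m2^1.5` with divisor-`n` central moments, computed per image and
  averaged across images (*average-of-values*). A compact bright blob on a
  dim body yields strong right skew.

A single-maximum variant of the ratio is also provided; it behaves like the
5% version on clean data but inherits the noise sensitivity of a per-image
maximum, which is why the 5% form is the default.

### Calibration and classification

The two metrics live on different scales, so each is min–max normalized to
[0, 1] using the range observed on the *calibration cohort* — homogeneous
groups whose genotype is known with certainty — and combined as
`w * n1 + (1 - w) * n2`. Calibration evaluates a grid of 101 weights
(step 0.01) by 1000 thresholds (evenly spaced over each weight's observed
score range) and selects the operating point `(w*, theta*)` at the center
of the widest contiguous maximum-accuracy threshold run, preferring the
weight whose run is longest. The plateau-center rule operationalizes
"largest cross-section of the maximum-accuracy region": a wide plateau
tolerates score drift between calibration and application data, which is
the failure mode that matters when cohorts are recorded on different days.

Heterogeneous groups are classified two ways:

- **Threshold mode**: score ≥ `theta*` → GFP.
- **Prior-count mode**: scores sorted in descending order; the top `N`
  flies are called GFP, where `N` is the known number of labeled animals.
  This uses strictly more information and is the mode of choice when group
  composition is controlled, reaching a given accuracy with far fewer
  images.

## Numerical and tie-break choices

These rules make every result bit-reproducible; each was an open choice and
is fixed as follows.

- **Top-5% count**: `k = max(1, ceiling(0.05 * n))` — never empty, no
  rounding ambiguity.
- **Skewness degenerate inputs**: fewer than 3 pixels or zero variance is
  an error, not an NA; pipelines should treat such ROIs as data defects.
- **Threshold boundary**: score exactly equal to the threshold is called
  GFP. Equality has measure zero for continuous scores; fixing the side
  makes the sweep deterministic.
- **Degenerate sweep**: if every calibration score is identical, the sweep
  returns the larger-class proportion at every threshold and is flagged
  non-separable.
- **Plateau ties**: equal-length maximum runs break to the lower threshold
  run; equal runs across weights break to the smaller weight. For an
  even-length run the midpoint is the mean of the run's end thresholds.
- **Prior-count ties**: equal scores at the cut break by ascending fly id,
  so permuting input order never changes a call. The reported margin is the
  distance to the midpoint between the scores at ranks `N` and `N + 1`.
- **Pixel membership**: a pixel belongs to an ROI when its center lies
  inside the oriented rectangle (tolerance 1e-9). Pixels exactly on the
  front/rear split plane belong to the Front half, so the two halves always
  tile the Total box exactly. Whether the original rig's boxes were
  body-oriented or axis-aligned cannot be determined from published
  figures; oriented boxes are implemented as the geometrically faithful
  choice.
- **Image selection**: with pre- and post-experiment illumination blocks,
  `alternate` draws images pre-first, alternating, with an odd count's
  extra image from the pre block; `end_only` takes the first `n` post-block
  frames. The alternation order within the stated start/end scheme is fixed
  here for determinism and recorded in output metadata.
- **Angle convention**: head-ward, counterclockwise from +x, radians,
  normalized to [-pi, pi); importers must convert. Image origin is the
  top-left pixel, x rightward, y downward, 0-based.
- **Tracker imports**: exported axis lengths are treated as semi-axes after
  a configurable scale factor (export conventions vary between full-,
  half- and quarter-axis); the importer reads a JSON container of the
  tracker's flat per-frame arrays and points users at CSV/JSON conversion
  for anything else.

## What the synthetic generator emulates — and what it does not

`scene_config()` draws walking flies (Gaussian turn and step noise,
reflecting walls) in an arena whose default 424 × 106 px corresponds to an
80 × 20 mm walking arena at ~5.3 px/mm, the scale at which the default
16 px body equals a ~3 mm adult fly. Flies carry excluded volume: centers
may not come closer than the sum of their semi-major axes. Without this,
independently walking flies interpenetrate for many consecutive frames and
a non-GFP fly's Front ROI is persistently contaminated by a neighbor's
thorax — an artifact solid animals cannot produce, which dominated
classification error in early versions of the generator.

The fluorescence forward model per fly: a dim body ellipse
(`body_base_amp`), a posterior abdominal blob (`abdomen_auto_amp`, all
flies), an anterior thoracic blob (`thorax_gfp_amp`) for labeled flies, and
two small eye-marker spots (`eye_auto_amp`) for unlabeled flies — the
worst-case scenario of a second transgene whose marker lights up ocelli and
eyes. An optional anterior cuticular amplitude for unlabeled flies
(`thorax_auto_amp`, default 0) exists so that a true null model — zero
marker contrast, classes exchangeable — can be expressed; with the default
of 0, equalizing `thorax_gfp_amp` and `abdomen_auto_amp` alone does *not*
make the classes indistinguishable, because unlabeled flies would still
lack any anterior blob. Scenes add stationary arena autofluorescence
patches, a linear illumination gradient across the arena (default 20%
edge-to-edge), and per-pixel Gaussian noise, then clip to the 8-bit (or
16-bit) range. Flies compose by maximum intensity, so close neighbors still
contaminate each other's ROIs.

Defaults represent a high-contrast, low-noise recording: thorax 120 counts
vs abdomen 50, noise SD 3. `noisy_scene_config()` is the stressed regime —
thorax only 2× abdomen (100 vs 50), noise SD equal to the abdomen
amplitude (50), eye markers on — in which single-image classification is
unreliable and time averaging visibly matters.

Not emulated: wing/leg morphology, photobleaching, occlusion-aware tracking
errors, non-Gaussian sensor noise, and temporal correlation of illumination
fluctuations. Passing tests on synthetic scenes therefore demonstrates the
correctness and internal consistency of the pipeline — ROI geometry,
metric arithmetic, calibration logic, both classification modes, and the
qualitative benefits of metric combination, prior counts and image
averaging — but not the absolute accuracy attainable on any particular
rig's recordings, which depends on contrasts and noise the generator only
parameterizes.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use groups of 18 flies (9 + 9 in
heterogeneous scenes), 20 fluorescence frames per scene (10 pre + 10 post),
calibration cohorts of 15 + 15 homogeneous scenes (540 flies) in the
high-contrast condition and 8 + 8 in the noisy condition, 15 fresh
heterogeneous groups for application, and 30 replicate noisy scenes for the
accuracy-vs-image-count curves at counts {1, 2, 4, 10, 20}. These sizes
give stable statistics at desk scale; the pipeline itself has no
dependence on them.

## Known limitations

- Normalization ranges come from the calibration cohort min/max; a single
  outlier fly stretches the range and compresses everyone else. Median
  absolute deviation-based normalization would be more robust but would
  depart from the simple, auditable min–max contract persisted in the
  calibration JSON.
- Threshold mode transfers a fixed cut to new data and therefore inherits
  any systematic shift between calibration and application conditions;
  prior-count mode is immune to monotone score shifts but requires the
  group composition to be known exactly.
- The registry ships the two headline metrics plus the single-max variant;
  further ROI statistics can be added, but the calibration landscape is
  defined over exactly two metrics at a time.
- Identity is per-trajectory: if the tracker swaps two flies mid-video,
  both inherit whichever identity their merged trajectory earns.
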