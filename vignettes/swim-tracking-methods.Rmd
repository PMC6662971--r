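---
title: "Methods: swim tracking, curvature and segregation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swim tracking, curvature and segregation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and limitations of
swimtrackr. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement problem

Overhead videos of 2–3 adult fish in a home tank (the package is
calibrated around 1920×1080 at 24.96 frames/s) are reduced to two
per-fish numbers: mean instantaneous velocity and range of movement
(max − min of a per-frame body-curvature scalar), both over the 100
most-active frames of that fish. These are then compared between
genotype groups. Alongside, the package computes the organism-level
statistics such screens report: Mendelian segregation chi-squares,
genotype percentages, fish BMI (`w/L²`, g/cm²) and Fulton's condition
factor (`K = 100·w/L³`), and balanced two-way ANOVA with Sidak-adjusted
comparisons.

## Segmentation model and parameters

- **Greyscale conversion** uses optical densities,
  `OD = −log10(max(I, 1)/255)`, optionally unmixed against a stain
  matrix. Which deconvolution vectors suit a given tank/dye setup is
  user-specific, so the default stain matrix is the identity (per-channel
  OD) with channel 1; zeros are clamped to intensity 1 so OD stays
  finite. The rescale to [0, 255] uses one global range per video, not
  per frame: per-frame rescaling would make the background level drift
  with fish position and defeat median-projection subtraction.
- **Background**: per-pixel median over time. Valid whenever each pixel
  is fish-covered in under half the frames used — true for swimming
  fish, false for a fish asleep in one spot (a known limitation). For an
  even frame count the lower median is used so background values are
  observed grey levels. The pipeline feeds 50 evenly spaced frames to
  the projection by default (`background_frames`), a pure speed choice;
  the estimator is unchanged.
- **Intermodes threshold**: the 256-bin histogram of `|gray − bg|` is
  smoothed with a 3-bin moving mean (zero-padded ends) until exactly two
  strict local maxima remain; threshold = rounded midpoint of the modes;
  foreground is strictly above. If the mode count ever drops below two
  — unimodal or flat histograms, nothing moving — the threshold is
  undefined and the operation errors after at most 10,000 passes.
  `segment_frame()` propagates that error (its contract); the
  `track_swim_video()` wrapper converts it to an empty frame with a
  warning so one static frame cannot abort a video. The threshold is
  recomputed every frame.
- **Median filter** (radius 2 px default) is a strict-majority vote in
  the clipped square window; it removes speckle but also erodes sharp
  convex corners for a few passes before reaching a fixed point, which
  is why the test suite asserts idempotence on a disk and only
  convergence for a rectangle.
- **Size gate**: components outside [100, 50 000] px are dropped. The
  defaults assume an adult fish at the stated resolution (a 180×36 px
  body covers ≈ 5 600 px; at the 640×360 test scale a 60×12 px body
  covers ≈ 830 px). All parameters are exposed.

## Tracking

Linking minimises total Euclidean centroid separation per frame
transition with the Munkres (Hungarian) algorithm, implemented from
scratch (classic star/prime formulation, O(n³), padded to square).
Zero tests need no floating-point tolerance because every compared
value is produced by subtracting a minimum from itself. After solving,
pairs longer than `max_link_distance` (150 px default, scaled down for
small test frames) are dissolved — gating after a global solve keeps
the pairing optimal among admissible links. Unmatched detections spawn
tracks; unmatched tracks terminate immediately. There is deliberately
no gap closing, motion model or appearance model: the method is the
simplest faithful reading of centroid-cost linking, and the 50-frame
minimum-length filter (≈ 2 s) then removes the spurious fragments this
can produce. Two touching fish merge into one detection and both tracks
end; the remerged object starts a new track.

## Backbone curvature

Each detection's pixel set is thinned to a 1-px skeleton (Zhang–Suen).
The backbone is the longest endpoint-to-endpoint geodesic through the
skeleton's 8-adjacency graph (orthogonal edges weight 1, diagonal √2),
which drops side branches from fins or thinning artefacts. Components
`x(s)`, `y(s)` are then fitted against normalised cumulative chord
length.

Two deliberate numerical choices:

- **Regression B-splines, not penalised smoothing splines.** Penalised
  cubic smoothing splines carry natural boundary conditions (second
  derivative zero at the ends), which force the estimated curvature to
  zero exactly where the head and tail bend. Unpenalised cubic B-spline
  regression with evenly spaced interior knots leaves end curvature
  free; smoothness is controlled by basis size. The default basis size
  is ≈ n/10 (clamped to [5, 12]): at that resolution a 1-px skeleton
  staircase is averaged out while a single body bend (fish bodies bend
  at tail-beat wavelengths, not pixel wavelengths) is followed. For
  near-straight objects a smaller basis (e.g. 5) suppresses jitter
  curvature below 0.01 px⁻¹, which the tests exercise explicitly.
- **Per-frame curvature scalar = trimmed mean of signed samples.** The
  scalar is the mean of 100 signed curvature samples with the outer 5%
  of arc length excluded at each end (end effects dominate there).
  A signed mean makes the scalar oscillate in ±A during tail beats, so
  max − min captures the full bend amplitude 2A; an unsigned mean or a
  max would confound amplitude with posture. Curvature sign is only
  defined up to traversal direction, so orientation is made continuous
  in time: the head end of frame *t* is the end nearer the head end of
  frame *t − 1* (first frame arbitrary). A global sign flip per track
  is possible but cancels in max − min.

## Statistics

- `mendelian_chi2` uses the plain goodness-of-fit statistic without
  Yates correction, `df = classes − 1`, upper-tail p. Validation: for
  the printed worked example (observed [7, 131] against 1:15) it gives
  χ² = 0.3266, p = 0.5677; the study's printed "P = 0.567" equals the
  p-value of the 3-digit-rounded statistic (pchisq(0.327) = 0.5674), so
  the acceptance test asserts agreement within one unit of the last
  printed digit. For the combined-lethality example ([0, 104] vs 1:15)
  the statistic is 6.93 and p = 0.0085; the source text prints
  "χ² = 0.008", which matches the p-value, not the statistic — the
  function returns both so either reading is checkable.
- `two_way_anova` accepts balanced designs only (equal cell counts), so
  the type-I/II distinction vanishes and the decomposition is unique;
  it is backed by `stats::lm`/`anova` and validated in the tests
  against an explicit cell-means decomposition. With one observation
  per cell the interaction is inestimable and is dropped with a note.
  Unbalanced data error out rather than silently switching SS types.
- `sidak_adjust` is the exact `1 − (1 − p)^m`.

## The synthetic world

`simulate_swim()`/`render_video()` generate the only data the tests
use. Each fish is a filled capsule (width `body_width`, round caps)
whose midline is a **constant-curvature arc** of length `body_length`;
the arc's signed curvature follows `κ(t) = A·sin(2π·f·t + φ)`. A
constant-curvature midline makes the programmed per-frame curvature a
single unambiguous scalar, directly comparable to the pipeline's
frame-curvature output — a travelling body wave would not have that
property. The midline is centred on its own centroid before placement,
so body bending does not displace the blob centroid and programmed
speed stays the exact centroid ground truth. Fish advance `speed`
px/frame along a heading with Gaussian increments (`heading_sd`) and
reflect off the walls; initial positions must be ≥ 2 body lengths
apart.

Defaults are one stated world: full scale is 1920×1080 at 24.96 fps
with a 180×36 px body; the desk-scale tests use the 3×-reduced frame
(640×360, body 60×12, speed 5 px/frame, A = 0.015 px⁻¹ — curvature is
1/px so it scales inversely). Unstated quantities were fixed once at
values realistic for such recordings and are not tuned: background
grey 160 with static texture SD 8, fish 60 grey levels darker,
per-frame sensor noise SD 3, tail beat 2 Hz, heading SD 0.05 rad/frame.
Rendering is integer-quantised and losslessly round-trips through
binary PGM.

What a green end-to-end test establishes: segmentation, linking,
skeleton/spline curvature and the summary statistics jointly recover
programmed fish count, speed (within 5%), bend amplitude (within 15%)
and identity (zero swaps) under realistic noise. What it does not
establish: performance under reflections and shadows, touching or
occluding fish, non-uniform illumination, lens distortion, or fish
whose body wave deviates strongly from an arc — real-video behaviour
beyond the generator's scope.

## Frame I/O

Compressed containers are not decoded (no decoder dependency);
`read_frames()` reads lexicographically ordered directories of 8-bit
Netpbm images (PGM/PPM, ASCII or binary), which are lossless and
self-contained, and `write_frames()`/`write_pnm()` write them. Frame
directories carry no rate metadata, so `fps` is required there.

## Known limitations

- No occlusion handling: merged fish produce one detection and track
  breaks (by design; the length filter absorbs the fragments).
- `two_way_anova` refuses unbalanced designs instead of approximating.
- The per-frame curvature scalar is a signed mean; a fish bent into an
  S (equal and opposite bends) scores near zero — acceptable for
  range-of-movement of beat-swimming fish, not a posture descriptor.
- Background subtraction assumes a static camera and mostly-moving
  fish.
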