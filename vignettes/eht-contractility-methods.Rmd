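---
title: "Measuring EHT contractility from cantilever deflection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring EHT contractility from cantilever deflection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehtforce)
```

## The measurement model

An engineered heart tissue (EHT) on this class of platform spans two
cylindrical PDMS cantilevers, 3 mm long, each carrying a carbon-black-stained
disc at the tip. Under 1 Hz field pacing the tissue twitches and pulls the
posts toward each other. The only primary observable is the pair of dark
markers in a brightfield image stack; everything else is derived:

* **deflection** δ(t) = d₀ − d(t), where d(t) is the Euclidean distance
  between the two marker centroids (µm) and d₀ the relaxed baseline;
* **force** via small-deflection Euler–Bernoulli bending of a cylindrical
  cantilever loaded at the tissue height *a* above the base:
  F = 3πER⁴δ / (2a²(3L−a)), the inverse of the tip deflection
  δ = Fa²(3L−a)/(6EI) with second moment I = πR⁴/4;
* **kinetics** per twitch: amplitude, maximal rates of rise and decay, and
  times to 10%/90% of contraction and relaxation;
* **pharmacology**: absolute gains versus the 0 nM baseline (positive
  inotropy) and a descending Hill curve r(c) = 1/(1+(c/IC50)^h) for
  negative inotropy;
* **morphometry**: projected tissue area, compaction fractions, success
  rate, seeding dose.

### Assumptions of the force model

The beam equation assumes linear elasticity, small deflections (δ ≪ L), a
point load at height *a*, and a prismatic circular cross-section. Large
deflections, shear (Timoshenko) corrections, the stiffening effect of the
tip disc, and distributed tissue loading are all outside the model. δ is
the *total* change of the inter-marker distance — both posts bend — and it
is fed to the equation as printed; a `per_post_deflection` switch divides
it by two for users who prefer the symmetric-post convention, since the
community is not unanimous on which convention a given rig reports.

Because the marker sits at the post tip while the load acts at *a* < L, the
measured tip displacement and the displacement at the load height differ in
general; the equation used here is expressed directly in terms of the tip
deflection for a load at *a*, and no further correction is applied.

### Geometry parameters

| parameter | meaning | unit | default | note |
|---|---|---|---|---|
| `E_pa` | PDMS Young's modulus | Pa | 2.0e6 | typical Sylgard 184, 1:10 — **calibrate** |
| `R_m`  | post radius | m | 0.25e-3 | placeholder — **calibrate** |
| `L_m`  | post length | m | 3e-3 | platform design value |
| `a_m`  | tissue height on post | m | 1.5e-3 | placeholder — **calibrate** |

E, R and a are not knowable from the image alone: absolute forces are only
as good as the user's calibration of these three numbers. All internal
computation is strict SI; reporting units are µN and µN/s, the magnitudes
usual in the EHT literature. Negative forces (δ < 0) are reported rather
than clipped — they flag a mis-estimated baseline to the user.

## Marker detection and tracking

Detection is deliberately simple, because carbon-black markers are the
highest-contrast object in the field: invert the frame, threshold with
Otsu's method, label connected components, and filter on area and
circularity 4πA/P² ≥ 0.5. Centroids are intensity-weighted over the blob
grown by one pixel (to capture the anti-aliased rim) after subtracting the
background level of the inverted image, which makes them sub-pixel: on
noiseless synthetic discs the error is < 0.05 px, and < 0.5 px with 5%
sensor noise.

Frame-to-frame association keeps the two blobs nearest the previous pair
(first valid frame: the two largest, ties to the leftmost). Runs of up to
`max_gap = 5` frames (50 ms at 100 fps — shorter than any twitch phase at
1 Hz) without a valid pair are bridged by linear interpolation and flagged
in the output; longer runs abort with the offending frame range, because
silently inventing half a twitch is worse than failing.

The baseline distance d₀ is the *maximum* inter-marker distance over the
recording, not the first-frame distance: recordings routinely start
mid-twitch, and the relaxed state is the observable maximum. A config
override exists for platforms where the relaxed distance is known by
design. Note that with noisy centroids the maximum is biased slightly
upward; per-beat amplitudes are unaffected because the per-beat baseline is
re-estimated within each window, which is why amplitude recovery is tested
through the kinetics layer.

## Twitch segmentation and features

With a known pacing frequency, the largest peak per pacing period is kept
(ectopic extra peaks ignored, as is usual for paced recordings) and window
boundaries sit at the force minima between consecutive peaks. Without
pacing — these tissues retain an auto-pacing phenotype — peaks are accepted
by a prominence criterion (default 0.2 of the global amplitude). A window
only counts as complete if the force at both boundaries is back near
baseline (within 0.25 of the global amplitude); incomplete first/last beats
are discarded.

Per beat: baseline = mean of the first 10% of the window; amplitude = peak −
baseline; t10/t90 of contraction run from the upstroke onset (last baseline
crossing before the peak) to the crossings of baseline + 10%/90% of the
amplitude; relaxation times run from the peak sample to the 90%/10%
crossings on the decay — "10% relaxed" means crossing the 90% level. All
crossings are linearly interpolated between samples, so the features are
sub-frame accurate. Velocities are extrema of the Savitzky–Golay smoothed
derivative (window 11 samples, order 3 at 100 fps; both configurable) — the
filter is gentle enough that the peak derivative of a 1 Hz raised-cosine
twitch is attenuated by less than 0.1%.

Reference values for testing come from the raised-cosine twitch
F(t) = A/2(1 − cos 2πt/d): the 10→90% contraction interval is
(d/2π)(arccos(−0.8) − arccos(0.8)) ≈ 0.2952·d (0.1181 s at d = 0.4 s) and
the maximal slope is Aπ/d. These closed forms were confirmed against an
independent dense-grid oracle (10⁵ points) before being frozen into the
tests; the same dense-grid route generates ground truth for the asymmetric
two-phase shape.

## Dose–response analysis

The nifedipine protocol normalizes each tissue's amplitude to its own 0 nM
recording, and only then averages across tissues — the two orders differ
whenever tissues differ in absolute force, and the within-tissue pairing is
the one the dosing protocol actually controls. The Hill model is fitted
with top fixed at 1 and bottom at 0 (the response is baseline-normalized,
and saturating L-type calcium block abolishes contraction); on 5–7 point
series a free 4-parameter logistic is poorly identified, though a
`free_bottom` switch exists. Optimization is Levenberg–Marquardt over
(log₁₀ IC50, h) from 16 log-spaced IC50 starts spanning the tested range,
h seeded at 1; the 0-concentration anchor is excluded from the fit domain
(log 0 is undefined). Degenerate inputs (too few points, non-decreasing
responses) return a flagged failure rather than raising, so a plate-scale
batch keeps running. Fitting in log-concentration space makes the estimator
exactly scale-equivariant: rescaling concentrations rescales the IC50.

## Morphometry

Projected areas use the same Otsu/largest-component/hole-filling chain as
marker detection (the original workflow traced areas by hand; automation is
what makes the computation testable, and a user-supplied mask reproduces a
manual tracing exactly). Early-stage compaction is area(day 5)/11 mm² —
the seeding footprint — and late-stage compaction is area(day d)/area(day 5)
for d ∈ {11, 15, 20}; missing days give missing metrics, not errors.
Success is a manual annotation (homogeneous distribution around the posts,
no rupture at any timepoint): judging that from a single brightfield
snapshot is not something this package attempts. Success rates are reported
raw and rounded to integer percent, the platform's reporting style.

## The synthetic-fixture generators

Every test input is generated, with ground truth, by code:

* **twitch traces** — raised-cosine or asymmetric two-phase twitches, one
  per pacing period (defaults: 1 Hz, duty 0.4, 100 fps, 10 s — the
  acquisition conditions the package targets), optional seeded Gaussian
  noise. The first upstroke sits 0.3 periods into the trace, because
  acquisition is not synchronized with the stimulus and a recording opens
  mid-baseline.
* **marker videos** — two anti-aliased dark discs (4× supersampled
  coverage), each displaced toward the other by δ/2, on a light background;
  defaults mimic the platform scaled to the field of view (markers 100 px
  apart, 8 px radius discs standing in for the 1 mm tip disc). Noise models
  are additive Gaussian sensor noise and slow sinusoidal illumination
  drift, the two dominant brightfield artifacts. Frames are quantized to
  the 16-bit grid so a written TIFF round-trips bit-identically.
* **dose tables and silhouettes** — exact Hill responses and disk / ellipse
  / capsule shapes with closed-form areas.

All generators are pure functions of their parameters and seed. What they
do *not* emulate: tissue texture, post bending curvature in the image
(markers translate rigidly), marker deformation, focus drift, or beat-rate
variability. Passing the synthetic suite therefore demonstrates the
correctness of the algorithms under controlled imaging conditions, not
robustness to every artifact of live-cell microscopy; real recordings with
unusual illumination or debris may need the detection filters adjusted.

## Numerical choices and degenerate inputs

* Intensities are normalized to [0, 1] on load; grayscale conversion is an
  unweighted channel mean (the markers are near-black, channel weighting is
  immaterial). Frame rate and pixel size are explicit user inputs — TIFF
  metadata dialects are too unreliable to parse.
* Supported containers are multi-page TIFF for stacks and PNG/TIFF for
  snapshots.
* Frames whose intensity range is below `min_contrast = 0.1` yield no
  detections (blank-frame guard); a flat force trace raises a "no beats"
  error carrying the measured noise estimate rather than returning empty
  summaries.
* Coordinates are x-right/y-down with pixel centers at integer positions;
  sub-pixel centroids are continuous values in that frame.
* Tie-breaks: first-frame marker choice prefers larger area, then leftmost
  x; equal-cost pairings resolve to the first enumeration.
* `a = 0` or `a > L` fail geometry validation before any computation, as
  does a non-positive frame rate or pixel size.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations to run on a
single CPU in a few minutes: 20 rendered videos of 1000 frames (160×90 px)
for tracking recovery, 1000 randomized geometries for the beam oracle, 900
seeded replicates (3 IC50 × 3 h × 100) for noisy IC50 recovery, and dense
grids of 10³–10⁵ points for the kinetics closed forms. These sizes were
chosen to keep Monte-Carlo error well below the tolerances being checked.

## Known limitations

* Absolute force accuracy is bounded by the user's calibration of E, R and
  a; the package validates the transduction formula, not the constants.
* One marker pair per recording: analysing a three-tissue well means one
  run per ROI.
* No optical-flow or template tracker; heavily defocused or low-contrast
  markers will defeat the blob detector before the tracker sees them.
* Success/rupture classification is out of scope by design.
* AVI input is not supported; convert to multi-page TIFF upstream.
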