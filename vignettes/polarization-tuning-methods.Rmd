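---
title: "Methods: polarization-tuning analysis of stepped-polarizer calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarization-tuning analysis of stepped-polarizer calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poltune)
```

## The experiment this package models

A fly (or other insect) views a patch of linearly polarized UV light whose
angle of polarization (AoP) is set by a rotating polarizer. The polarizer
steps discontinuously — by default 30° every 4 s with 0.5 s transitions —
through at least two full device revolutions, so each of the six unique
AoPs (AoP is defined modulo 180°) is presented twice per revolution at
diametrically opposite device angles. Ten seconds of darkness precede and
follow each stimulus set; a control condition removes the polarizer while
keeping irradiance matched. Activity is recorded as volumetric two-photon
calcium imaging at ≥ 1 volume/s in two channels: an indicator channel
(activity-dependent) and a structural channel (activity-independent), the
latter used exclusively for motion registration.

All angles follow one convention: AoP in degrees on [−90°, +90°), defined
modulo 180°, seen from an external viewpoint toward the animal, 0° =
vertical.

## Pipeline overview

1. **Registration** (`register_volume`): per-frame rigid (x, y) shifts are
   estimated on the maximum-intensity projection of the structural channel
   by Fourier cross-correlation with subpixel refinement (local DFT
   upsampling, 1/20 px), against the time-average of that projection as
   reference. The identical shifts are applied to every plane of every
   channel. The reference choice makes the estimate robust to any single
   noisy frame; the cost is that corrections are expressed relative to the
   mean head position rather than to any particular frame, which is
   irrelevant downstream.
2. **Inactivity projection** (`inactivity_projection`): for each plane, the
   frames lying entirely inside inactivity windows are averaged; at each
   (x, y) the brightest plane *at rest* is selected, and that pixel's whole
   time series is taken from that single plane. This deliberately avoids
   biasing the projection toward neurons that are bright because they are
   driven, and guarantees each pixel's series has one fixed source plane.
   Frames only partially inside an inactivity window are excluded.
3. **Tuning** (`tuning_curve`, `preferred_aop`, `psi`, `pixel_tuning`):
   raw fluorescence is averaged over the non-transition samples of each
   device position, pooled per AoP, and summarized by the
   grouping-corrected axial mean resultant vector. PSI uses the first two
   presentations (in time) of the preferred and orthogonal AoPs.
4. **Regions and ROIs** (`region_partition`, `auto_rois`,
   `roi_timeseries`): the *neurons* region is the brightest 10% of pixels
   inside the hand-drawn overall ROI, the *background* the dimmest 10%
   outside it (decile sizes rounded up; ties broken by row-major scan
   order). Automatic ROIs discretize a thresholded tuning map into
   half-open 30°-wide bands around the presented angles and keep, per
   angle, the largest 8-connected component of at least 20 pixels.
5. **Population analyses** (`polarotopy_analysis`, `population_vector`,
   `polar_histogram`): circular–linear regression of doubled preferred
   angles on normalized anatomical position, pooled and per recording;
   PSI-weighted axial population vectors; area-true polar histograms.
6. **Protocerebral-bridge analyses** (`best_pairing`,
   `autocorr_peak_shift`, `cycle_tuning`, `g0_shift_analysis`): left/right
   glomerulus pairing by zero-lag cross-correlation over all eight wrapped
   schemes; phase-locking by the distance of the first autocorrelation
   peak from the stimulus period; cycle-by-cycle tuning with G0-referenced
   shift distributions.

## The synthetic-data generator

`simulate_response` models a polarization-tuned neuron as a sinusoidal
axial analyzer: during a hold at AoP θ the mean fluorescence is
B·(1 + A·cos 2(θ − φ)), with preferred angle φ, modulation depth A ∈ [0, 1]
and baseline B. With the polarizer removed the level is B·(1 + sA)
throughout light-on, s = −1 by default (suppression by unpolarized light).
During inactivity the level is B. Transitions ramp linearly between
neighboring hold levels. The level trace is convolved with a causal
single-exponential kernel (τ = 1 s by default) to mimic a slow calcium
indicator, then Gaussian noise is added and the result clipped at zero.

`render_volume` places Gaussian-footprint neurons (σ = radius/2, truncated
at 2.5σ) into a two-channel volume: the activity channel is background plus
footprint-scaled response traces sampled at each plane's own acquisition
times; the structural channel is the static footprints. Per-frame rigid
motion and voxel noise are applied identically where requested.
`make_pb_dataset` builds sixteen bridge glomerulus traces in which each
right-side trace duplicates its ground-truth left partner under one of the
eight wrapped pairing schemes.

**What the generator emulates:** the stepped stimulus timing (including
optional uniform hold jitter on [4, 4.5] s), sinusoidal axial tuning,
suppression under unpolarized light, indicator dynamics, rigid in-plane
motion, shot-like (Gaussian, zero-clipped) noise, and linear polarotopy
gradients with exact ground truth.

**What it does not emulate:** optics of the stimulus device (the ±5%
intensity ripple over a revolution, spectra), non-rigid or z-axis motion,
neuropil contamination, bleaching, correlated network noise, and any
biophysics of photoreceptors or indicators beyond a first-order kernel.
Passing tests therefore certify the *analysis* — that known tunings,
gradients and pairings are recovered under realistic noise — not that the
generator reproduces every property of in-vivo recordings.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `step_angle_deg` | 30 | deg | 12 positions, 6 unique AoPs per revolution; must divide 180 |
| `hold_s` / `transition_s` | 4 / 0.5 | s | protocol timing; only hold samples enter tuning averages |
| `n_revolutions` | 2 | — | two presentations per AoP per revolution; PSI uses the first two |
| `inactivity_s` | 10 | s | spontaneous-activity windows framing each stimulus set |
| `tau_s` | 1 | s | indicator decay; 0 disables the kernel |
| `upsample` (registration) | 20 | — | 1/20 px subpixel precision |
| PSI threshold | mean + 1 SD | — | sample SD (n − 1) of background PSIs; for bridge recordings, of polarizer-removed neuron PSIs |
| `min_px` (auto-ROIs) | 20 | px | minimum contiguous area |
| slope search | [−4, 4] | cycles/unit | more than ~2 axial cycles across one neuropil axis is anatomically implausible; ±4 leaves margin |
| `n_perm` | 10,000 | — | permutation floor p = 1/10001 |
| `n_boot` | 10,000 | — | hierarchical bootstrap replicates |

## Numerical and design choices

- **Degenerate tuning curves.** A flat curve has zero resultant; the
  preferred angle is reported as `NA` with `R = 0` and a `defined = FALSE`
  flag rather than an arbitrary angle.
- **Negative PSI** is reported as computed. The index's nominal range
  [0, 1] assumes the resultant angle maximizes the first-two-presentation
  mean; drift can violate that, and clamping would hide exactly the
  pathologies the polarizer-removed controls are designed to expose.
- **Nearest-angle ties** (preferred angle exactly between two presented
  AoPs) resolve to the AoP presented earlier; deterministic and logged in
  the selection.
- **SD convention**: sample SD (n − 1) everywhere a "+1 SD" threshold is
  computed.
- **Grouping correction** (δ/2)/sin(δ/2) is capped so R never exceeds 1.
- **Permutation test exchangeability**: the observed statistic compared
  against shuffles is recomputed with the identical grid-only slope search
  used for the shuffles (1601 points on [−4, 4]); the reported fit itself
  adds golden-section refinement. The grid is fine enough (0.005
  cycles/unit) that the difference is negligible, and using one statistic
  for both sides keeps the test exact.
- **Per-recording p-values** use the same permutation machinery (1000
  permutations by default) rather than a parametric approximation — one
  clearly seeded route instead of two.
- **Autocorrelation estimator**: per-lag Pearson correlation of the two
  lagged segments. The conventional biased estimator tapers the
  autocorrelation triangularly and a global demeaning of a non-integer
  number of periods adds an oscillatory cross term; both drag the first
  peak off the true period by up to a second at these window lengths.
  Verified against pure sinusoids of known period.
- **Hierarchical bootstrap**: flies are resampled with replacement, then
  each chosen fly's recordings; BCa acceleration comes from a
  delete-one-fly jackknife. Degenerate (all-identical) inputs collapse to
  a zero-width interval.
- **"Cycle"** in the bridge analyses means one 180° sweep (six consecutive
  positions, ≈ 27 s nominal), since tuned responses repeat with the AoP
  period, not the device period; a full-revolution option exists.
- **Connectivity** for "contiguous" areas is 8-connectivity, stated
  explicitly for reproducibility.
- **16-bit TIFF export** stores intensities scaled by each channel's
  maximum; the scale is recorded in the JSON sidecar, so round-trips are
  exact up to 1/65535 relative quantization.

## Problem sizes used in the tests

The simulation-based guarantees run on deliberately desk-scale problems:
64 × 64 × 2 volumes at 2 Hz with 20 neurons for the gradient-recovery
check (about 260 volumes over a 128 s protocol), 48 × 48 single-plane
volumes for the control nulls, 10,000 permutations on 20 pooled ROI
points, and oracle comparisons over 1000 random samples of up to 1000
angles. These sizes were chosen so the full suite runs in minutes while
every assertion still exercises the same code paths as full-size data.

## Known limitations

- Registration is rigid and in-plane only; z-drift and non-rigid motion
  are out of scope, matching the analysis it implements.
- The circular–linear fit assumes a single linear phase gradient; piecewise
  or curved polarotopies will depress ρ rather than fail loudly.
- The permutation and bootstrap routines are exact only conditional on
  their seeds; across-machine reproducibility relies on R's RNG stream
  (Mersenne-Twister, R ≥ 3.6 sample kind).
- The polarizer-removed control analysis labels device positions with the
  AoPs they *would* present, so its "tunings" are nominal by construction;
  only PSI magnitudes and ΔPSI are meaningful there.
- With fewer than two revolutions the "first two presentations" rule for
  PSI degenerates to the two device positions of a single revolution —
  supported, but estimates are noisier.
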