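---
title: "Models and methods behind lightmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lightmask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightmask)
```

This vignette is the package's own account of its models: what the
synthetic-data generators emulate, how the two analysis arms work, which
parameters matter, and where design decisions were genuinely open.

# The behavioral model

## What the generator emulates

The behavioral arm targets diel vertical migration of single larval
zebrafish in a 3.0 × 1.0 × 5.0 cm chamber, filmed at 5 fps over ten cycles
of 60 s light ON / 60 s light OFF. Depth is measured in cm from the water
surface downward, shared by every module (`chamberHeight()` = 5 cm; the
half-column mark used for occurrence rates is 2.5 cm).

`simulateTrajectories()` uses a first-order drift–diffusion model, the
simplest process that reproduces sawtooth-like climb/dive traces:

* At each epoch start a fish decides independently, with probability equal
  to its channel `responsiveness`, whether to respond during that epoch.
* Responders drift up (lit epochs) or down (dark epochs) at a speed drawn
  once per epoch from `N(climbSpeed, speedSd)` (resp. `diveSpeed`),
  truncated at zero. Dark epochs inherit the responsiveness of the adjacent
  lit epoch — diving in darkness is part of the masking response to the
  alternation, not a response to darkness itself, which is why the `dark`
  responsiveness is pinned at 0.
* Every 1/rate step adds diffusion noise `N(0, positionNoiseSd²·dt)` and
  the position is clipped to `[0, 5]` cm. Clipping (a sticky boundary)
  rather than reflection was chosen so that a determined climber rests at
  the surface instead of bouncing, which matches how larvae hold station at
  the top of the column.

Defaults — responsiveness 0.85 for blue/green, 0.30 for red, 0.25 for UV;
climb/dive speed 0.12 cm/s with SD 0.03; diffusion scale 0.15 cm·s^-1/2;
start depth uniform in [3.5, 5] cm (dark-adapted fish sit low) — were chosen
once so that a default blue group shows the qualitative structure of the
assay: most fish crossing the half column in most cycles (occurrence rates
in the 70–110 out of 120 range), median pairwise correlations around 0.5,
and initial 20 s speeds of roughly 0.1 cm/s. The published experiments do
not specify a per-fish response model, only aggregate counts; the Bernoulli
per-epoch response is the simplest mechanism that yields partial occurrence
rates.

What the generator does *not* emulate: horizontal position, body posture,
fluid mechanics, habituation or circadian drift across cycles, and any
camera model beyond a Gaussian blob plus Gaussian noise. Passing tests
therefore demonstrate correctness of the analysis chain, not realism of
larval kinematics.

## Tracking

`trackPositions()` mirrors threshold-based tracking of a bright,
IR-illuminated fish on a dark background: per frame, the largest
above-threshold connected component (largest-area rule, resolving
reflections) contributes an intensity-weighted sub-pixel centroid row, which
the linear calibration converts to cm. Frames with no component are filled
by linear interpolation up to 5 consecutive frames (1 s at 5 fps) and
flagged; longer gaps, or more than 20% missing overall, are hard errors —
such a video should be re-acquired, not patched. A `invert` flag handles
dark-fish-on-bright videos. On rendered videos with signal-to-noise ≥ 5 the
tracker recovers the planted trajectory with sub-pixel RMSE (the test suite
checks 10 seeded videos at SNR 10 and one at SNR 5).

## The statistical battery

* **Initial speed** is net displacement over the first 20 s of an epoch
  divided by 20 s, signed so the epoch-congruent direction is positive.
  "Initial speed" could also mean mean absolute frame-to-frame speed; net
  displacement was chosen because climb/dive speeds are displacement-based
  quantities and a jittering, non-migrating fish should score zero.
* **Occurrence** requires an actual crossing of the 2.5 cm mark in the
  epoch-congruent direction within the epoch; a fish already above the
  half-column at light onset does not count as having climbed to it.
* **Correlation sample.** Pairwise Pearson correlations are computed on the
  full concatenated recording without detrending, and group comparisons use
  the upper-triangle off-diagonal values (66 values for 12 fish, 276 for
  24).
* **Jennrich test.** Implemented exactly as the 1970 statistic (see the
  README for the formula), with `df = p(p−1)/2`. When applied to time
  series, the sample counts are numbers of time samples and temporal
  autocorrelation violates the independence assumption — the statistic is
  then anticonservative. This is documented rather than corrected, because
  the published analyses do the same; a `decimate` argument lets users thin
  the effective sample count. Under i.i.d. sampling the test is calibrated:
  the suite verifies mean χ² ≈ df and a ~5% rejection rate on 1000
  same-distribution replicates (p = 5, n = 500).
* **Mann–Whitney.** `U = min(Uₓ, U_y)` with midrank ties; exact p from the
  null U distribution for tie-free samples with `n1+n2 ≤ 20` (verified
  against brute-force enumeration over all labelings), otherwise normal
  approximation with tie and continuity corrections. The rank-biserial
  correlation `|1 − 2U/(n1 n2)|` is reported as a magnitude, matching how
  printed values treat sign-negative cases.
* **Bonferroni** divides α by the stated hypothesis count only (no FDR);
  **Shapiro–Wilk** is included to justify the nonparametric battery;
  **photon intensity** uses CODATA constants, and direct evaluation of the
  three matched wavelength/power pairs gives 1.53–1.55 × 10¹⁵ cm⁻²s⁻¹
  (published roundings of such values sit ~1.5% higher).

# The imaging model

## The calcium-movie generator

`simulateCalciumMovie()` renders a single-plane T × Y × X movie over a
randomized schedule of 60 s blue/red pulses alternating with 60 s darkness.
Each planted source is a Gaussian footprint (support truncated at 5% of
peak) with one of five temporal classes: sustained blue, sustained red,
transient at every light onset, transient at every light offset, and
transient at blue offset only. The unit response is the class's driving
signal — a 0/1 square over the relevant epochs, or a unit impulse train at
the relevant edges — convolved with a single-exponential rise/decay
indicator kernel (defaults τ_r = 0.1 s, τ_d = 0.7 s, GCaMP6f-like; the
experiments give no kinetics).

Two numerical choices matter:

* **Frame-integrated kernel.** The kernel taps integrate h(t) over each
  frame interval rather than point-sampling it. A camera integrates over
  the exposure, and at a 1 Hz frame rate point-sampling would place a
  transient's peak one frame after its event, misaligning responses with
  their stimulus-locked templates.
* **Frame rate 1 Hz.** Whole-brain volumetric acquisition at 7.1 Hz over 10
  planes gives ~0.7 Hz per plane; the simulator treats planes as
  independent single-plane movies and uses 1 Hz as a convenient per-plane
  rate.

The default imaging run uses 10 colored pulses (5 blue, 5 red) on a
28 × 40 px field with source amplitude 1, noise SD 0.1 (SNR 10) and ±2 px
per-fish positional jitter. These sizes were set so that the weakest class
(blue-offset, with only ~5 events per recording) carries clearly more
energy than the largest noise eigenvalue of the pixel covariance — at these
dimensions roughly a factor of two above the Marchenko–Pastur edge — while
a 7-fish, 20-seed end-to-end suite still runs in minutes. Gaussian pixel
noise is the only noise source: no photon shot noise, motion, bleaching or
neuropil contamination, so end-to-end recovery results bound what the
pipeline can do on ideal data, not on real recordings.

## PCA → ICA

`pcaReduce()` factors the mean-subtracted pixel–time matrix through the
smaller Gram matrix and fixes component signs by positive skewness of the
spatial loading. `spatialICA()` rotates the whitened components by a
fixed-point iteration that maximises skewness — calcium signals are
positively skewed, so the third moment is the natural contrast — of the
µ-weighted concatenation of spatial and temporal views (µ = 0, the default,
is purely spatial ICA; the spatiotemporal weighting of the original
experiments is unstated). Symmetric decorrelation keeps the rotation
orthogonal; the identity initialisation makes results deterministic, with
an optional seeded random start. Components are ordered by decreasing
temporal skewness and sign-oriented to positive temporal skewness.
Non-convergence within `maxIter` returns the best iterate, flagged and with
a warning.

Defaults: `k = 30` retained PCs and as many ICA components (no counts are
published; tests and the default pipeline use `k = 10` because the
synthetic movies contain five sources). ROI segmentation thresholds each
map at mean + 2 SD and keeps connected components of ≥ 10 px, first-come
(higher-skewness components claim overlapping pixels). ROI traces are
spatial means z-scored over the recording.

## Templates and cross-animal integration

`buildTemplates()` derives the five templates from the fish's own schedule:
squares for sustained blue/red responses, exponential-decay sawtooths
(jump to 1 at the event, decay with constant τ) for the transients. The
waveform kind is fixed; its decay constant is not published, so it is a
parameter. The default is **τ = 2 s**: a transient calcium response decays
with the indicator (~0.7 s), and a closed-form overlap calculation shows
that correlating such a transient against a τ = 10 s sawtooth yields
r ≈ 0.5 — exactly at the classification threshold — whereas τ of a few
indicator time constants yields r ≈ 0.9 with clean margins between the
mixed and blue-only transient categories. Classification takes the maximum
Pearson correlation over available templates and assigns the category iff
it exceeds 0.5 (the published, empirically chosen threshold), ties broken
in fixed key order.

`registerAndAverage()` aligns each fish's classified map to the reference
fish by the integer translation maximising the dot product on the overlap
(searched exhaustively up to a quarter of the field), then averages
per-pixel over contributing fish. Translation-only registration is
deliberate; no rotation, scaling or nonrigid warp, and averages are
unweighted (no published weighting rule). Anatomical labelling of the
averaged maps is out of scope.

# Reproducibility and problem sizes

Every generator consumes an explicit integer seed through an isolated RNG
stream (the caller's `.Random.seed` is untouched), and the pipeline
functions derive per-fish seeds from the config seed, so reruns are
byte-identical. The test suite sizes were chosen to keep the full run in a
few minutes: 1000 replicates for the Jennrich null calibration (p = 5,
n = 500), 100 seeds each for the power and type-I checks of the behavior
battery (12 fish, 10 cycles, 5 fps), 20 seeds × 7 fish for end-to-end
imaging class recovery, and 10 seeded videos for tracker RMSE.

# Known limitations

* The drift–diffusion fish and the Gaussian-blob camera are deliberately
  minimal; parameters map to figure-level phenomenology, not to measured
  larval kinematics.
* The Jennrich test on time series inherits the anticonservatism discussed
  above.
* ICA with a skewness contrast assumes positively skewed sources; it will
  not separate symmetric or negatively skewed signals (flip the sign
  convention for inhibitory-dominant data).
* The imaging simulation is single-plane; volumetric acquisitions are
  treated as independent planes, and no cross-plane (3-D) registration is
  attempted.
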