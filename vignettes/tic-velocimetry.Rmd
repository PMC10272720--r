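---
title: "Time-intensity-curve velocimetry for stented arteries"
author: "AngioTIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-intensity-curve velocimetry for stented arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AngioTIC)
```

## The measurement problem

After a stent is placed in an artery, the vessel dilates and the blood-flow
velocity typically drops.  Whether a stent design (for example a helical
centerline stent that imposes a swirling flow, versus a conventional
straight stent) preserves more of the pre-stent velocity is a hemodynamic
question that digital subtraction angiography (DSA) can answer without any
extra instrumentation: the contrast bolus that is injected anyway is a flow
tracer.

The time-intensity-curve (TIC) method turns a DSA cine loop into a velocity
estimate.  Contrast medium attenuates X-rays, so in a DSA frame the lumen
darkens while the bolus passes: the mean intensity inside a small region of
interest (ROI) dips once per cardiac cycle.  If two ROIs are placed on the
same vessel, the dip train at the downstream ROI is a delayed copy of the
dip train at the upstream ROI, and the delay divided into the
along-vessel distance is the transport velocity.

For each matched peak $k$,

$$v_k \;=\; \frac{\Delta x\,[\mathrm{px}]}{\Delta t_k\,[\mathrm{frames}]}
\times \text{resolution}\,[\mathrm{mm/px}] \times
\text{fps}\,[\mathrm{frame/s}],$$

where $\Delta x$ is measured **along the vessel centerline** (not the
chord) and $\Delta t_k$ is the frame shift of the $k$-th contrast peak.
The per-peak velocities are averaged; the spread over peaks is reported as
a population SD (a single usable peak reports SD $0$).  The effect of the
stent is summarised by the velocity retention ratio

$$\text{retention}\,[\%] \;=\;
100 \times \frac{\bar v_\text{after}}{\bar v_\text{before}},$$

and the geometric effect by the per-site diameter expansion
$100\,(d_\text{after}-d_\text{before})/d_\text{before}$.

## Pipeline stages and their parameters

`runCase()` chains the stages below on a before and an after sequence with
identical settings; every threshold lives in `angioConfig()` and is
embedded in the emitted report.

**Segmentation** (`extractVesselMask`).  The vessel is whatever the bolus
darkened: the per-pixel temporal range (max $-$ min over frames, the
default) or a background-minus-minimum-projection statistic is thresholded
at a fraction (default 0.5) of its image-wide maximum, and the largest
connected component is kept.  A sequence without intensity change has no
vessel and is an error.

**Centerline** (`extractCenterline`).  The mask is thinned to a one-pixel
skeleton (Zhang–Suen), the skeleton is pruned to its longest
endpoint-to-endpoint geodesic (side-branch spurs drop out; a closed-loop
skeleton is an error because it has no endpoints), and points are ordered
from the inflow end — by default the end nearer the left image border,
configurable, because nothing else disambiguates flow direction in a
single projection.  The row and column series are then smoothed with a
Savitzky–Golay filter (window 21 points, order 3 by default): the window
suppresses the pixel-lattice staircase that would otherwise inflate the
arc length, while the cubic order avoids shortcutting genuine curvature.
Arc length is accumulated along the smoothed polyline.  Coordinates are
1-based `(row, col)` with pixel centers at integers, the native R
convention.

**ROI placement** (`placeRois`).  ROIs are 20 × 20 px boxes.  In practice
the proximal ROI is chosen where cardiac-motion noise has died down but
the TIC peak is clear, and the distal ROI where the peak is about to fade;
the `auto` strategy mimics that: it scans candidates every 10 px of arc,
computes each candidate's best contrast-peak prominence, and takes the
first position exceeding 50% of the best prominence (proximal) and the
last position still above 20% (distal).  Manual index placement is
available and is what a careful operator would use.

**TIC and peaks** (`computeTic`, `detectPeaks`).  The TIC is the plain
area mean per frame — no temporal filtering.  Contrast peaks are relative
minima of the TIC; internally the curve is inverted so "peak" means
maximum contrast concentration.  A peak must be a window maximum within
`order` frames (default `round(fps/10)`, i.e. 2–3 frames) and have
topographic prominence of at least 5% of the TIC dynamic range; both are
tunable.  An `excludeFirst` flag drops the first detected peak, mirroring
the case-by-case judgement that a first pulsation whose distal intensity
change is too small is unusable.

**Velocity** (`estimateVelocity`).  Peaks are matched ordinally (the
$k$-th proximal to the $k$-th distal peak, truncated to the shorter list):
pulsation peaks are periodic and ordered, so a 1–1 ordered pairing is the
only rule consistent with per-peak subtraction.  A non-positive frame
shift is an error, not a value — it means the ROIs are too close to
resolve a delay.  $\Delta t$ is an integer frame count by default;
parabolic sub-frame refinement exists behind `refine_subframe` but is off,
because frame counting is the method's native granularity.

**Diameter** (`measureDiameter`).  The width is read as the full width at
half the contrast depth (FWHM) of the intensity profile perpendicular to
the centerline — the standard angiographic convention, and the one that is
exactly testable on phantoms.  The profile is taken on the frame of
strongest *local* contrast (the frame minimizing a 21 × 21 px mean at the
site): with a pulsatile bolus, a whole-vessel criterion can select a frame
on which no pulse is crossing the measurement site.  Before/after site
matching is by arc fraction (defaults 0.15 and 0.5 for "proximal" and
"middle"); this is a documented repo convention, since nothing in a 2D
projection identifies "the same" site exactly.

## The synthetic phantom

No in-vivo sequences are distributed, so validation runs on a synthetic
phantom (`phantomConfig()`, `generatePhantom()`) that emulates exactly the
statistical structure the analysis relies on:

* a straight or sinusoidal vessel path (the 2D projection of a helically
  deformed artery — the analysis only ever sees projections);
* a train of Gaussian concentration pulses in arc length, advected at a
  known velocity `v/(resolution × fps)` px/frame — Gaussian because the
  method needs nothing more than a smooth single-extremum pulse;
* mass-conserving dispersion: the pulse width grows by a configured rate
  per frame while the amplitude decays as $\sigma_0/\sigma(t)$, so a
  dispersing bolus genuinely fades downstream (this is what lets the
  auto-placed distal ROI "run out of peak");
* a soft one-pixel lumen edge, so the FWHM of a cross profile equals the
  configured diameter;
* additive, seeded Gaussian noise.

Defaults mirror routine carotid C-arm acquisition: 1024 × 1024 detector,
0.2 mm/px (within the 0.109–0.249 range of typical systems), 30 fps
(15 also used), a 6 mm vessel (radius 15 px), a 300 mm/s bolus (carotid
pre-stent velocities span roughly 250–450 mm/s), pulses every 0.6 s
(≈100 beats/min under anesthesia), and noise at 1% of the contrast depth.
The initial pulse width (default 40 px) must stay comfortably above the
per-frame displacement, otherwise arc positions between two consecutive
pulse-center samples never see full contrast; tests that sweep velocity
scale it as `0.7 × v/(resolution × fps)`.

Every phantom ships a `PhantomTruth`: the exact centerline, arc length,
rasterized tube and, per pulse and arc position, the frame of maximal
concentration *on the discrete frame grid* — the right reference for an
estimator that can never see between frames.  `generatePairedCase()`
produces before/after pairs sharing a path with scaled radii and a scaled
velocity, the ground-truth analogue of a stented case.

What the phantom deliberately does not model: X-ray projection physics,
swirling-flow fields, vessel-wall motion, cardiac-motion artifacts, and
the foreshortening of a truly 3D helix.  Passing the recovery tests
therefore demonstrates that the *estimator* is correct and
quantization-limited, not that segmentation or peak detection would
survive every clinical artifact.

## Numerical behaviour and verification design

The dominant error source is frame quantization: $\Delta t$ is an integer,
so a single peak pair constrains the velocity only to
$[\Delta x\,\mathrm{fps}/(\Delta t + \tfrac12),\;
  \Delta x\,\mathrm{fps}/(\Delta t - \tfrac12)]$,
a relative half-width of about $1/(2\Delta t)$.  Halving the frame rate
halves $\Delta t$ and doubles the band.  The recovery tests assert exactly
this: across velocities 100–500 mm/s at 15 and 30 fps (ROI separations
chosen so $\Delta t \ge 5$), the noiseless estimate must bracket the truth
within the band at every grid point, and with noise at 5% of the contrast
depth at least 90% of seeded runs must stay in band.  Recovery fixtures
place ROIs so that the true inter-ROI transit is a whole number of frames;
on a half-frame boundary the rounding of two independently quantized peak
times is unstable by construction, which is a property of frame
quantization, not of an implementation.

Independent oracles used by the test-suite: a brute-force
cross-correlation over all integer lags (must equal the peak shift for
non-dispersing single pulses), a hand-written Dijkstra over skeleton
pixels (must reproduce the longest-geodesic pruning), closed-form arc
lengths (quarter circle), brute-force rasterized tube widths (FWHM
check), and pydicom as a third-party reader of the DICOM writer's output.
Worked-example checks recompute every published retention ratio (six) and
expansion rate (twelve) from the printed before/after measurements, and
the straight-arm mean velocity (327 mm/s after integer rounding).

Problem sizes in the tests and the acceptance script are chosen for
sub-second phantom generation (images of 48–160 rows and up to ~1200
columns, 30–90 frames); the estimator's quantization behaviour is
independent of image size once $\Delta t$ is fixed.

## Known limitations

* $\Delta t$ resolution: one or two frames often carry a whole
  measurement; higher frame rates are the only real cure.
* Ordinal peak matching assumes no peak is missed between the two ROIs;
  the mismatch error is deliberately fatal rather than self-healing.
* FWHM diameters on dispersed, shallow profiles bias slightly narrow.
* Site matching between before/after acquisitions is by arc fraction; no
  registration is attempted.
* The DICOM layer covers uncompressed little-endian multi-frame (and
  single-frame series) objects only — the format's compressed transfer
  syntaxes are out of scope.

## A worked phantom example

```{r example}
cfg <- phantomConfig(shape = c(96L, 420L), vesselRadiusPx = 8,
                     bolusVelocity = 300, fps = 30, resolution = 0.2,
                     nPulses = 3L, pulsePeriodS = 0.4, sigma0Px = 40,
                     noiseSd = 0, pathMarginPx = 50)
ph <- generatePhantom(cfg)
mask <- extractVesselMask(ph$sequence)
cl <- extractCenterline(mask)
rois <- placeRois(cl, ph$sequence)
dx <- arcDistance(cl, rois$proximal@centerIndex, rois$distal@centerIndex,
                  resolution(ph$sequence))
estimateVelocity(computeTic(ph$sequence, rois$proximal),
                 computeTic(ph$sequence, rois$distal), dx)
```

The estimate differs from the configured 300 mm/s by no more than the
frame-quantization band around the measured mean frame shift.
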