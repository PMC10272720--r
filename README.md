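# AngioTIC

Time-intensity-curve (TIC) velocimetry for angiographic cine sequences, in
R.  The package estimates blood-flow velocity before and after arterial
stenting directly from digital subtraction angiography (DSA) loops — no
Doppler probe, no CFD — and quantifies the stent's geometric effect on the
vessel.  It is written for researchers analysing pre/post-stenting
angiography (e.g. comparing helical-centerline and straight stents) and
for anyone who needs a tested, reproducible bolus-transit velocimetry
pipeline with a ground-truth phantom generator.

## The method

Contrast medium darkens the lumen, so the mean intensity of a small
region of interest (ROI) on the vessel dips each time a contrast pulse
passes.  With a proximal and a distal ROI on the same vessel, each matched
pair of contrast peaks gives a velocity

```
v_k [mm/s] = Δx / Δt_k × resolution [mm/px] × fps [frame/s]
```

where `Δx` is the ROI separation in pixels **along the vessel
centerline** and `Δt_k` the frame shift of the k-th peak.  Per-peak
velocities are averaged (mean ± population SD), and the stent effect is
summarised as

```
retention [%] = 100 × mean_velocity(after) / mean_velocity(before)
expansion [%] = 100 × (diameter_after − diameter_before) / diameter_before
```

with diameters read as the full width at half the contrast depth (FWHM)
of a profile perpendicular to the centerline.

The pipeline: read DICOM/image stack → segment the vessel from temporal
intensity changes → thin to a one-pixel centerline (Zhang–Suen), prune to
the longest endpoint-to-endpoint geodesic, Savitzky–Golay smooth → place
20 × 20 px ROIs (automatically or manually) → area-averaged TICs →
relative-minima peak detection with prominence filtering → ordinal peak
matching and the velocity formula above.

A synthetic phantom module (`phantomConfig()`, `generatePhantom()`,
`generatePairedCase()`) renders a contrast bolus advected at a known
velocity along a straight or sinusoidal (projected-helix) vessel, with a
pulsatile peak train, mass-conserving dispersion and seeded noise, and
emits exact ground truth for parameter-recovery testing.

## Worked example

```r
library(AngioTIC)

cfg <- phantomConfig(shape = c(96L, 420L), vesselRadiusPx = 8,
                     bolusVelocity = 300, fps = 30, resolution = 0.2,
                     nPulses = 3L, pulsePeriodS = 0.4, sigma0Px = 40,
                     noiseSd = 0, pathMarginPx = 50)
ph   <- generatePhantom(cfg)          # sequence + ground truth
mask <- extractVesselMask(ph$sequence)
cl   <- extractCenterline(mask)
rois <- placeRois(cl, ph$sequence)    # auto proximal/distal placement
dx   <- arcDistance(cl, rois$proximal@centerIndex,
                    rois$distal@centerIndex, resolution(ph$sequence))
estimateVelocity(computeTic(ph$sequence, rois$proximal),
                 computeTic(ph$sequence, rois$distal), dx)
#> VelocityEstimate: 310.0 +/- 0.0 mm/s over 3 peak(s), dx = 62.00 mm
#>   per-peak dt (frames): 6, 6, 6
```

The configured truth is 300 mm/s; the estimate of 310 mm/s sits inside
the frame-quantization band `[dx·fps/6.5, dx·fps/5.5] = [286, 338]` that
an integer 6-frame shift implies — the method's native uncertainty.

For a full before/after case:

```r
pair <- generatePairedCase(cfg, expansionFactor = c(1.2, 1.4),
                           velocityFactor = 0.7)
report <- runCase(pair$before$sequence, pair$after$sequence,
                  caseId = "demo", vessel = "helical")
report           # velocities, retention %, per-site diameters/expansion
```

`runCase()`/`runBatch()` write JSON reports, CSV summaries and
intermediate artifacts (mask PNG, centerline CSV, TIC CSVs); a thin CLI
lives at `inst/scripts/angiotic.R` with `phantom`, `run-case` and
`run-batch` subcommands.

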