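#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("frames", "AngioSequence", function(object) object@frames)

#' @rdname accessors
setMethod("fps", "AngioSequence", function(object) object@fps)

#' @rdname accessors
setMethod("fps", "TimeIntensityCurve", function(object) object@fps)

#' @rdname accessors
setMethod("resolution", "AngioSequence", function(object) object@resolution)

#' @rdname accessors
setMethod("frameCount", "AngioSequence",
          function(object) dim(object@frames)[3L])

#' @rdname accessors
setMethod("frameDim", "AngioSequence",
          function(object) dim(object@frames)[1:2])

#' @rdname accessors
setMethod("maskMatrix", "VesselMask", function(object) object@mask)

#' @rdname accessors
setMethod("maskMatrix", "PhantomTruth", function(object) object@vesselMask)

#' @rdname accessors
setMethod("centerlinePoints", "Centerline", function(object) object@points)

#' @rdname accessors
setMethod("centerlinePoints", "PhantomTruth",
          function(object) object@centerlinePoints)

#' @rdname accessors
setMethod("cumulativeArcPx", "Centerline", function(object) object@cumArcPx)

#' @rdname accessors
setMethod("cumulativeArcPx", "PhantomTruth", function(object) object@cumArcPx)

#' @rdname accessors
setMethod("ticValues", "TimeIntensityCurve", function(object) object@values)

#' @rdname accessors
setMethod("peakFrames", "PeakSet", function(object) object@peakFrames)

#' @rdname accessors
setMethod("perPeakVelocities", "VelocityEstimate",
          function(object) object@perPeakVelocities)

#' @rdname accessors
setMethod("meanVelocity", "VelocityEstimate",
          function(object) object@meanVelocity)

#' @rdname accessors
setMethod("sdVelocity", "VelocityEstimate",
          function(object) object@sdVelocity)

#' @rdname accessors
setMethod("diameterMm", "DiameterMeasurement",
          function(object) object@diameterMm)

#' @rdname accessors
setMethod("retentionPct", "CaseReport", function(object) object@retentionPct)

setMethod("show", "AngioSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("AngioSequence: %d frames of %d x %d px, %g fps, %g mm/px\n",
              d[3L], d[1L], d[2L], object@fps, object@resolution))
  cat(sprintf("  intensity range [%g, %g] (contrast lowers intensity)\n",
              min(object@frames), max(object@frames)))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d x %d px, %d foreground px (frames %d..%d)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@sourceFrameRange[1L], object@sourceFrameRange[2L]))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, arc length %.1f px\n",
              nrow(object@points), max(object@cumArcPx)))
})

setMethod("show", "TimeIntensityCurve", function(object) {
  cat(sprintf(
    "TimeIntensityCurve: %d frames at %g fps, intensity [%.1f, %.1f]\n",
    length(object@values), object@fps, min(object@values),
    max(object@values)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d contrast peaks at frames %s%s\n",
              length(object@peakFrames),
              paste(object@peakFrames, collapse = ", "),
              if (object@excludedFirst) " (first peak excluded)" else ""))
})

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf(
    "VelocityEstimate: %.1f +/- %.1f mm/s over %d peak(s), dx = %.2f mm\n",
    object@meanVelocity, object@sdVelocity,
    length(object@perPeakVelocities), object@dxMm))
  cat(sprintf("  per-peak dt (frames): %s\n",
              paste(format(object@perPeakDtFrames), collapse = ", ")))
})

setMethod("show", "DiameterMeasurement", function(object) {
  cat(sprintf("DiameterMeasurement: %s site (arc %.2f): %.3f mm [%s]\n",
              object@site, object@arcFraction, object@diameterMm,
              object@method))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d x %d px, %g fps, %g mm/px, %s path\n",
    object@shape[1L], object@shape[2L], object@fps, object@resolution,
    object@pathKind))
  cat(sprintf(
    "  bolus %g mm/s, %d pulse(s) every %g s, radius %s px, noise sd %g\n",
    object@bolusVelocity, object@nPulses, object@pulsePeriodS,
    paste(object@vesselRadiusPx, collapse = "/"), object@noiseSd))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %g mm/s along %.1f mm (%d centerline points, %d pulse(s))\n",
    object@bolusVelocity, object@arcLengthMm,
    nrow(object@centerlinePoints), nrow(object@peakPassTimes)))
})

setMethod("show", "CaseReport", function(object) {
  cat(sprintf("CaseReport %s (%s)\n", object@caseId, object@vessel))
  cat(sprintf("  velocity before: %.1f +/- %.1f mm/s\n",
              object@before@meanVelocity, object@before@sdVelocity))
  cat(sprintf("  velocity after:  %.1f +/- %.1f mm/s\n",
              object@after@meanVelocity, object@after@sdVelocity))
  cat(sprintf("  retention: %.1f %%\n", object@retentionPct))
  if (nrow(object@diameters)) {
    for (i in seq_len(nrow(object@diameters))) {
      d <- object@diameters[i, ]
      cat(sprintf("  %s diameter: %.3f -> %.3f mm (expansion %.1f %%)\n",
                  d$site, d$before_mm, d$after_mm, d$expansion_pct))
    }
  }
})
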