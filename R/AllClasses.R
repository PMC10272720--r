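#' @import methods
NULL

#' AngioSequence: an angiographic cine sequence
#'
#' Container for an ordered stack of 2D grayscale angiography frames together
#' with the acquisition metadata the velocimetry needs: the frame rate
#' (frames per second) and the spatial resolution (mm per pixel).
#'
#' Frames are stored as a 3D array indexed \code{[row, col, frame]}, in the
#' native (typically integer) grayscale units of the source.  The intensity
#' convention is fixed throughout the package: arriving contrast medium
#' \emph{decreases} intensity, so contrast "peaks" are intensity minima.
#'
#' @slot frames 3D numeric array, \code{dim = c(rows, cols, frame_count)}.
#' @slot fps frame rate in frames per second (> 0).
#' @slot resolution spatial resolution in mm/pixel (> 0).
#'
#' @seealso [readSequence()], [writeSequence()], [generatePhantom()]
#' @export
setClass("AngioSequence",
  representation(frames = "array", fps = "numeric", resolution = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
      return("frames must be a 3D array [row, col, frame]")
    if (d[3L] < 2L)
      return("frame_count must be >= 2")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      return("fps must be a single positive number")
    if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
        object@resolution <= 0)
      return("resolution must be a single positive number (mm/px)")
    TRUE
  }
)

#' Construct an AngioSequence
#'
#' @param frames 3D array \code{[row, col, frame]} of grayscale intensities.
#' @param fps frame rate (frames/s).
#' @param resolution spatial resolution (mm/px).
#' @return An [AngioSequence-class] object.
#' @examples
#' seq <- AngioSequence(array(100, dim = c(8, 8, 3)), fps = 30, resolution = 0.2)
#' frameCount(seq)
#' @export
AngioSequence <- function(frames, fps, resolution) {
  new("AngioSequence", frames = frames, fps = as.numeric(fps),
      resolution = as.numeric(resolution))
}

#' VesselMask: binary vessel segmentation
#'
#' @slot mask logical matrix, TRUE on the vessel lumen.
#' @slot sourceFrameRange integer range of frames used to build the mask.
#' @export
setClass("VesselMask",
  representation(mask = "matrix", sourceFrameRange = "integer"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask has no foreground")
    TRUE
  }
)

#' Centerline: ordered vessel centerline with arc length
#'
#' Ordered path of centerline points from the inflow (proximal) end to the
#' outflow end.  \code{points} holds the smoothed sub-pixel coordinates;
#' \code{rawPoints} the one-pixel-connected skeleton path they derive from.
#' \code{cumArcPx} is the cumulative polyline arc length in pixels, starting
#' at 0 and strictly increasing; arc-length differences between two indices
#' times the image resolution give the along-vessel distance used as the
#' velocimetry numerator.
#'
#' @slot points n x 2 numeric matrix of smoothed (row, col) coordinates.
#' @slot rawPoints n x 2 numeric matrix of raw skeleton (row, col) pixels.
#' @slot cumArcPx cumulative arc length (px) per point, first entry 0.
#' @export
setClass("Centerline",
  representation(points = "matrix", rawPoints = "matrix",
                 cumArcPx = "numeric"),
  validity = function(object) {
    n <- nrow(object@points)
    if (n < 2L) return("centerline needs at least 2 points")
    if (ncol(object@points) != 2L) return("points must be n x 2 (row, col)")
    if (length(object@cumArcPx) != n)
      return("cumArcPx length must match points")
    if (object@cumArcPx[1L] != 0) return("cumArcPx must start at 0")
    if (any(diff(object@cumArcPx) <= 0))
      return("cumArcPx must be strictly increasing")
    TRUE
  }
)

#' Build a Centerline from an ordered point matrix
#'
#' Utility constructor for synthetic or externally supplied centerlines; the
#' cumulative arc length is computed from the polyline.  Duplicate
#' consecutive points are dropped.
#'
#' @param points n x 2 matrix of ordered (row, col) coordinates.
#' @param rawPoints optional raw (pre-smoothing) points; defaults to `points`.
#' @return A [Centerline-class] object.
#' @export
centerlineFromPoints <- function(points, rawPoints = points) {
  points <- as.matrix(points)
  step <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                        points[-nrow(points), , drop = FALSE])^2))
  keep <- c(TRUE, step > 0)
  points <- points[keep, , drop = FALSE]
  arc <- c(0, cumsum(step[step > 0]))
  new("Centerline", points = points,
      rawPoints = as.matrix(rawPoints), cumArcPx = arc)
}

#' ROI: a square region of interest on the image grid
#'
#' @slot centerIndex index of the centerline point the ROI is centered on.
#' @slot halfSizePx half of the ROI edge length in pixels (edge = 2 * half).
#' @slot bounds integer vector (rmin, rmax, cmin, cmax), inclusive pixel box.
#' @export
setClass("ROI",
  representation(centerIndex = "integer", halfSizePx = "integer",
                 bounds = "integer"),
  validity = function(object) {
    b <- object@bounds
    if (length(b) != 4L) return("bounds must be (rmin, rmax, cmin, cmax)")
    if (b[2L] < b[1L] || b[4L] < b[3L]) return("degenerate ROI bounds")
    TRUE
  }
)

#' TimeIntensityCurve: per-frame area-averaged ROI intensity
#'
#' @slot values numeric vector, one mean intensity per frame.
#' @slot fps frame rate of the source sequence (frames/s).
#' @slot roi the source [ROI-class].
#' @export
setClass("TimeIntensityCurve",
  representation(values = "numeric", fps = "numeric", roi = "ROI"),
  validity = function(object) {
    if (length(object@values) < 3L) return("TIC too short")
    if (object@fps <= 0) return("fps must be positive")
    TRUE
  }
)

#' PeakSet: detected contrast peaks of a TIC
#'
#' Contrast arrival lowers image intensity, so peaks of contrast
#' concentration are relative minima of the TIC; frame indices are stored in
#' increasing order.
#'
#' @slot peakFrames integer frame indices (1-based), strictly increasing.
#' @slot peakFramesRefined numeric sub-frame peak positions (parabolic
#'   refinement) when requested, otherwise equal to `peakFrames`.
#' @slot polarity fixed tag "contrast-max = intensity-min".
#' @slot excludedFirst whether the first detected peak was dropped.
#' @export
setClass("PeakSet",
  representation(peakFrames = "integer", peakFramesRefined = "numeric",
                 polarity = "character", excludedFirst = "logical"),
  validity = function(object) {
    p <- object@peakFrames
    if (length(p) < 1L) return("no peaks")
    if (any(diff(p) <= 0)) return("peak frames must be strictly increasing")
    TRUE
  }
)

#' VelocityEstimate: per-peak velocities and their summary
#'
#' Each matched peak pair contributes one velocity
#' \eqn{v_k = \Delta x / \Delta t_k \times fps} (mm/s), where \eqn{\Delta x}
#' is the along-centerline ROI separation in mm and \eqn{\Delta t_k} the
#' frame shift of the k-th contrast peak between the proximal and distal
#' ROI.  The summary is the arithmetic mean and the population standard
#' deviation over peaks (a single peak reports SD 0).
#'
#' @slot perPeakVelocities velocities per matched peak (mm/s).
#' @slot meanVelocity mean of `perPeakVelocities` (mm/s).
#' @slot sdVelocity population SD of `perPeakVelocities` (mm/s).
#' @slot dxMm ROI separation along the centerline (mm).
#' @slot perPeakDtFrames frame shift per matched peak.
#' @export
setClass("VelocityEstimate",
  representation(perPeakVelocities = "numeric", meanVelocity = "numeric",
                 sdVelocity = "numeric", dxMm = "numeric",
                 perPeakDtFrames = "numeric"),
  validity = function(object) {
    if (any(object@perPeakVelocities <= 0))
      return("all per-peak velocities must be positive")
    m <- mean(object@perPeakVelocities)
    if (abs(m - object@meanVelocity) > 1e-8 * max(1, abs(m)))
      return("meanVelocity must equal the mean of perPeakVelocities")
    TRUE
  }
)

#' DiameterMeasurement: vessel width at a named site
#'
#' @slot site site label, "proximal" or "middle" (free text allowed).
#' @slot arcFraction fractional arc-length position of the site in [0, 1].
#' @slot diameterMm measured full width at half contrast depth (mm).
#' @slot method fixed method tag, "fwhm".
#' @export
setClass("DiameterMeasurement",
  representation(site = "character", arcFraction = "numeric",
                 diameterMm = "numeric", method = "character"),
  validity = function(object) {
    if (object@diameterMm <= 0) return("diameter must be positive")
    TRUE
  }
)

#' PhantomConfig: parameters of the synthetic angiographic phantom
#'
#' See [phantomConfig()] for the constructor, defaults and units.
#'
#' @slot shape image size c(rows, cols) in pixels.
#' @slot fps frame rate (frames/s).
#' @slot resolution spatial resolution (mm/px).
#' @slot pathKind "straight" or "sinusoid" (projected helix).
#' @slot pathAmplitudePx sinusoid amplitude (px).
#' @slot pathPeriodPx sinusoid period (px).
#' @slot vesselRadiusPx vessel half-width (px); length 1 (constant) or 2
#'   (proximal, middle) for a radius varying along the path.
#' @slot bolusVelocity true bolus transport speed (mm/s).
#' @slot nPulses number of bolus concentration pulses.
#' @slot pulsePeriodS seconds between pulse starts.
#' @slot dispersionPxPerFrame growth rate of the pulse width (px/frame).
#' @slot sigma0Px initial pulse width (px, Gaussian sigma in arc length).
#' @slot backgroundLevel background intensity (grayscale units).
#' @slot bolusDepth intensity drop of undiluted contrast (grayscale units).
#' @slot noiseSd additive Gaussian noise SD (grayscale units).
#' @slot pathMarginPx margin between path ends and the image border (px).
#' @slot nFrames number of frames; NA = long enough for the full transit.
#' @slot seed random seed for the noise.
#' @export
setClass("PhantomConfig",
  representation(shape = "integer", fps = "numeric", resolution = "numeric",
                 pathKind = "character", pathAmplitudePx = "numeric",
                 pathPeriodPx = "numeric", vesselRadiusPx = "numeric",
                 bolusVelocity = "numeric", nPulses = "integer",
                 pulsePeriodS = "numeric", dispersionPxPerFrame = "numeric",
                 sigma0Px = "numeric", backgroundLevel = "numeric",
                 bolusDepth = "numeric", noiseSd = "numeric",
                 pathMarginPx = "numeric", nFrames = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@bolusVelocity <= 0) return("bolus_velocity must be > 0")
    if (object@nPulses < 1L) return("n_pulses must be >= 1")
    if (object@noiseSd < 0) return("noise_sd must be >= 0")
    if (!object@pathKind %in% c("straight", "sinusoid"))
      return("path_kind must be 'straight' or 'sinusoid'")
    if (!length(object@vesselRadiusPx) %in% 1:2 ||
        any(object@vesselRadiusPx <= 0))
      return("vesselRadiusPx must be 1 or 2 positive values")
    TRUE
  }
)

#' PhantomTruth: ground truth accompanying a synthetic sequence
#'
#' @slot bolusVelocity true transport speed (mm/s).
#' @slot centerlinePoints ordered true centerline (row, col), ~1 px spacing.
#' @slot cumArcPx cumulative arc length (px) along `centerlinePoints`.
#' @slot arcLengthMm total path length in mm.
#' @slot peakPassTimes nPulses x nPoints matrix; frame index (1-based) of the
#'   maximum local contrast concentration of each pulse at each arc position.
#' @slot vesselMask logical matrix, the rasterized vessel tube.
#' @export
setClass("PhantomTruth",
  representation(bolusVelocity = "numeric", centerlinePoints = "matrix",
                 cumArcPx = "numeric", arcLengthMm = "numeric",
                 peakPassTimes = "matrix", vesselMask = "matrix"),
  validity = function(object) {
    polyLen <- sum(sqrt(rowSums(diff(object@centerlinePoints)^2)))
    if (abs(polyLen - max(object@cumArcPx)) > 1e-6)
      return("cumArcPx inconsistent with centerline polyline length")
    if (object@arcLengthMm <= 0)
      return("arcLengthMm must be positive")
    TRUE
  }
)

#' CaseReport: end-to-end result of one before/after stenting case
#'
#' @slot caseId case identifier.
#' @slot vessel vessel / stent-arm label.
#' @slot before [VelocityEstimate-class] of the pre-stent sequence.
#' @slot after [VelocityEstimate-class] of the post-stent sequence.
#' @slot retentionPct velocity retention ratio (%), 1 decimal.
#' @slot diameters data.frame: site, before_mm, after_mm, expansion_pct.
#' @slot provenance list: resolved config, input paths, config hash, seed.
#' @export
setClass("CaseReport",
  representation(caseId = "character", vessel = "character",
                 before = "VelocityEstimate", after = "VelocityEstimate",
                 retentionPct = "numeric", diameters = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    recomputed <- round(100 * object@after@meanVelocity /
                          object@before@meanVelocity, 1L)
    if (abs(recomputed - object@retentionPct) > 0.05)
      return("retentionPct not recomputable from stored velocities")
    d <- object@diameters
    if (nrow(d)) {
      exp2 <- round(100 * (d$after_mm - d$before_mm) / d$before_mm, 1L)
      if (any(abs(exp2 - d$expansion_pct) > 0.05))
        return("expansion_pct not recomputable from stored diameters")
    }
    TRUE
  }
)
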