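#' @include AllClasses.R
NULL

.roiFromCenter <- function(cl, index, edgePx, frameDim) {
  ctr <- round(centerlinePoints(cl)[index, ])
  half <- as.integer(edgePx / 2L)
  rmin <- as.integer(ctr[1L]) - half + 1L
  cmin <- as.integer(ctr[2L]) - half + 1L
  bounds <- c(rmin, rmin + edgePx - 1L, cmin, cmin + edgePx - 1L)
  if (bounds[1L] < 1L || bounds[3L] < 1L ||
      bounds[2L] > frameDim[1L] || bounds[4L] > frameDim[2L])
    return(NULL)
  new("ROI", centerIndex = as.integer(index),
      halfSizePx = half, bounds = as.integer(bounds))
}

# best contrast-peak prominence of the TIC at a candidate ROI (0 if none)
.bestProminence <- function(seq, roi) {
  v <- .roiMeans(frames(seq), roi)
  y <- max(v) - v
  cand <- .relativeMaxima(y, order = 1L)
  if (!length(cand)) return(0)
  max(vapply(cand, function(p) .prominence(y, p), numeric(1L)))
}

#' Place proximal and distal ROIs along the centerline
#'
#' Either places 20 x 20 px boxes at user-given centerline indices
#' (`strategy = "manual"`), or scans candidate positions along the
#' centerline (`strategy = "auto"`): the proximal ROI is the first position
#' from the inflow end whose TIC shows a contrast peak of sufficient
#' prominence, and the distal ROI is the last position whose TIC still
#' retains a detectable peak — i.e. just before the peak fades out.
#' Prominence thresholds are fractions of the best prominence seen along
#' the vessel.
#'
#' @param cl a [Centerline-class].
#' @param seq the source [AngioSequence-class].
#' @param strategy "auto" or "manual".
#' @param indices length-2 centerline indices (proximal, distal) for
#'   manual placement.
#' @param edgePx ROI edge length in px (default 20).
#' @param stepPx candidate spacing along the arc for auto placement.
#' @param promFrac prominence fraction qualifying the proximal ROI.
#' @param fadeFrac prominence fraction below which the peak has "faded".
#' @return list(proximal = [ROI-class], distal = [ROI-class]).
#' @export
placeRois <- function(cl, seq, strategy = c("auto", "manual"),
                      indices = NULL, edgePx = 20L, stepPx = 10,
                      promFrac = 0.5, fadeFrac = 0.2) {
  strategy <- match.arg(strategy)
  fd <- frameDim(seq)
  arc <- cumulativeArcPx(cl)

  if (strategy == "manual") {
    if (is.null(indices) || length(indices) != 2L)
      stop("manual placement needs two centerline indices")
    rois <- lapply(indices, .roiFromCenter, cl = cl, edgePx = edgePx,
                   frameDim = fd)
    if (any(vapply(rois, is.null, logical(1L))))
      stop("ROI does not fit inside the frame at the given index")
  } else {
    candIdx <- vapply(seq(0, max(arc), by = stepPx),
                      function(s) which.min(abs(arc - s)), integer(1L))
    candIdx <- unique(candIdx)
    cands <- lapply(candIdx, .roiFromCenter, cl = cl, edgePx = edgePx,
                    frameDim = fd)
    ok <- !vapply(cands, is.null, logical(1L))
    candIdx <- candIdx[ok]; cands <- cands[ok]
    if (length(cands) < 2L) stop("not enough ROI candidates fit the frame")
    prom <- vapply(cands, .bestProminence, numeric(1L), seq = seq)
    top <- max(prom)
    if (top <= 0) stop("no candidate ROI shows a contrast peak")
    iProx <- which(prom >= promFrac * top)[1L]
    iDist <- max(which(prom >= fadeFrac * top))
    if (is.na(iProx) || iDist <= iProx)
      stop("no candidate pair satisfies the prominence thresholds")
    rois <- list(cands[[iProx]], cands[[iDist]])
  }

  sep <- abs(arc[rois[[2L]]@centerIndex] - arc[rois[[1L]]@centerIndex])
  if (sep <= edgePx)
    stop("proximal and distal ROIs overlap (arc separation ", round(sep, 1),
         " px <= ROI edge ", edgePx, " px)")
  list(proximal = rois[[1L]], distal = rois[[2L]])
}

.roiMeans <- function(fr, roi) {
  b <- roi@bounds
  block <- fr[b[1L]:b[2L], b[3L]:b[4L], , drop = FALSE]
  apply(block, 3L, mean)
}

#' Compute the area-averaged time-intensity curve of an ROI
#'
#' `values[t]` is the mean intensity of frame `t` over the ROI box;
#' averaging over the box suppresses pixel noise.  No temporal filtering is
#' applied.
#'
#' @param seq an [AngioSequence-class].
#' @param roi an [ROI-class].
#' @return A [TimeIntensityCurve-class].
#' @export
computeTic <- function(seq, roi) {
  fd <- frameDim(seq)
  b <- roi@bounds
  if (b[1L] < 1L || b[3L] < 1L || b[2L] > fd[1L] || b[4L] > fd[2L])
    stop("ROI out of frame bounds")
  new("TimeIntensityCurve", values = .roiMeans(frames(seq), roi),
      fps = fps(seq), roi = roi)
}

# indices of relative maxima of y within +/- order, plateaus keep the first
.relativeMaxima <- function(y, order) {
  n <- length(y)
  if (n <= 2L * order) return(integer(0L))
  out <- integer(0L)
  for (i in (order + 1L):(n - order)) {
    w <- y[(i - order):(i + order)]
    if (y[i] == max(w) && any(w < y[i])) {
      if (length(out) && i - out[length(out)] <= order &&
          y[i] == y[out[length(out)]]) next  # plateau continuation
      out <- c(out, i)
    }
  }
  out
}

# topographic prominence of peak p in series y (edges count as valleys)
.prominence <- function(y, p) {
  leftHigher <- which(y[seq_len(p - 1L)] > y[p])
  lFrom <- if (length(leftHigher)) max(leftHigher) else 1L
  leftValley <- min(y[lFrom:p])
  rightHigher <- which(y[(p + 1L):length(y)] > y[p]) + p
  rTo <- if (length(rightHigher)) min(rightHigher) else length(y)
  rightValley <- min(y[p:rTo])
  y[p] - max(leftValley, rightValley)
}

#' Detect contrast peaks in a TIC
#'
#' Contrast arrival lowers intensity, so the TIC is inverted and contrast
#' peaks are detected as relative maxima of the inverted curve within
#' `order` frames, kept when their topographic prominence reaches
#' `minProminence`.  Optionally the first detected peak is dropped — the
#' case-by-case rule for a first pulsation whose intensity change is too
#' small at the distal ROI to be usable.
#'
#' @param tic a [TimeIntensityCurve-class].
#' @param order neighbourhood half-width in frames; default
#'   `max(1, round(fps / 10))`.
#' @param minProminence minimum prominence in intensity units; default 5%
#'   of the TIC dynamic range.
#' @param excludeFirst drop the first detected peak.
#' @return A [PeakSet-class].
#' @export
detectPeaks <- function(tic, order = NULL, minProminence = NULL,
                        excludeFirst = FALSE) {
  v <- ticValues(tic)
  if (is.null(order)) order <- max(1L, as.integer(round(fps(tic) / 10)))
  if (length(v) <= 2L * order)
    stop("TIC too short for the requested neighbourhood order")
  if (is.null(minProminence)) minProminence <- 0.05 * diff(range(v))
  y <- max(v) - v
  cand <- .relativeMaxima(y, order)
  if (length(cand)) {
    prom <- vapply(cand, function(p) .prominence(y, p), numeric(1L))
    cand <- cand[prom >= minProminence]
  }
  excluded <- FALSE
  if (excludeFirst && length(cand) > 1L) {
    cand <- cand[-1L]
    excluded <- TRUE
  }
  if (!length(cand)) stop("no contrast peak passes the prominence filter")
  # parabolic sub-frame refinement (reported alongside integer frames)
  refined <- vapply(cand, function(p) {
    if (p <= 1L || p >= length(y)) return(as.numeric(p))
    den <- y[p - 1L] - 2 * y[p] + y[p + 1L]
    if (den >= 0) return(as.numeric(p))
    d <- 0.5 * (y[p - 1L] - y[p + 1L]) / den
    p + max(-0.5, min(0.5, d))
  }, numeric(1L))
  new("PeakSet", peakFrames = as.integer(cand), peakFramesRefined = refined,
      polarity = "contrast-max = intensity-min", excludedFirst = excluded)
}

#' Estimate flow velocity from the proximal/distal TIC peak shift
#'
#' Matches the k-th proximal contrast peak to the k-th distal peak (ordinal
#' matching, truncated to the shorter list).  Each matched pair gives a
#' frame shift `dt = distal frame - proximal frame` and a velocity
#' `v = dx / dt * fps` (mm/s), where `dx` is the along-centerline ROI
#' separation in mm (the pixel arc length times the image resolution).
#' The mean and the population SD over peaks are reported; a single peak
#' reports SD 0.  Frame shifts are integer by default; sub-frame parabolic
#' refinement can be enabled with `refineSubframe`.
#'
#' @param ticProx,ticDist proximal and distal [TimeIntensityCurve-class]s.
#' @param dxMm ROI separation along the centerline (mm, > 0).
#' @param matching peak matching rule; only "ordinal" is defined.
#' @param order,minProminence peak-detection parameters, see
#'   [detectPeaks()].
#' @param excludeFirst drop the first detected peak of both TICs before
#'   matching.
#' @param refineSubframe use parabolic sub-frame peak positions.
#' @param peaksProx,peaksDist optional precomputed [PeakSet-class]s.
#' @return A [VelocityEstimate-class].
#' @examples
#' # one peak pair 2 frames apart, 20 mm apart, at 30 fps -> 300 mm/s
#' mkTic <- function(peakAt) {
#'   v <- rep(1000, 40); v[peakAt] <- 500
#'   new("TimeIntensityCurve", values = v, fps = 30,
#'       roi = new("ROI", centerIndex = 1L, halfSizePx = 10L,
#'                 bounds = c(1L, 20L, 1L, 20L)))
#' }
#' est <- estimateVelocity(mkTic(10), mkTic(12), dxMm = 20)
#' meanVelocity(est)
#' @export
estimateVelocity <- function(ticProx, ticDist, dxMm,
                             matching = c("ordinal"), order = NULL,
                             minProminence = NULL, excludeFirst = FALSE,
                             refineSubframe = FALSE, peaksProx = NULL,
                             peaksDist = NULL) {
  matching <- match.arg(matching)
  if (dxMm <= 0) stop("dxMm must be positive")
  if (abs(fps(ticProx) - fps(ticDist)) > 1e-9)
    stop("proximal and distal TICs have different frame rates")
  if (is.null(peaksProx))
    peaksProx <- detectPeaks(ticProx, order, minProminence, excludeFirst)
  if (is.null(peaksDist))
    peaksDist <- detectPeaks(ticDist, order, minProminence, excludeFirst)

  pp <- if (refineSubframe) peaksProx@peakFramesRefined
        else as.numeric(peakFrames(peaksProx))
  pd <- if (refineSubframe) peaksDist@peakFramesRefined
        else as.numeric(peakFrames(peaksDist))
  k <- min(length(pp), length(pd))
  dt <- pd[seq_len(k)] - pp[seq_len(k)]
  if (any(dt < 1 - refineSubframe * 0.5) || any(dt <= 0))
    stop("non-positive peak shift: peaks mis-matched or ROI separation ",
         "insufficient to generate a peak delay")
  v <- dxMm / dt * fps(ticProx)
  m <- mean(v)
  new("VelocityEstimate", perPeakVelocities = v, meanVelocity = m,
      sdVelocity = sqrt(mean((v - m)^2)), dxMm = dxMm,
      perPeakDtFrames = dt)
}

#' Velocity retention ratio after stenting, in percent
#'
#' `100 * after / before`, reported to 1 decimal: the fraction of the
#' pre-stent mean velocity retained after stent placement.
#'
#' @param meanBefore,meanAfter mean velocities in mm/s (before > 0), or
#'   [VelocityEstimate-class] objects.
#' @return retention percentage, rounded to 1 decimal.
#' @examples
#' retentionRatio(441.4, 252.4)  # 57.2
#' @export
retentionRatio <- function(meanBefore, meanAfter) {
  if (is(meanBefore, "VelocityEstimate")) meanBefore <- meanVelocity(meanBefore)
  if (is(meanAfter, "VelocityEstimate")) meanAfter <- meanVelocity(meanAfter)
  if (any(meanBefore <= 0)) stop("meanBefore must be positive")
  round(100 * meanAfter / meanBefore, 1L)
}
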