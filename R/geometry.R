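#' @include AllClasses.R
NULL

#' Extract the vessel mask from intensity changes
#'
#' Segments the contrast-filled lumen from the temporal intensity signature
#' of the sequence: a pixel belongs to the vessel when contrast passage
#' changed its intensity.  Two statistics are offered:
#' \describe{
#'   \item{temporal_range}{per-pixel max - min over frames: pixels the
#'     bolus darkened at some point score high.}
#'   \item{min_projection}{background minus the per-pixel minimum
#'     projection, with the background level taken as the image-wide median
#'     of the minimum projection (most pixels never see contrast).}
#' }
#' Foreground = statistic >= `threshold` times its image-wide maximum;
#' the largest connected component (8-connectivity) is kept.
#'
#' @param seq an [AngioSequence-class].
#' @param thresholdMode "temporal_range" or "min_projection".
#' @param threshold fraction of the image-wide maximum statistic (default
#'   0.5).
#' @return A [VesselMask-class].
#' @export
extractVesselMask <- function(seq,
                              thresholdMode = c("temporal_range",
                                                "min_projection"),
                              threshold = 0.5) {
  thresholdMode <- match.arg(thresholdMode)
  fr <- frames(seq)
  nt <- dim(fr)[3L]
  mn <- fr[, , 1L]; mx <- fr[, , 1L]
  for (t in 2:nt) {
    mn <- pmin(mn, fr[, , t])
    mx <- pmax(mx, fr[, , t])
  }
  stat <- if (thresholdMode == "temporal_range") mx - mn
          else pmax(stats::median(mn) - mn, 0)
  top <- max(stat)
  if (top <= 0)
    stop("empty foreground: no intensity change anywhere in the sequence")
  fg <- stat >= threshold * top
  if (!any(fg)) stop("empty foreground at the given threshold")
  labels <- as.array(EBImage::bwlabel(fg * 1))
  tab <- tabulate(labels[labels > 0])
  mask <- matrix(labels == which.max(tab), nrow(fg), ncol(fg))
  new("VesselMask", mask = mask, sourceFrameRange = c(1L, nt))
}

#' Extract and smooth the vessel centerline
#'
#' Thins the vessel mask to a one-pixel skeleton (Zhang-Suen), prunes it to
#' the single longest endpoint-to-endpoint geodesic (side-branch spurs
#' drop out), orders the points from the inflow end, and smooths the row
#' and column coordinate series with a Savitzky-Golay polynomial filter to
#' remove the pixel-lattice staircase before the arc length is accumulated.
#'
#' @param mask a [VesselMask-class] (or logical matrix).
#' @param smoothWindow odd Savitzky-Golay window length (points); windows
#'   longer than the path are shrunk.
#' @param smoothOrder polynomial order, must be < `smoothWindow`.
#' @param inflow which image border the proximal (inflow) end is nearest:
#'   "left", "right", "top" or "bottom".
#' @return A [Centerline-class].
#' @export
extractCenterline <- function(mask, smoothWindow = 21L, smoothOrder = 3L,
                              inflow = c("left", "right", "top", "bottom")) {
  inflow <- match.arg(inflow)
  m <- if (is(mask, "VesselMask")) maskMatrix(mask) else mask
  if (!any(m)) stop("mask is empty")
  if (smoothWindow %% 2L == 0L) stop("smoothWindow must be odd")
  if (smoothOrder >= smoothWindow)
    stop("smoothOrder must be smaller than smoothWindow")

  skel <- thinMask(m)
  raw <- .longestSkeletonPath(skel)

  startsAtInflow <- switch(inflow,
    left   = raw[1L, 2L] <= raw[nrow(raw), 2L],
    right  = raw[1L, 2L] >= raw[nrow(raw), 2L],
    top    = raw[1L, 1L] <= raw[nrow(raw), 1L],
    bottom = raw[1L, 1L] >= raw[nrow(raw), 1L])
  if (!startsAtInflow) raw <- raw[rev(seq_len(nrow(raw))), , drop = FALSE]

  n <- nrow(raw)
  win <- min(smoothWindow, if (n %% 2L == 1L) n else n - 1L)
  if (win > smoothOrder + 1L) {
    sm <- cbind(signal::sgolayfilt(raw[, 1L], p = smoothOrder, n = win),
                signal::sgolayfilt(raw[, 2L], p = smoothOrder, n = win))
  } else {
    sm <- raw
  }

  step <- sqrt(rowSums((sm[-1L, , drop = FALSE] -
                        sm[-n, , drop = FALSE])^2))
  keep <- c(TRUE, step > 1e-12)
  sm <- sm[keep, , drop = FALSE]
  arc <- c(0, cumsum(step[step > 1e-12]))
  new("Centerline", points = sm, rawPoints = raw[keep, , drop = FALSE],
      cumArcPx = arc)
}

#' Along-centerline distance between two points
#'
#' @param cl a [Centerline-class].
#' @param idxA,idxB point indices, `idxA <= idxB`.
#' @param resolution spatial resolution (mm/px).
#' @return distance in mm.
#' @examples
#' cl <- centerlineFromPoints(cbind(10, 1:200))
#' arcDistance(cl, 50, 150, resolution = 0.2)  # 20 mm
#' @export
arcDistance <- function(cl, idxA, idxB, resolution) {
  n <- length(cl@cumArcPx)
  if (idxA < 1L || idxB > n || idxA > idxB)
    stop("point indices out of range (need 1 <= idxA <= idxB <= ", n, ")")
  (cl@cumArcPx[idxB] - cl@cumArcPx[idxA]) * resolution
}

# bilinear interpolation of matrix `img` at float (row, col) positions
.bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmin(pmax(r0, 1L), nrow(img) - 1L)
  c0 <- pmin(pmax(c0, 1L), ncol(img) - 1L)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Measure the vessel diameter at a site along the centerline
#'
#' Samples the intensity profile along the line perpendicular to the local
#' centerline tangent at the requested arc-length fraction, on the frame of
#' strongest local contrast (the "highest TIC" frame at the site: the frame
#' minimizing the mean intensity of a 21 x 21 px box at the site, so that a
#' contrast pulse is actually crossing the site when the width is read),
#' and returns the full width at half the profile's contrast depth times
#' the spatial resolution — the standard angiographic FWHM convention.
#'
#' @param seq an [AngioSequence-class].
#' @param cl a [Centerline-class].
#' @param siteFraction fractional arc position of the site in [0, 1].
#' @param profileFrame optional frame index; default picks the strongest
#'   local contrast frame.
#' @param site site label; defaults to "proximal" for fractions <= 0.3,
#'   "middle" otherwise.
#' @param profileHalfWidthPx half-length of the sampled profile (px).
#' @param stepPx profile sampling step (px).
#' @return A [DiameterMeasurement-class].
#' @export
measureDiameter <- function(seq, cl, siteFraction, profileFrame = NULL,
                            site = NULL,
                            profileHalfWidthPx = 40, stepPx = 0.25) {
  stopifnot(siteFraction >= 0, siteFraction <= 1)
  if (is.null(site)) site <- if (siteFraction <= 0.3) "proximal" else "middle"
  arc <- cumulativeArcPx(cl)
  pts <- centerlinePoints(cl)
  i <- which.min(abs(arc - siteFraction * max(arc)))
  k <- min(5L, i - 1L, nrow(pts) - i)
  if (k < 1L) stop("centerline too short to define a tangent at the site")
  tang <- pts[i + k, ] - pts[i - k, ]
  tang <- tang / sqrt(sum(tang^2))
  normal <- c(-tang[2L], tang[1L])

  fr <- frames(seq)
  if (is.null(profileFrame)) {
    ctr <- round(pts[i, ])
    rr <- max(1L, ctr[1L] - 10L):min(dim(fr)[1L], ctr[1L] + 10L)
    cc <- max(1L, ctr[2L] - 10L):min(dim(fr)[2L], ctr[2L] + 10L)
    means <- vapply(seq_len(dim(fr)[3L]),
                    function(t) mean(fr[rr, cc, t]), numeric(1L))
    profileFrame <- which.min(means)
  }
  img <- fr[, , profileFrame]

  u <- seq(-profileHalfWidthPx, profileHalfWidthPx, by = stepPx)
  rr <- pts[i, 1L] + u * normal[1L]
  cc <- pts[i, 2L] + u * normal[2L]
  inb <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  if (!all(inb))
    stop("profile leaves the frame; vessel too close to the image edge")
  prof <- .bilinear(img, rr, cc)

  nTail <- max(3L, floor(length(u) * 0.15))
  bg <- mean(c(prof[seq_len(nTail)], prof[(length(prof) - nTail + 1L):
                                            length(prof)]))
  iMin <- which.min(prof)
  depth <- bg - prof[iMin]
  if (depth <= 0) stop("no contrast depth in the profile at this site")
  half <- bg - depth / 2

  crossing <- function(side) {
    idx <- if (side == "left") rev(seq_len(iMin - 1L))
           else (iMin + 1L):length(prof)
    for (j in idx) {
      if (prof[j] >= half) {
        jPrev <- if (side == "left") j + 1L else j - 1L
        f <- (half - prof[jPrev]) / (prof[j] - prof[jPrev])
        return(u[jPrev] + f * (u[j] - u[jPrev]))
      }
    }
    stop("profile does not cross half-depth on the ", side,
         " side (vessel at frame edge?)")
  }
  widthPx <- crossing("right") - crossing("left")
  new("DiameterMeasurement", site = site, arcFraction = siteFraction,
      diameterMm = widthPx * resolution(seq), method = "fwhm")
}

#' Diameter expansion after stenting, in percent
#'
#' `100 * (after - before) / before`, reported to 1 decimal — the expansion
#' rate convention used for stented-artery diameter tables.
#'
#' @param diameterBefore,diameterAfter diameters in mm (before > 0).
#' @return expansion percentage, rounded to 1 decimal.
#' @examples
#' expansionPercent(4.698, 5.568)  # 18.5
#' @export
expansionPercent <- function(diameterBefore, diameterAfter) {
  if (any(diameterBefore <= 0)) stop("diameterBefore must be positive")
  round(100 * (diameterAfter - diameterBefore) / diameterBefore, 1L)
}
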