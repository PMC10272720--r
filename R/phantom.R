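#' @include AllClasses.R
NULL

#' Configure a synthetic angiographic phantom
#'
#' Builds a [PhantomConfig-class] describing a synthetic DSA-like sequence:
#' a dark contrast bolus advected along a straight or sinusoidal (projected
#' helix) vessel at a known velocity, as a train of Gaussian concentration
#' pulses whose leading edge disperses over time, on a noisy background.
#'
#' Defaults emulate the acquisition conditions of carotid angiography with a
#' C-arm system: a 1024 x 1024 detector, 0.2 mm/px, 30 fps, a 6 mm vessel
#' (radius 15 px at 0.2 mm/px), a 300 mm/s bolus and a pulse train at 0.6 s
#' intervals (about 100 beats/min under anesthesia).  Intensities use a
#' 16-bit scale with background 3000 and contrast depth 2000.
#'
#' @param shape image size c(rows, cols) px.
#' @param fps frame rate (frames/s); angiographic practice uses 15 or 30.
#' @param resolution spatial resolution (mm/px), detector-dependent
#'   (0.109-0.249 typical).
#' @param pathKind "straight" or "sinusoid" (2D projection of a helical
#'   vessel).
#' @param pathAmplitudePx,pathPeriodPx sinusoid amplitude and period (px).
#' @param vesselRadiusPx vessel half-width (px); a length-2 vector
#'   (proximal, middle) produces a radius varying along the path
#'   (inhomogeneous diameter).
#' @param bolusVelocity true transport speed (mm/s).
#' @param nPulses number of bolus concentration pulses (cardiac cycles).
#' @param pulsePeriodS seconds between pulse starts.
#' @param dispersionPxPerFrame pulse-width growth rate (px/frame); pulse
#'   amplitude decays as sigma0/sigma so dispersed contrast fades distally.
#' @param sigma0Px initial Gaussian pulse width in arc length (px).  Keep
#'   it comfortably above the per-frame bolus displacement
#'   `v / (resolution * fps)` so that every arc position sees a
#'   near-maximal concentration on some frame.
#' @param backgroundLevel,bolusDepth background intensity and the intensity
#'   drop of undiluted contrast (grayscale units, 16-bit scale).
#' @param noiseSd additive Gaussian noise SD (grayscale units).
#' @param pathMarginPx margin between the path ends and the image border.
#' @param nFrames number of frames; NA chooses enough for the full transit.
#' @param seed random seed for the noise.
#' @return A validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(shape = c(96, 320), vesselRadiusPx = 8,
#'                      bolusVelocity = 150, noiseSd = 0)
#' cfg
#' @export
phantomConfig <- function(shape = c(1024L, 1024L), fps = 30,
                          resolution = 0.2, pathKind = "straight",
                          pathAmplitudePx = 40, pathPeriodPx = 300,
                          vesselRadiusPx = 15, bolusVelocity = 300,
                          nPulses = 4L, pulsePeriodS = 0.6,
                          dispersionPxPerFrame = 0.5, sigma0Px = 40,
                          backgroundLevel = 3000, bolusDepth = 2000,
                          noiseSd = 20, pathMarginPx = 60, nFrames = NA,
                          seed = 1L) {
  new("PhantomConfig", shape = as.integer(shape), fps = fps,
      resolution = resolution, pathKind = pathKind,
      pathAmplitudePx = pathAmplitudePx, pathPeriodPx = pathPeriodPx,
      vesselRadiusPx = as.numeric(vesselRadiusPx),
      bolusVelocity = bolusVelocity, nPulses = as.integer(nPulses),
      pulsePeriodS = pulsePeriodS,
      dispersionPxPerFrame = dispersionPxPerFrame, sigma0Px = sigma0Px,
      backgroundLevel = backgroundLevel, bolusDepth = bolusDepth,
      noiseSd = noiseSd, pathMarginPx = pathMarginPx,
      nFrames = as.numeric(nFrames), seed = as.integer(seed))
}

# True centerline sampled at ~1 px arc spacing: n x 2 (row, col) + arc px
.phantomPath <- function(config) {
  rows <- config@shape[1L]; cols <- config@shape[2L]
  m <- config@pathMarginPx
  if (cols - m <= m + 2)
    stop("image too narrow for the path margin")
  if (config@pathKind == "straight") {
    cc <- seq(m, cols - m, by = 1)
    rr <- rep(round(rows / 2), length(cc))
    pts <- cbind(row = rr, col = cc)
    arc <- cc - cc[1L]
  } else {
    ccf <- seq(m, cols - m, by = 0.25)
    rrf <- rows / 2 + config@pathAmplitudePx *
      sin(2 * pi * (ccf - m) / config@pathPeriodPx)
    arcf <- c(0, cumsum(sqrt(diff(rrf)^2 + diff(ccf)^2)))
    sOut <- seq(0, max(arcf), by = 1)
    pts <- cbind(row = stats::approx(arcf, rrf, xout = sOut)$y,
                 col = stats::approx(arcf, ccf, xout = sOut)$y)
    # arc coordinates of the stored (resampled) polyline
    arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  }
  list(points = pts, arc = arc)
}

# Radius (px) as a function of arc position; length-2 radii interpolate
# proximal (up to 0.35 L) -> middle (from 0.5 L on).
.radiusAt <- function(s, L, radii) {
  if (length(radii) == 1L) return(rep(radii, length(s)))
  stats::approx(x = c(0, 0.35, 0.5, 1) * L,
                y = c(radii[1L], radii[1L], radii[2L], radii[2L]),
                xout = s, rule = 2L)$y
}

#' Generate a synthetic angiographic sequence with ground truth
#'
#' Renders the phantom described by a [PhantomConfig-class].  Inside the
#' vessel tube, intensity is
#' `background - depth * edge(pixel) * concentration(arc position, frame)`
#' plus noise; outside, background plus noise.  The concentration is a sum
#' of Gaussian pulses (clamped at 1) whose centers travel along the path at
#' the configured velocity, converted to px/frame as
#' `v / (resolution * fps)`, and whose widths grow by the dispersion rate
#' while their amplitudes decay in proportion (mass-conserving spreading).
#' `edge()` falls linearly from 1 inside the lumen to 0 over one pixel at
#' the wall, so the full width at half depth of a cross profile equals the
#' configured diameter.  Identical config and seed give bit-identical
#' output.
#'
#' @param config a [PhantomConfig-class].
#' @return A list with elements `sequence` ([AngioSequence-class], integer
#'   intensities) and `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomConfig(shape = c(64, 200), vesselRadiusPx = 6,
#'                                     bolusVelocity = 120, nPulses = 1,
#'                                     noiseSd = 0))
#' ph$sequence
#' ph$truth
#' @export
generatePhantom <- function(config) {
  validObject(config)
  rows <- config@shape[1L]; cols <- config@shape[2L]
  path <- .phantomPath(config)
  pts <- path$points; s <- path$arc
  L <- max(s)
  maxRad <- max(config@vesselRadiusPx)

  if (min(pts[, 1L]) - maxRad - 1 < 1 || max(pts[, 1L]) + maxRad + 1 > rows ||
      min(pts[, 2L]) - maxRad - 1 < 1 || max(pts[, 2L]) + maxRad + 1 > cols)
    stop("vessel path (plus radius) exits the frame")

  vPxF <- config@bolusVelocity / (config@resolution * config@fps)
  if (L / vPxF < 2)
    stop("bolus would traverse the path in under 2 frames; ",
         "no peak shift is resolvable at this fps")

  periodFrames <- config@pulsePeriodS * config@fps
  t0 <- (seq_len(config@nPulses) - 1L) * periodFrames
  # pulse centers start one lead-in length upstream of the path so each
  # pulse enters, crosses and leaves the field of view
  lead <- 3.5 * config@sigma0Px
  nFrames <- config@nFrames
  if (is.na(nFrames)) {
    Tg <- max(t0) + (L + lead + 4 * config@sigma0Px) / vPxF
    for (i in 1:3)
      Tg <- max(t0) + (L + lead + 4 * (config@sigma0Px +
             config@dispersionPxPerFrame * Tg)) / vPxF
    nFrames <- max(2L, as.integer(ceiling(Tg)) + 2L)
  }
  nFrames <- as.integer(nFrames)

  # nearest-centerline assignment: squared distance D and arc position S
  D <- matrix(Inf, rows, cols)
  S <- matrix(0, rows, cols)
  R <- as.integer(ceiling(maxRad)) + 2L
  for (i in seq_len(nrow(pts))) {
    pr <- pts[i, 1L]; pc <- pts[i, 2L]
    rr <- max(1L, as.integer(round(pr)) - R):min(rows,
                                                 as.integer(round(pr)) + R)
    cc <- max(1L, as.integer(round(pc)) - R):min(cols,
                                                 as.integer(round(pc)) + R)
    d2 <- outer((rr - pr)^2, (cc - pc)^2, "+")
    Dw <- D[rr, cc]
    upd <- d2 < Dw
    if (any(upd)) {
      Dw[upd] <- d2[upd]
      D[rr, cc] <- Dw
      Sw <- S[rr, cc]; Sw[upd] <- s[i]; S[rr, cc] <- Sw
    }
  }
  candAll <- which(is.finite(D))
  dPix <- sqrt(D[candAll]); sAll <- S[candAll]
  radPix <- .radiusAt(sAll, L, config@vesselRadiusPx)
  edge <- pmin(1, pmax(0, radPix + 0.5 - dPix))
  keep <- edge > 0
  cand <- candAll[keep]; sPix <- sAll[keep]; edge <- edge[keep]

  truthMask <- matrix(FALSE, rows, cols)
  truthMask[candAll[dPix <= radPix]] <- TRUE

  concAt <- function(sv, tt) {
    total <- numeric(length(sv))
    for (k in seq_len(config@nPulses)) {
      dt <- tt - t0[k]
      sig <- config@sigma0Px + config@dispersionPxPerFrame * max(0, dt)
      amp <- config@sigma0Px / sig
      ctr <- vPxF * dt - lead
      total <- total + amp * exp(-(sv - ctr)^2 / (2 * sig^2))
    }
    pmin(1, total)
  }

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(config@seed)

  fr <- array(0L, dim = c(rows, cols, nFrames))
  for (t in seq_len(nFrames)) {
    img <- matrix(config@backgroundLevel, rows, cols)
    img[cand] <- config@backgroundLevel -
      config@bolusDepth * edge * concAt(sPix, t - 1)
    if (config@noiseSd > 0)
      img <- img + matrix(stats::rnorm(rows * cols, sd = config@noiseSd),
                          rows, cols)
    fr[, , t] <- as.integer(pmin(65535, pmax(0, round(img))))
  }

  # ground truth: per pulse, frame index of maximum concentration at each
  # centerline arc position (evaluated on the same discrete frame grid)
  tt <- seq_len(nFrames) - 1
  peakPass <- matrix(0L, nrow = config@nPulses, ncol = length(s))
  for (k in seq_len(config@nPulses)) {
    dt <- tt - t0[k]
    sig <- config@sigma0Px + config@dispersionPxPerFrame * pmax(0, dt)
    amp <- config@sigma0Px / sig
    ctr <- vPxF * dt - lead
    Z <- exp(-(outer(s, ctr, "-"))^2 /
               matrix(2 * sig^2, length(s), nFrames, byrow = TRUE)) *
      matrix(amp, length(s), nFrames, byrow = TRUE)
    peakPass[k, ] <- max.col(Z, ties.method = "first")
  }

  truth <- new("PhantomTruth", bolusVelocity = config@bolusVelocity,
               centerlinePoints = pts, cumArcPx = s,
               arcLengthMm = L * config@resolution,
               peakPassTimes = peakPass, vesselMask = truthMask)
  list(sequence = AngioSequence(fr, config@fps, config@resolution),
       truth = truth)
}

#' Generate a matched before/after stenting phantom pair
#'
#' Emits two phantoms sharing one vessel path: the "after" sequence has its
#' proximal and middle radii scaled by the expansion factors and its bolus
#' velocity scaled by the velocity factor — an end-to-end fixture for
#' recovery of the velocity retention ratio and the diameter expansion
#' rate.
#'
#' @param config a [PhantomConfig-class] for the before sequence.
#' @param expansionFactor length-2 positive multipliers
#'   c(proximal, middle) for the vessel radius, recycled if length 1.
#' @param velocityFactor positive multiplier for the bolus velocity
#'   (the true retention ratio is `100 * velocityFactor`).
#' @return list(before = list(sequence, truth), after = list(sequence,
#'   truth)).
#' @export
generatePairedCase <- function(config, expansionFactor = c(1, 1),
                               velocityFactor = 1) {
  if (any(expansionFactor <= 0) || velocityFactor <= 0)
    stop("expansion and velocity factors must be positive")
  expansionFactor <- rep(expansionFactor, length.out = 2L)
  before <- generatePhantom(config)
  after <- config
  r <- rep(config@vesselRadiusPx, length.out = 2L)
  after@vesselRadiusPx <- r * expansionFactor
  after@bolusVelocity <- config@bolusVelocity * velocityFactor
  after@seed <- config@seed + 1L
  list(before = before, after = generatePhantom(after))
}
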