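mkRoi <- function(rmin = 1L, cmin = 1L, edge = 20L, centerIndex = 1L) {
  new("ROI", centerIndex = centerIndex, halfSizePx = as.integer(edge / 2),
      bounds = as.integer(c(rmin, rmin + edge - 1L, cmin,
                            cmin + edge - 1L)))
}

mkTic <- function(values, fpsv = 30) {
  new("TimeIntensityCurve", values = values, fps = fpsv, roi = mkRoi())
}

test_that("ROI averaging is the plain area mean", {
  seq <- AngioSequence(array(100L, dim = c(32L, 32L, 4L)), 30, 0.2)
  tic <- computeTic(seq, mkRoi())
  expect_equal(ticValues(tic), rep(100, 4))

  # checkerboard of 0 / 255 averages to 127.5
  cb <- outer(1:32, 1:32, function(r, c) ((r + c) %% 2L) * 255L)
  seq2 <- AngioSequence(array(cb, dim = c(32L, 32L, 3L)), 30, 0.2)
  expect_equal(ticValues(computeTic(seq2, mkRoi()))[1L], 127.5)

  expect_error(computeTic(seq, mkRoi(rmin = 20L)), "out of frame")
})

test_that("a single dip is detected as a single contrast peak", {
  v <- rep(1000, 40)
  v[15:19] <- c(900, 700, 500, 700, 900)  # triangular dip at frame 17
  ps <- detectPeaks(mkTic(v))
  expect_identical(peakFrames(ps), 17L)
})

test_that("phantom TIC peaks match the truth pass times, and the first can
           be excluded", {
  cfg <- smallConfig(nPulses = 4L, pulsePeriodS = 0.4)
  ph <- generatePhantom(cfg)
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  rois <- placeRois(cl, ph$sequence, "manual", indices = c(150L, 250L))
  tic <- computeTic(ph$sequence, rois$proximal)
  ps <- detectPeaks(tic)
  expect_length(peakFrames(ps), 4L)
  iTruth <- truthIndexNear(ph$truth,
                           centerlinePoints(cl)[rois$proximal@centerIndex, ])
  expect_lte(max(abs(peakFrames(ps) - ph$truth@peakPassTimes[, iTruth])), 1)

  ps2 <- detectPeaks(tic, excludeFirst = TRUE)
  expect_identical(peakFrames(ps2), peakFrames(ps)[-1L])
  expect_true(ps2@excludedFirst)
})

test_that("velocity arithmetic follows dx / dt * fps", {
  # dx = 20 mm, dt = 2 frames at 30 fps -> 300 mm/s, SD 0
  p <- rep(1000, 40); p[10] <- 500
  d <- rep(1000, 40); d[12] <- 500
  est <- estimateVelocity(mkTic(p), mkTic(d), dxMm = 20)
  expect_equal(meanVelocity(est), 300)
  expect_equal(sdVelocity(est), 0)
  expect_equal(est@perPeakDtFrames, 2)

  # dt = {2, 2, 3}: per-peak {300, 300, 200}, mean 266.7
  p <- rep(1000, 60); p[c(10, 25, 40)] <- 500
  d <- rep(1000, 60); d[c(12, 27, 43)] <- 500
  est3 <- estimateVelocity(mkTic(p), mkTic(d), dxMm = 20)
  expect_equal(perPeakVelocities(est3), c(300, 300, 200))
  expect_equal(meanVelocity(est3), 266.7, tolerance = 1e-3)

  # distal peak before proximal peak -> mismatch error
  expect_error(estimateVelocity(mkTic(d), mkTic(p), dxMm = 20),
               "non-positive peak shift")
})

test_that("velocities are invariant under affine intensity rescaling", {
  ph <- generatePhantom(smallConfig(noiseSd = 10))
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  rois <- placeRois(cl, ph$sequence)
  dx <- arcDistance(cl, rois$proximal@centerIndex, rois$distal@centerIndex,
                    resolution(ph$sequence))
  est1 <- estimateVelocity(computeTic(ph$sequence, rois$proximal),
                           computeTic(ph$sequence, rois$distal), dx)
  seq2 <- AngioSequence(frames(ph$sequence) * 1.7 + 311, 30, 0.2)
  est2 <- estimateVelocity(computeTic(seq2, rois$proximal),
                           computeTic(seq2, rois$distal), dx)
  expect_identical(perPeakVelocities(est1), perPeakVelocities(est2))
})

test_that("retention ratios follow the after/before convention", {
  expect_equal(retentionRatio(441.4, 252.4), 57.2)
  expect_equal(retentionRatio(123.4, 123.4), 100.0)
  expect_error(retentionRatio(0, 100), "positive")
})

test_that("manual ROI placement uses 20 px boxes at the given indices", {
  ph <- generatePhantom(smallConfig())
  cl <- extractCenterline(extractVesselMask(ph$sequence))
  rois <- placeRois(cl, ph$sequence, "manual", indices = c(50L, 250L))
  b <- rois$proximal@bounds
  expect_equal(b[2L] - b[1L] + 1L, 20L)
  expect_equal(b[4L] - b[3L] + 1L, 20L)
  ctr <- round(centerlinePoints(cl)[50L, ])
  expect_true(b[1L] <= ctr[1L] && ctr[1L] <= b[2L])
  expect_true(b[3L] <= ctr[2L] && ctr[2L] <= b[4L])
  expect_error(placeRois(cl, ph$sequence, "manual", indices = c(50L, 55L)),
               "overlap")
})

test_that("auto ROI placement brackets the usable peak region", {
  ph <- generatePhantom(smallConfig())
  cl <- extractCenterline(extractVesselMask(ph$sequence))
  rois <- placeRois(cl, ph$sequence, "auto")
  expect_lt(rois$proximal@centerIndex, rois$distal@centerIndex)

  # a strongly dispersing bolus fades distally: the distal ROI must sit at
  # or before the last arc position whose brute-force prominence still
  # clears the fade threshold
  cfgF <- smallConfig(shape = c(96L, 720L), bolusVelocity = 150,
                      sigma0Px = 25, dispersionPxPerFrame = 6,
                      nPulses = 2L, pulsePeriodS = 0.5)
  phF <- generatePhantom(cfgF)
  clF <- extractCenterline(extractVesselMask(phF$sequence, threshold = 0.2))
  roisF <- placeRois(clF, phF$sequence, "auto", fadeFrac = 0.2)
  # brute-force prominence profile along the centerline
  arc <- cumulativeArcPx(clF)
  cand <- vapply(seq(0, max(arc), by = 10),
                 function(s) which.min(abs(arc - s)), integer(1L))
  prom <- vapply(cand, function(i) {
    roi <- AngioTIC:::.roiFromCenter(clF, i, 20L, frameDim(phF$sequence))
    if (is.null(roi)) return(0)
    tic <- computeTic(phF$sequence, roi)
    ps <- tryCatch(detectPeaks(tic, minProminence = 0), error = function(e) NULL)
    if (is.null(ps)) return(0)
    y <- max(ticValues(tic)) - ticValues(tic)
    max(y[peakFrames(ps)])
  }, numeric(1L))
  lastGood <- max(which(prom >= 0.2 * max(prom)))
  expect_lte(arc[roisF$distal@centerIndex], arc[cand[lastGood]] + 10)
  # and the distal TIC still has a detectable peak
  expect_silent(detectPeaks(computeTic(phF$sequence, roisF$distal)))
})

test_that("halving the frame rate at most doubles the quantization band", {
  r30 <- recoveryRun(300, 30)
  r15 <- recoveryRun(300, 15)
  bound30 <- 1 / (2 * r30$dtBar)
  bound15 <- 1 / (2 * r15$dtBar)
  expect_lte(abs(r30$estimate - 300) / 300, bound30 + 1e-9)
  expect_lte(abs(r15$estimate - 300) / 300, bound15 + 1e-9)
  expect_lte(bound15, 2 * bound30 + 1e-9)
})
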