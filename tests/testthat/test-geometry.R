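test_that("the extracted mask equals the rasterized tube on a clean phantom", {
  # half-integer radius + integer-row straight path: every pixel distance
  # to the centerline is an integer, so the threshold cannot straddle a
  # boundary pixel and the temporal-range mask must match the truth tube
  # exactly
  cfg <- smallConfig(vesselRadiusPx = 7.5, dispersionPxPerFrame = 0,
                     nPulses = 1L)
  ph <- generatePhantom(cfg)
  mask <- extractVesselMask(ph$sequence, "temporal_range", 0.5)
  expect_identical(maskMatrix(mask), maskMatrix(ph$truth))

  mask2 <- extractVesselMask(ph$sequence, "min_projection", 0.5)
  expect_identical(maskMatrix(mask2), maskMatrix(ph$truth))
})

test_that("a bolus-free sequence has no extractable foreground", {
  seq <- AngioSequence(array(1000L, dim = c(32L, 32L, 4L)), 30, 0.2)
  expect_error(extractVesselMask(seq), "empty foreground")
})

test_that("the sinusoid mask is one component containing the truth path", {
  ph <- generatePhantom(smallConfig(pathKind = "sinusoid",
                                    shape = c(160L, 420L),
                                    pathAmplitudePx = 25,
                                    pathPeriodPx = 200))
  mask <- extractVesselMask(ph$sequence)
  m <- maskMatrix(mask)
  pts <- round(centerlinePoints(ph$truth))
  expect_true(all(m[pts]))
  lab <- as.array(EBImage::bwlabel(m * 1))
  expect_equal(max(lab), 1)
})

test_that("a straight tube yields a straight, full-length centerline", {
  m <- matrix(FALSE, 64, 260)
  m[25:39, 31:230] <- TRUE   # 200 px long, 15 px wide
  cl <- extractCenterline(new("VesselMask", mask = m,
                              sourceFrameRange = c(1L, 2L)))
  pts <- centerlinePoints(cl)
  # thinning shaves up to half the tube width off each end
  expect_gte(max(cumulativeArcPx(cl)), 199 - 15 - 2)
  expect_lte(max(cumulativeArcPx(cl)), 199.5)
  expect_true(all(abs(pts[, 1L] - 32) < 1))
  # ordered from the left (inflow) border
  expect_lt(pts[1L, 2L], pts[nrow(pts), 2L])
})

test_that("the sinusoid centerline stays within 1.5 px of the truth path", {
  ph <- generatePhantom(smallConfig(pathKind = "sinusoid",
                                    shape = c(160L, 420L),
                                    pathAmplitudePx = 25,
                                    pathPeriodPx = 200))
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  pts <- centerlinePoints(cl)
  inner <- pts[cumulativeArcPx(cl) > 10 &
               cumulativeArcPx(cl) < max(cumulativeArcPx(cl)) - 10, ]
  expect_lt(maxDistToPolyline(inner, centerlinePoints(ph$truth)), 1.5)
})

test_that("side-branch spurs are pruned to the longest geodesic", {
  m <- matrix(FALSE, 40, 120)
  m[19:21, 11:110] <- TRUE   # main tube
  m[5:18, 59:61] <- TRUE     # short vertical spur
  cl <- extractCenterline(new("VesselMask", mask = m,
                              sourceFrameRange = c(1L, 2L)),
                          smoothWindow = 5L, smoothOrder = 1L)
  raw <- cl@rawPoints
  # oracle: brute-force Dijkstra over all skeleton endpoint pairs
  oracle <- bruteLongestGeodesic(thinMask(m))
  expect_equal(unname(max(cumulativeArcPx(cl))), oracle$length,
               tolerance = 0.15)
  # the spur (rows < 15) must not survive
  expect_true(all(raw[, 1L] >= 15))
})

test_that("smoothing never pulls the centerline far from the skeleton", {
  ph <- generatePhantom(smallConfig(pathKind = "sinusoid",
                                    shape = c(160L, 420L),
                                    pathAmplitudePx = 25,
                                    pathPeriodPx = 200))
  cl <- extractCenterline(extractVesselMask(ph$sequence),
                          smoothWindow = 21L, smoothOrder = 3L)
  dev <- sqrt(rowSums((centerlinePoints(cl) - cl@rawPoints)^2))
  expect_lt(max(dev), 21 / 2)
})

test_that("arc distances are exact, additive and respect closed forms", {
  cl <- centerlineFromPoints(cbind(10, 1:300))
  expect_equal(arcDistance(cl, 100, 200, 0.2), 20)
  expect_equal(arcDistance(cl, 57, 57, 0.2), 0)
  expect_error(arcDistance(cl, 200, 100, 0.2), "indices")
  expect_error(arcDistance(cl, 1, 400, 0.2), "indices")

  # additivity
  a <- arcDistance(cl, 10, 120, 0.2) + arcDistance(cl, 120, 290, 0.2)
  expect_equal(a, arcDistance(cl, 10, 290, 0.2), tolerance = 1e-9)

  # quarter circle of radius 100 px at 0.109 mm/px: (pi/2)*100*0.109
  th <- seq(0, pi / 2, length.out = 400L)
  qc <- centerlineFromPoints(cbind(120 - 100 * cos(th),
                                   20 + 100 * sin(th)))
  got <- arcDistance(qc, 1, nrow(centerlinePoints(qc)), 0.109)
  expect_equal(got, (pi / 2) * 100 * 0.109, tolerance = 0.02)
})

test_that("FWHM diameters recover the configured vessel width", {
  # radius 15 px at 0.2 mm/px -> 6.0 mm
  ph <- generatePhantom(smallConfig(shape = c(128L, 420L),
                                    vesselRadiusPx = 15))
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  d <- measureDiameter(ph$sequence, cl, 0.5)
  expect_equal(diameterMm(d), 6.0, tolerance = 0.2 / 6.0 * 3)

  # FWHM within +/- 1 px of the brute-force rasterized mask width
  pts <- centerlinePoints(cl)
  i <- which.min(abs(cumulativeArcPx(cl) - 0.5 * max(cumulativeArcPx(cl))))
  bruteWidth <- sum(maskMatrix(ph$truth)[, round(pts[i, 2L])])
  expect_lte(abs(diameterMm(d) / 0.2 - bruteWidth), 1)
})

test_that("measured diameter is monotone in the configured radius", {
  widths <- vapply(c(6, 9, 12), function(r) {
    ph <- generatePhantom(smallConfig(vesselRadiusPx = r))
    mask <- extractVesselMask(ph$sequence)
    cl <- extractCenterline(mask)
    diameterMm(measureDiameter(ph$sequence, cl, 0.5))
  }, numeric(1L))
  expect_true(all(diff(widths) > 0))

  # proximal 12 px vs middle 9 px: proximal measurement must be larger
  ph <- generatePhantom(smallConfig(vesselRadiusPx = c(12, 9)))
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  dP <- measureDiameter(ph$sequence, cl, 0.1)
  dM <- measureDiameter(ph$sequence, cl, 0.5)
  expect_gt(diameterMm(dP), diameterMm(dM))
  expect_equal(dP@site, "proximal")
  expect_equal(dM@site, "middle")
})

test_that("expansion percentages follow the stented-diameter convention", {
  expect_equal(expansionPercent(4.698, 5.568), 18.5)
  expect_equal(expansionPercent(3.480, 5.394), 55.0)
  expect_equal(expansionPercent(3.14, 3.14), 0.0)
  expect_error(expansionPercent(0, 5), "positive")
})
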