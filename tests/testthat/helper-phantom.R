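# Shared fixtures and independent brute-force oracles.

# A small, fast noiseless straight-vessel phantom configuration.
smallConfig <- function(...) {
  defaults <- list(shape = c(96L, 420L), fps = 30, resolution = 0.2,
                   pathKind = "straight", vesselRadiusPx = 8,
                   bolusVelocity = 300, nPulses = 3L, pulsePeriodS = 0.4,
                   dispersionPxPerFrame = 0.5, sigma0Px = 40,
                   noiseSd = 0, pathMarginPx = 50, seed = 7L)
  do.call(phantomConfig, utils::modifyList(defaults, list(...)))
}

# Brute-force integer-lag cross-correlation between two inverted TICs:
# the lag L maximizing sum_t yP[t] * yD[t + L] over all valid overlaps.
bruteXcorrLag <- function(ticProx, ticDist) {
  yP <- max(ticValues(ticProx)) - ticValues(ticProx)
  yD <- max(ticValues(ticDist)) - ticValues(ticDist)
  n <- length(yP)
  lags <- (-(n - 1L)):(n - 1L)
  score <- vapply(lags, function(L) {
    t0 <- max(1L, 1L - L); t1 <- min(n, n - L)
    if (t1 < t0) return(-Inf)
    sum(yP[t0:t1] * yD[(t0:t1) + L])
  }, numeric(1L))
  lags[which.max(score)]
}

# Dijkstra over a skeleton pixel graph (8-connectivity, Euclidean weights),
# written independently of the package's igraph-based path extraction.
bruteLongestGeodesic <- function(skel) {
  idx <- which(skel)
  nr <- nrow(skel)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  id <- function(r, c) which(rr == r & cc == c)
  nbrs <- lapply(seq_len(n), function(i) {
    out <- integer(0L); w <- numeric(0L)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      j <- id(rr[i] + dr, cc[i] + dc)
      if (length(j)) { out <- c(out, j); w <- c(w, sqrt(dr^2 + dc^2)) }
    }
    list(j = out, w = w)
  })
  ends <- which(vapply(nbrs, function(x) length(x$j), integer(1L)) == 1L)
  dijkstra <- function(src) {
    dist <- rep(Inf, n); dist[src] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u]) || all(done)) break
      done[u] <- TRUE
      for (k in seq_along(nbrs[[u]]$j)) {
        v <- nbrs[[u]]$j[k]
        alt <- dist[u] + nbrs[[u]]$w[k]
        if (alt < dist[v]) dist[v] <- alt
      }
      if (all(done | !is.finite(dist))) break
    }
    dist
  }
  best <- c(NA_integer_, NA_integer_); bestLen <- -Inf
  for (e in ends) {
    d <- dijkstra(e)
    for (f in ends) {
      if (is.finite(d[f]) && d[f] > bestLen) {
        bestLen <- d[f]; best <- c(e, f)
      }
    }
  }
  list(length = bestLen,
       from = c(rr[best[1L]], cc[best[1L]]),
       to = c(rr[best[2L]], cc[best[2L]]))
}

# max perpendicular distance from each point in `pts` to the polyline `poly`
maxDistToPolyline <- function(pts, poly) {
  segD <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- max(0, min(1, t))
    sqrt(sum((p - (a + t * ab))^2))
  }
  worst <- 0
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    # candidate segments near p only (speed): nearest polyline vertex +- 10
    j <- which.min((poly[, 1L] - p[1L])^2 + (poly[, 2L] - p[2L])^2)
    jj <- max(1L, j - 10L):min(nrow(poly) - 1L, j + 10L)
    d <- min(vapply(jj, function(k)
      segD(p, poly[k, ], poly[k + 1L, ]), numeric(1L)))
    worst <- max(worst, d)
  }
  worst
}

# truth centerline index nearest an image point
truthIndexNear <- function(truth, point) {
  pts <- centerlinePoints(truth)
  which.min((pts[, 1L] - point[1L])^2 + (pts[, 2L] - point[2L])^2)
}

# One parameter-recovery run on a noiseless or noisy straight phantom:
# returns the truth, the pipeline estimate and the frame-quantization band
# implied by the measured mean frame shift.
recoveryRun <- function(v, fpsv, noiseSd = 0, seed = 1L,
                        targetDtFrames = 6) {
  res <- 0.2
  vPxF <- v / (res * fpsv)
  sigma0 <- max(40, ceiling(0.7 * vPxF))
  lead <- 3.5 * sigma0
  dxPx <- round(targetDtFrames * vPxF)
  m <- ceiling((40 + lead) / vPxF)          # align ROI with pulse passage
  sP <- round(m * vPxF - lead)
  sD <- sP + dxPx
  margin <- 50
  cfg <- phantomConfig(shape = c(48L, as.integer(2 * margin + sD + 40)),
                       fps = fpsv, resolution = res,
                       vesselRadiusPx = 8, bolusVelocity = v,
                       nPulses = 3L, pulsePeriodS = 12 / fpsv,
                       dispersionPxPerFrame = 0.5, sigma0Px = sigma0,
                       noiseSd = noiseSd, pathMarginPx = margin,
                       seed = seed)
  ph <- generatePhantom(cfg)
  mask <- extractVesselMask(ph$sequence)
  cl <- extractCenterline(mask)
  cols <- centerlinePoints(cl)[, 2L]
  idx <- c(which.min(abs(cols - (margin + sP))),
           which.min(abs(cols - (margin + sD))))
  rois <- placeRois(cl, ph$sequence, "manual", indices = idx)
  dxMm <- arcDistance(cl, rois$proximal@centerIndex,
                      rois$distal@centerIndex, res)
  est <- estimateVelocity(computeTic(ph$sequence, rois$proximal),
                          computeTic(ph$sequence, rois$distal), dxMm)
  dtBar <- mean(est@perPeakDtFrames)
  list(truth = v, estimate = meanVelocity(est), dtBar = dtBar,
       band = c(dxMm * fpsv / (dtBar + 0.5), dxMm * fpsv / (dtBar - 0.5)),
       inBand = v >= dxMm * fpsv / (dtBar + 0.5) &
                v <= dxMm * fpsv / (dtBar - 0.5))
}
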