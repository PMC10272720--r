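# Zhang-Suen morphological thinning of a binary mask to a one-pixel-wide,
# 8-connected skeleton.  Vectorized over the whole image; converges in a
# number of passes proportional to the vessel half-width.

.shiftMat <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rsrc <- max(1L, 1L - dr):min(nrow(m), nrow(m) - dr)
  csrc <- max(1L, 1L - dc):min(ncol(m), ncol(m) - dc)
  out[rsrc + dr, csrc + dc] <- m[rsrc, csrc]
  out
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Zhang-Suen thinning: iteratively deletes border pixels that do not break
#' 8-connectivity until the mask is one pixel wide.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size, the skeleton.
#' @export
thinMask <- function(mask) {
  p <- mask
  storage.mode(p) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2..P9
      P2 <- .shiftMat(p, -1L,  0L); P3 <- .shiftMat(p, -1L,  1L)
      P4 <- .shiftMat(p,  0L,  1L); P5 <- .shiftMat(p,  1L,  1L)
      P6 <- .shiftMat(p,  1L,  0L); P7 <- .shiftMat(p,  1L, -1L)
      P8 <- .shiftMat(p,  0L, -1L); P9 <- .shiftMat(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (sub == 1L) {
        cond <- p & B >= 2L & B <= 6L & A == 1L &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- p & B >= 2L & B <= 6L & A == 1L &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# Build an igraph over skeleton pixels (8-connectivity, Euclidean edge
# weights) and return the ordered pixel path of the longest
# endpoint-to-endpoint geodesic.
.longestSkeletonPath <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 2L) stop("skeleton is empty or a single pixel")
  nr <- nrow(skel)
  ids <- matrix(0L, nrow(skel), ncol(skel))
  ids[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L

  edges <- NULL; weights <- NULL
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    r2 <- rr + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nrow(skel) & c2 >= 1L & c2 <= ncol(skel)
    ok[ok] <- skel[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    from <- ids[cbind(rr[ok], cc[ok])]
    to <- ids[cbind(r2[ok], c2[ok])]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(sqrt(sum(o^2)), sum(ok)))
  }
  if (is.null(edges)) stop("skeleton has no connected pixels")
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)

  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  inMain <- comp$membership == main

  deg <- igraph::degree(g)
  ends <- which(deg == 1L & inMain)
  if (!length(ends))
    stop("skeleton has no endpoints (closed loop); cannot order a centerline")
  dm <- igraph::distances(g, v = ends, to = ends, weights = weights)
  dm[!is.finite(dm)] <- -1
  best <- arrayInd(which.max(dm), dim(dm))
  vp <- igraph::shortest_paths(g, from = ends[best[1L]],
                               to = ends[best[2L]], weights = weights,
                               output = "vpath")$vpath[[1L]]
  v <- as.integer(vp)
  cbind(row = rr[v], col = cc[v])
}
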