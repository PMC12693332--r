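## Shared fixtures and independent oracles used across the suite.
## Oracles deliberately re-derive results by brute force / direct
## simulation, independent of the implementation paths they check.

## Small, fast phantom used by most tests.
tinyPhantomSpec <- function(...) {
  args <- list(rows = 96, cols = 96, nSlices = 5,
               endoRadiusPx = 14, epiRadiusPx = 24,
               scarSectors = data.frame(slice = 0:4, thetaStartDeg = 150,
                                        thetaEndDeg = 240, fStart = 0, fEnd = 1))
  user <- list(...)
  args[names(user)] <- user
  do.call(phantomSpec, args)
}

## Exhaustive between-class-variance maximization over all ordered triples
## up to the largest occupied bin, with the same plateau tolerance rule as
## the implementation (among triples within tol of the maximum, take the
## lexicographically smallest).
bruteForceMultiOtsu <- function(vals, tol = 1e-9) {
  bins <- pmin(pmax(as.integer(round(vals)), 0L), 255L)
  hi <- max(bins)
  bcv <- function(t) {
    g <- (bins > t[1]) + (bins > t[2]) + (bins > t[3])
    s <- 0
    for (k in 0:3) {
      w <- mean(g == k)
      if (w > 0) s <- s + w * mean(bins[g == k])^2
    }
    s
  }
  rows <- list()
  bestv <- -Inf
  for (t1 in 0:(hi - 2)) for (t2 in (t1 + 1):(hi - 1)) for (t3 in (t2 + 1):hi) {
    v <- bcv(c(t1, t2, t3))
    rows[[length(rows) + 1L]] <- c(t1, t2, t3, v)
    if (v > bestv) bestv <- v
  }
  M <- do.call(rbind, rows)
  M <- M[M[, 4] >= bestv - tol, , drop = FALSE]
  M <- M[order(M[, 1], M[, 2], M[, 3]), , drop = FALSE]
  as.numeric(M[1, 1:3])
}

## Literal step-by-step simulation of the adaptive region-growing rule:
## evaluate the 4-connected neighborhood of the region, admit the candidate
## with minimal |v - mean(region)| (ties by row, then col), update the
## mean, stop when the minimum exceeds maxDev.
simulateRegionGrow <- function(v, myo, seedRow, seedCol, maxDev) {
  nr <- nrow(v); nc <- ncol(v)
  region <- matrix(FALSE, nr, nc)
  region[seedRow, seedCol] <- TRUE
  repeat {
    cand <- NULL
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (region[r, cc] || !myo[r, cc]) next
      adj <- (r > 1 && region[r - 1, cc]) || (r < nr && region[r + 1, cc]) ||
        (cc > 1 && region[r, cc - 1]) || (cc < nc && region[r, cc + 1])
      if (adj) cand <- rbind(cand, c(r, cc))
    }
    if (is.null(cand)) break
    mu <- mean(v[region])
    dev <- abs(v[cand] - mu)
    i <- order(dev, cand[, 1], cand[, 2])[1]
    if (dev[i] > maxDev) break
    region[cand[i, 1], cand[i, 2]] <- TRUE
  }
  region
}

## Brute-force even-odd point-in-polygon: per-pixel crossing count, scalar.
bruteForceInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  out <- logical(length(px))
  for (q in seq_along(px)) {
    cnt <- 0L
    for (e in seq_len(n)) {
      a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
      if ((a[2] > py[q]) != (b[2] > py[q])) {
        xi <- (b[1] - a[1]) * (py[q] - a[2]) / (b[2] - a[2]) + a[1]
        if (px[q] < xi) cnt <- cnt + 1L
      }
    }
    out[q] <- cnt %% 2L == 1L
  }
  out
}

## Random star-shaped polygon around (cx, cy) with radii in [rMin, rMax].
randomStarPolygon <- function(cx, cy, rMin, rMax, nV = 12L) {
  ang <- sort(stats::runif(nV, 0, 2 * pi))
  r <- stats::runif(nV, rMin, rMax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

## Rotate a (x, y) coordinate matrix by 90 deg counterclockwise in the
## pixel frame of an n x n grid: (x, y) -> (n - 1 - y, x).
rotateXY90 <- function(xy, n) cbind(n - 1 - xy[, 2], xy[, 1])

## Rotate a matrix the same way: value at (row y, col x) moves to
## (row x, col n-1-y), i.e. t(m) with columns reversed.
rotateSlice90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
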