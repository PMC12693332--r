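## Planar geometry primitives shared by rasterization, phantom construction
## and the chord engine. All coordinates are continuous 0-based pixel
## coordinates (x = col, y = row); polygons are implicitly closed.

## Even-odd (crossing-number) point-in-polygon test, vectorized over points.
## Points exactly on an edge follow the half-open crossing rule; the pixel
## membership convention is "center-in decides" so no special casing.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  idx <- c(2:n, 1L)
  x2 <- poly[idx, 1]; y2 <- poly[idx, 2]
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xi <- (x2[e] - x1[e]) * (py[crosses] - y1[e]) / (y2[e] - y1[e]) + x1[e]
      hit <- px[crosses] < xi
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

## Proper-intersection test between all non-adjacent edge pairs; O(V^2)
## vectorized, adequate for contour-sized polygons.
polygonIsSimple <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(TRUE)
  idx <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[idx, 1]; by <- poly[idx, 2]
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  if (!nrow(pairs)) return(TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d1 <- (bx[i] - ax[i]) * (ay[j] - ay[i]) - (by[i] - ay[i]) * (ax[j] - ax[i])
  d2 <- (bx[i] - ax[i]) * (by[j] - ay[i]) - (by[i] - ay[i]) * (bx[j] - ax[i])
  d3 <- (bx[j] - ax[j]) * (ay[i] - ay[j]) - (by[j] - ay[j]) * (ax[i] - ax[j])
  d4 <- (bx[j] - ax[j]) * (by[i] - ay[j]) - (by[j] - ay[j]) * (bx[i] - ax[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

## Strict containment: every vertex of inner lies inside outer and no edges
## properly cross.
polygonInsidePolygon <- function(inner, outer) {
  if (!all(pointInPolygon(inner[, 1], inner[, 2], outer))) return(FALSE)
  ni <- nrow(inner); no <- nrow(outer)
  ii <- c(2:ni, 1L); oo <- c(2:no, 1L)
  for (e in seq_len(ni)) {
    a <- inner[e, ]; b <- inner[ii[e], ]
    d1 <- (b[1] - a[1]) * (outer[, 2] - a[2]) - (b[2] - a[2]) * (outer[, 1] - a[1])
    d2 <- (b[1] - a[1]) * (outer[oo, 2] - a[2]) - (b[2] - a[2]) * (outer[oo, 1] - a[1])
    d3 <- (outer[oo, 1] - outer[, 1]) * (a[2] - outer[, 2]) -
      (outer[oo, 2] - outer[, 2]) * (a[1] - outer[, 1])
    d4 <- (outer[oo, 1] - outer[, 1]) * (b[2] - outer[, 2]) -
      (outer[oo, 2] - outer[, 2]) * (b[1] - outer[, 1])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## Area centroid (shoelace); falls back to the vertex mean for degenerate
## (near-zero-area) polygons.
polygonCentroid <- function(poly) {
  n <- nrow(poly)
  idx <- c(2:n, 1L)
  x <- poly[, 1]; y <- poly[, 2]
  cr <- x * y[idx] - x[idx] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + x[idx]) * cr), sum((y + y[idx]) * cr)) / (6 * a)
}

## Intersections of the ray origin + t * dir (t > 0) with a polygon.
## Returns the sorted positive ray parameters t.
rayPolygonIntersections <- function(origin, dir, poly) {
  n <- nrow(poly)
  idx <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  ex <- poly[idx, 1] - ax; ey <- poly[idx, 2] - ay
  denom <- dir[1] * ey - dir[2] * ex
  ok <- abs(denom) > 1e-12
  t <- (((ax - origin[1]) * ey - (ay - origin[2]) * ex) / denom)[ok]
  u <- ((dir[1] * (ay - origin[2]) - dir[2] * (ax - origin[1])) / denom)[ok]
  keep <- t > 1e-9 & u >= 0 & u < 1
  sort(t[keep])
}

## Regular polygon approximating a circle; vertices counterclockwise in the
## (x, y) frame starting at angle 0.
circlePolygon <- function(cx, cy, r, nVertices = 256L) {
  phi <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  cbind(cx + r * cos(phi), cy + r * sin(phi))
}

## Angle of (x, y) about (cx, cy), degrees in [0, 360).
angleDeg <- function(x, y, cx, cy) {
  a <- atan2(y - cy, x - cx) * 180 / pi
  (a %% 360)
}

modDeg <- function(a) a %% 360

## 4-connected component labeling on a logical matrix (flood fill).
## Hand-rolled to pin the 4-connectivity the region-growing and seeding
## rules require.
connectedComponents4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(m)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nb <- integer()
      if (r > 1L) nb <- c(nb, p - 1L)
      if (r < nr) nb <- c(nb, p + 1L)
      if (cc > 1L) nb <- c(nb, p - nr)
      if (cc < nc) nb <- c(nb, p + nr)
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b logical arrays of identical dimensions (or [VoxelMask-class]
#'   objects).
#' @return `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "VoxelMask")) a <- a@mask
  if (is(b, "VoxelMask")) b <- b@mask
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

## Grids of 0-based pixel-center coordinates for one slice.
pixelGrid <- function(rows, cols) {
  list(x = matrix(rep(0:(cols - 1L), each = rows), rows, cols),
       y = matrix(rep(0:(rows - 1L), times = cols), rows, cols))
}
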