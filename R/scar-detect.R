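## Scar detection within the myocardium on black-blood LGE images:
## (a) multi-level Otsu thresholding (three thresholds, four classes) on
##     the myocardial intensity histogram;
## (b) seeded adaptive region growing with an evolving region mean;
## (c) an "external" plug-in slot accepting a precomputed mask or a
##     detector callable, where a learned model would sit.

## Comparison tolerance for between-class-variance ties: plateaus (e.g.
## runs of empty bins) must resolve to the lexicographically smallest
## triple regardless of floating-point summation order.
BCV_TOL <- 1e-9

#' Multi-level Otsu thresholds (three thresholds, four classes)
#'
#' Builds a 256-bin histogram of the supplied intensities (0-255 scale,
#' values rounded to the nearest bin) and finds the threshold triple
#' `0 <= t1 < t2 < t3 <= 255` maximizing the between-class variance of the
#' four classes `v <= t1`, `t1 < v <= t2`, `t2 < v <= t3`, `v > t3`.
#' Ties are broken by the lexicographically smallest triple.
#'
#' @param intensities numeric vector of myocardial pixel values on the
#'   0-255 scale (at least 4 distinct values).
#' @return numeric `c(t1, t2, t3)`.
#' @examples
#' v <- rep(c(10, 90, 170, 250), each = 50)
#' multiotsuThresholds(v)  # one spike per class
#' @export
multiotsuThresholds <- function(intensities) {
  stopifnot(is.numeric(intensities), length(intensities) > 0)
  bins <- pmin(pmax(as.integer(round(intensities)), 0L), 255L)
  if (length(unique(bins)) < 4L)
    stop("degenerate-histogram error: fewer than 4 distinct intensity values",
         call. = FALSE)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  P <- cumsum(p)              # P[b+1] = mass of bins 0..b
  M <- cumsum(p * lev)        # M[b+1] = first moment of bins 0..b
  Ptot <- P[256]; Mtot <- M[256]
  ## The lexicographically smallest maximizer has all four classes
  ## nonempty (splitting a class with two distinct occupied bins strictly
  ## increases the between-class variance), hence every threshold equals
  ## the largest occupied bin of its class: candidates are occupied bins.
  obs <- which(h > 0L) - 1L
  m <- length(obs)
  Po <- P[obs + 1L]; Mo <- M[obs + 1L]
  ## contribution of the class holding bins (obs[i], obs[j]]: w * mu^2
  cls <- function(Pa, Pb, Ma, Mb) {
    w <- Pb - Pa
    out <- (Mb - Ma)^2 / w
    out[w <= 0] <- 0
    out
  }
  C0 <- cls(0, Po, 0, Mo)                               # class (-inf, t1]
  C3 <- cls(Po, Ptot, Mo, Mtot)                         # class (t3, inf)
  Cij <- matrix(-Inf, m, m)                             # class (t_i, t_j]
  for (i in seq_len(m - 1L)) {
    j <- (i + 1L):m
    Cij[i, j] <- cls(Po[i], Po[j], Mo[i], Mo[j])
  }
  C23 <- Cij + matrix(C3, m, m, byrow = TRUE)           # t2 rows, t3 cols
  best <- -Inf
  bestT <- NULL
  for (i1 in seq_len(m - 2L)) {
    V <- C23 + Cij[i1, ]                                # adds C(t1, t2] per row
    V[seq_len(i1), ] <- -Inf
    vmax <- max(V)
    tot <- C0[i1] + vmax
    if (tot > best + BCV_TOL) {
      cand <- which(V >= vmax - BCV_TOL, arr.ind = TRUE)
      pick <- cand[order(cand[, 1], cand[, 2])[1], ]
      best <- tot
      bestT <- c(obs[i1], obs[pick[1]], obs[pick[2]])
    }
  }
  as.numeric(bestT)
}

#' Classify myocardial tissue by threshold intervals
#'
#' Within the myocardium, on the 0-255 working scale: `v <= t2` healthy,
#' `t2 < v <= t3` gray zone, `v > t3` scar; everything else is outside.
#' The two lowest Otsu intervals are merged into "healthy": the lowest
#' interval captures blood-suppressed near-zero signal, which is healthy
#' tissue for reporting purposes. The three-category map (plus outside) is
#' the clinical output.
#'
#' @param bl a BL [ImageStack-class] normalized to 0-255.
#' @param myo a [MyocardiumMask-class] on the same grid.
#' @param thr numeric `c(t1, t2, t3)` as from [multiotsuThresholds()].
#' @param method provenance tag stored in the map.
#' @return a [TissueClassMap-class] (0 outside, 1 healthy, 2 gray zone,
#'   3 scar).
#' @export
classifyTissue <- function(bl, myo, thr, method = "otsu") {
  if (!sameGeometry(bl@geometry, myo@geometry))
    stop("geometry mismatch between BL stack and myocardium mask", call. = FALSE)
  stopifnot(length(thr) == 3, thr[1] < thr[2], thr[2] < thr[3])
  ## compare on the same 256-bin quantization the thresholds were
  ## estimated on, so that threshold t and intensity bin t agree
  v <- pmin(pmax(round(bl@voxels), 0), 255)
  lab <- array(0L, dim(v))
  lab[myo@mask] <- 1L + (v[myo@mask] > thr[2]) + (v[myo@mask] > thr[3])
  new("TissueClassMap", labels = lab, thresholds = as.numeric(thr),
      method = method, geometry = bl@geometry)
}

#' Default region-growing seed per slice
#'
#' The seed is the gravity center of the largest 4-connected scar-class
#' component on the slice, snapped to the nearest pixel of that component
#' (Euclidean distance, ties broken in row-major order). Slices without
#' scar-class pixels yield no seed.
#'
#' @param classMap a [TissueClassMap-class].
#' @return a data.frame with columns slice (0-based), row, col (0-based
#'   pixel indices); one row per slice that has a seed.
#' @export
defaultSeed <- function(classMap) {
  out <- data.frame(slice = integer(), row = integer(), col = integer())
  for (k in seq_len(dim(classMap@labels)[3])) {
    scar <- classMap@labels[, , k] == 3L
    if (!any(scar)) next
    lab <- connectedComponents4(scar)
    sizes <- tabulate(lab[lab > 0L])
    big <- which.max(sizes)  # ties: smallest label = first in column-major scan
    idx <- which(lab == big, arr.ind = TRUE)
    cent <- colMeans(idx)
    d2 <- (idx[, 1] - cent[1])^2 + (idx[, 2] - cent[2])^2
    ## ties by row-major (row, then col) order
    ord <- order(d2, idx[, 1], idx[, 2])
    pick <- idx[ord[1], ]
    out <- rbind(out, data.frame(slice = k - 1L, row = pick[1] - 1L, col = pick[2] - 1L))
  }
  rownames(out) <- NULL
  out
}

growSlice <- function(v, myo, seedRow, seedCol, maxDeviation) {
  nr <- nrow(v); nc <- ncol(v)
  region <- matrix(FALSE, nr, nc)
  inCand <- matrix(FALSE, nr, nc)
  seedIdx <- (seedCol - 1L) * nr + seedRow
  region[seedIdx] <- TRUE
  total <- v[seedIdx]; n <- 1L
  cand <- integer()
  pushNeighbors <- function(p, cand) {
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    nb <- integer()
    if (r > 1L) nb <- c(nb, p - 1L)
    if (r < nr) nb <- c(nb, p + 1L)
    if (cc > 1L) nb <- c(nb, p - nr)
    if (cc < nc) nb <- c(nb, p + nr)
    nb <- nb[myo[nb] & !region[nb] & !inCand[nb]]
    inCand[nb] <<- TRUE
    c(cand, nb)
  }
  cand <- pushNeighbors(seedIdx, cand)
  while (length(cand)) {
    m <- total / n
    dev <- abs(v[cand] - m)
    ## ties broken by (row, col) order within the slice
    r <- ((cand - 1L) %% nr) + 1L
    cc <- ((cand - 1L) %/% nr) + 1L
    i <- order(dev, r, cc)[1]
    if (dev[i] > maxDeviation) break
    p <- cand[i]
    cand <- cand[-i]
    inCand[p] <- FALSE
    region[p] <- TRUE
    total <- total + v[p]; n <- n + 1L
    cand <- pushNeighbors(p, cand)
  }
  region
}

#' Seeded adaptive region growing
#'
#' Grows a region from a seed pixel, slice by slice: at each step the
#' 4-connected neighborhood of the current region (restricted to the
#' myocardium) is evaluated and the candidate pixel with minimal absolute
#' intensity deviation from the current region mean is admitted, after
#' which the mean is updated. Growth stops when that minimal deviation
#' exceeds `maxDeviation` or the myocardium is exhausted. Candidate ties
#' are broken by (slice, row, col) order.
#'
#' @param bl a BL [ImageStack-class] on the working intensity scale.
#' @param myo a [MyocardiumMask-class].
#' @param seeds data.frame with columns slice, row, col (0-based) as from
#'   [defaultSeed()], or a single `c(slice, row, col)` vector.
#' @param maxDeviation maximum allowed absolute deviation from the region
#'   mean, intensity units on the working scale (default 25).
#' @return a [ScarMask-class] (union of the per-slice regions).
#' @export
regionGrow <- function(bl, myo, seeds, maxDeviation = 25) {
  stopifnot(maxDeviation >= 0)
  if (!sameGeometry(bl@geometry, myo@geometry))
    stop("geometry mismatch between BL stack and myocardium mask", call. = FALSE)
  if (is.numeric(seeds) && length(seeds) == 3L)
    seeds <- data.frame(slice = seeds[1], row = seeds[2], col = seeds[3])
  out <- array(FALSE, dim(bl@voxels))
  for (i in seq_len(nrow(seeds))) {
    k <- seeds$slice[i] + 1L
    r <- seeds$row[i] + 1L
    cc <- seeds$col[i] + 1L
    if (!myo@mask[r, cc, k])
      stop(sprintf("seed error: seed (%d, %d, %d) lies outside the myocardium",
                   seeds$slice[i], seeds$row[i], seeds$col[i]), call. = FALSE)
    out[, , k] <- out[, , k] |
      growSlice(bl@voxels[, , k], myo@mask[, , k], r, cc, maxDeviation)
  }
  scarMask(out, bl@geometry)
}

#' Detect scar within the myocardium
#'
#' Dispatches on the detection method:
#' \describe{
#'   \item{`otsu`}{stretches the BL stack to 0-255 ([normalize255()]),
#'     computes multi-level Otsu thresholds on the myocardial pixels only,
#'     and returns the scar class as the mask plus the full
#'     [TissueClassMap-class].}
#'   \item{`region_growing`}{same working scale; seeds default to the
#'     gravity center of the largest scar-class component per slice (or a
#'     user-supplied seed) and grows with `maxDeviation`.}
#'   \item{`external`}{accepts a precomputed mask (file path, logical
#'     array or [ScarMask-class]) or a detector `function(bl, myo)`;
#'     validates containment in the myocardium.}
#' }
#'
#' @param pair a [CoRegisteredPair-class] (detection runs on the BL stack).
#' @param myo a [MyocardiumMask-class].
#' @param method one of `"otsu"`, `"region_growing"`, `"external"`.
#' @param maxDeviation region-growing stop criterion (0-255 scale).
#' @param seeds optional user seeds for region growing (see [regionGrow()]).
#' @param external mask / path / callable for `method = "external"`.
#' @param stretchPercentiles passed to [normalize255()].
#' @return a list with elements `scar` (a [ScarMask-class]), `classMap`
#'   (a [TissueClassMap-class] or `NULL`), `thresholds`, `seeds`.
#' @export
detectScar <- function(pair, myo, method = c("otsu", "region_growing", "external"),
                       maxDeviation = 25, seeds = NULL, external = NULL,
                       stretchPercentiles = c(1, 99)) {
  method <- match.arg(method)
  bl <- pair@bl
  if (!sameGeometry(bl@geometry, myo@geometry))
    stop("geometry mismatch between pair and myocardium mask", call. = FALSE)
  if (method == "external") {
    mask <- external
    if (is.function(mask)) mask <- mask(bl, myo)
    if (is.character(mask)) mask <- readMask(mask, "scar", bl@geometry)
    if (is.array(mask) || is.matrix(mask)) mask <- scarMask(mask != 0, bl@geometry)
    if (!is(mask, "ScarMask"))
      stop("external detector must yield a scar mask", call. = FALSE)
    if (any(mask@mask & !myo@mask))
      stop("containment error: external scar mask is not a subset of the myocardium",
           call. = FALSE)
    return(list(scar = mask, classMap = NULL, thresholds = NULL, seeds = NULL))
  }
  work <- normalize255(bl, stretchPercentiles, mask = myo@mask)
  thr <- multiotsuThresholds(work@voxels[myo@mask])
  classMap <- classifyTissue(work, myo, thr, method = method)
  if (method == "otsu") {
    mask <- scarMask(classMap@labels == 3L, bl@geometry)
    return(list(scar = mask, classMap = classMap, thresholds = thr, seeds = NULL))
  }
  if (is.null(seeds)) seeds <- defaultSeed(classMap)
  if (is.numeric(seeds) && length(seeds) == 3L)
    seeds <- data.frame(slice = seeds[1], row = seeds[2], col = seeds[3])
  if (nrow(seeds) == 0)
    return(list(scar = scarMask(array(FALSE, dim(bl@voxels)), bl@geometry),
                classMap = classMap, thresholds = thr, seeds = seeds))
  mask <- regionGrow(work, myo, seeds, maxDeviation)
  list(scar = mask, classMap = classMap, thresholds = thr, seeds = seeds)
}
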