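## Landmark-driven quantification: AHA 16-segment partition with
## per-segment scar extent, mid-wall centerline with 100 chords per slice
## and per-chord transmurality, and the global volume/mass/extent metrics.
##
## Angular conventions (fixed for cross-case comparability): angles are
## degrees counterclockwise from the +x axis in the (x, y) pixel frame;
## sector numbering and chord 1 are anchored at the anterior RV insertion
## ray and proceed counterclockwise; a pixel exactly on a boundary angle
## belongs to the counterclockwise-following sector.

#' Assign anatomical levels to slices
#'
#' Slices containing myocardium are split into three contiguous groups --
#' base, mid, apex -- by terciles of slice index, remainder slices
#' distributed base-first. By default the lowest slice indices are basal
#' (`basalFirst = TRUE`). An explicit per-slice override is accepted
#' verbatim.
#'
#' @param myo a [MyocardiumMask-class].
#' @param override optional character vector (one of base/mid/apex/none per
#'   slice), used verbatim.
#' @param basalFirst if `FALSE`, the highest indices are basal.
#' @return character vector, one level per slice ("none" for slices without
#'   myocardium).
#' @export
assignLevels <- function(myo, override = NULL, basalFirst = TRUE) {
  ns <- myo@geometry@nSlices
  if (!is.null(override)) {
    stopifnot(length(override) == ns, all(override %in% c("base", "mid", "apex", "none")))
    return(override)
  }
  usable <- which(apply(myo@mask, 3, any))
  n <- length(usable)
  if (n < 3L)
    stop(sprintf("level-assignment error: %d slices contain myocardium, need at least 3", n),
         call. = FALSE)
  q <- n %/% 3L; r <- n %% 3L
  counts <- c(q + (r >= 1L), q + (r >= 2L), q)
  lv <- rep(c("base", "mid", "apex"), counts)
  if (!basalFirst) lv <- rev(lv)
  out <- rep("none", ns)
  out[usable] <- lv
  out
}

#' Angular sector boundaries from the RV insertion landmarks
#'
#' For basal and mid-ventricular slices (6 sectors): the two landmark rays
#' bound the septal arc (counterclockwise from anterior to inferior); its
#' bisector is the midline splitting it into 2 sectors, and the
#' complementary arc is split into 4 equal sectors. For apical slices
#' (4 sectors): the two boundaries are the landmark direction vectors
#' reversed (pointing away from the septum), together with the septal-arc
#' bisector and its reverse.
#'
#' @param anterior,inferior landmark coordinates `c(x, y)` (0-based pixels).
#' @param centroid LV center `c(x, y)` (endocardial contour centroid).
#' @param level `"base"`, `"mid"` or `"apex"`.
#' @return boundary angles in degrees, ordered counterclockwise starting at
#'   the boundary closest after the anterior landmark ray (6 for base/mid,
#'   4 for apex).
#' @examples
#' sectorBoundaries(c(2, 0), c(0, 2), c(0, 0), "base")
#' # 60/120-degree landmarks: c(60, 90, 120, 195, 270, 345)
#' @export
sectorBoundaries <- function(anterior, inferior, centroid, level = c("base", "mid", "apex")) {
  level <- match.arg(level)
  a <- angleDeg(anterior[1], anterior[2], centroid[1], centroid[2])
  b <- angleDeg(inferior[1], inferior[2], centroid[1], centroid[2])
  if (isTRUE(all.equal(modDeg(a - b), 0)))
    stop("landmark error: anterior and inferior rays coincide", call. = FALSE)
  wAB <- modDeg(b - a)
  mid <- modDeg(a + wAB / 2)
  if (level == "apex") {
    bounds <- c(modDeg(a + 180), modDeg(b + 180), mid, modDeg(mid + 180))
  } else {
    bounds <- c(a, mid, b, modDeg(b + (360 - wAB) / 4 * (1:3)))
  }
  bounds[order(modDeg(bounds - a))]
}

nearestLandmarkSlice <- function(landmarks, k) {
  ok <- which(stats::complete.cases(landmarks@anterior) &
                stats::complete.cases(landmarks@inferior))
  if (!length(ok))
    stop("missing landmarks with no propagation source", call. = FALSE)
  ok[order(abs(ok - k), ok)][1]
}

lvCentroid <- function(contours, myoSlice, k) {
  if (!is.null(contours) && k <= length(contours@slices) && !is.null(contours@slices[[k]]))
    return(polygonCentroid(contours@slices[[k]]$endo))
  idx <- which(myoSlice, arr.ind = TRUE)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
}

#' Build the AHA 16-segment label map
#'
#' Assigns every myocardial pixel of each quantified slice to the angular
#' sector containing its angle about the LV centroid. Numbering: basal
#' slices carry segments 1-6, mid 7-12, apical 13-16, counting
#' counterclockwise from the anterior insertion ray. Landmarks missing on a
#' slice are propagated from the nearest slice that has them.
#'
#' @param myo a [MyocardiumMask-class].
#' @param landmarks a [LandmarkSet-class].
#' @param levels per-slice levels as from [assignLevels()].
#' @param contours optional [ContourSet-class]; when given, the LV centroid
#'   is the endocardial contour centroid (otherwise the myocardial pixel
#'   centroid).
#' @return a [SegmentMap-class].
#' @export
buildSegmentMap <- function(myo, landmarks, levels = assignLevels(myo), contours = NULL) {
  g <- myo@geometry
  lab <- array(0L, dim(myo@mask))
  bounds <- vector("list", g@nSlices)
  gr <- pixelGrid(g@rows, g@cols)
  offsetFor <- c(base = 0L, mid = 6L, apex = 12L)
  for (k in seq_len(g@nSlices)) {
    if (levels[k] == "none") next
    sl <- myo@mask[, , k]
    if (!any(sl)) next
    lk <- nearestLandmarkSlice(landmarks, k)
    ctr <- lvCentroid(contours, sl, k)
    bd <- sectorBoundaries(landmarks@anterior[lk, ], landmarks@inferior[lk, ],
                           ctr, levels[k])
    bounds[[k]] <- bd
    th <- angleDeg(gr$x[sl], gr$y[sl], ctr[1], ctr[2])
    rel <- modDeg(th - bd[1])
    relBounds <- modDeg(bd - bd[1])
    sector <- findInterval(rel, c(relBounds, 360))
    m <- matrix(0L, g@rows, g@cols)
    m[sl] <- offsetFor[[levels[k]]] + sector
    lab[, , k] <- m
  }
  new("SegmentMap", labels = lab, levels = levels, boundaries = bounds, geometry = g)
}

#' Per-segment scar extent
#'
#' Scar pixel percentage per AHA segment: 100 x scar pixels / total
#' myocardial pixels in the segment, summed over the slices of that level.
#' Segments without myocardial pixels are reported with `NA` percent
#' (missing, not zero).
#'
#' @param scar a [ScarMask-class] (must be contained in the segmented
#'   myocardium).
#' @param segmap a [SegmentMap-class].
#' @return a [SegmentExtent-class].
#' @export
segmentExtent <- function(scar, segmap) {
  if (!sameGeometry(scar@geometry, segmap@geometry))
    stop("geometry mismatch between scar mask and segment map", call. = FALSE)
  quantified <- segmap@levels != "none"
  sl <- slice.index(scar@mask, 3)
  active <- quantified[sl]
  if (any(scar@mask & active & segmap@labels == 0L))
    stop("containment error: scar mask is not a subset of the segmented myocardium",
         call. = FALSE)
  total <- tabulate(segmap@labels[segmap@labels > 0L], nbins = 16L)
  sc <- tabulate(segmap@labels[scar@mask & segmap@labels > 0L], nbins = 16L)
  ext <- data.frame(segment = 1:16,
                    level = rep(c("base", "mid", "apex"), c(6, 6, 4)),
                    scarPx = sc, totalPx = total,
                    percent = ifelse(total > 0, 100 * sc / total, NA_real_))
  new("SegmentExtent", extents = ext)
}

#' Build the mid-wall centerline and its 100 chords
#'
#' For each contoured slice, the centerline is sampled at `nChords`
#' positions equally spaced in angle about the LV centroid, starting at the
#' anterior insertion ray and proceeding counterclockwise; the centerline
#' point at angle theta is the midpoint of the endocardial and epicardial
#' intersections of the ray at theta. Each chord is perpendicular to the
#' local centerline tangent (central difference over neighboring centerline
#' points) and extends from its endocardial to its epicardial intersection;
#' its thickness is the physical distance between the two intersections.
#'
#' @param contours a [ContourSet-class].
#' @param landmarks a [LandmarkSet-class] (angular origin; propagated from
#'   the nearest slice when missing).
#' @param geom the [ImageGeometry-class].
#' @param nChords chords per slice (100).
#' @return a [ChordSet-class].
#' @export
buildCenterlineChords <- function(contours, landmarks, geom, nChords = 100L) {
  rows <- list()
  for (k in seq_along(contours@slices)) {
    s <- contours@slices[[k]]
    if (is.null(s)) next
    lk <- nearestLandmarkSlice(landmarks, k)
    ctr <- polygonCentroid(s$endo)
    a0 <- angleDeg(landmarks@anterior[lk, 1], landmarks@anterior[lk, 2], ctr[1], ctr[2])
    theta <- modDeg(a0 + 360 / nChords * (seq_len(nChords) - 1L))
    rad <- theta * pi / 180
    centerline <- matrix(NA_real_, nChords, 2)
    endoRay <- matrix(NA_real_, nChords, 2)
    epiRay <- matrix(NA_real_, nChords, 2)
    for (j in seq_len(nChords)) {
      dirj <- c(cos(rad[j]), sin(rad[j]))
      tEn <- rayPolygonIntersections(ctr, dirj, s$endo)
      tEp <- rayPolygonIntersections(ctr, dirj, s$epi)
      if (!length(tEn) || !length(tEp))
        stop(sprintf("geometry error: ray at %.1f deg (slice %d) misses a contour",
                     theta[j], k - 1L), call. = FALSE)
      endoRay[j, ] <- ctr + max(tEn) * dirj
      epiRay[j, ] <- ctr + max(tEp) * dirj
      centerline[j, ] <- (endoRay[j, ] + epiRay[j, ]) / 2
    }
    nxt <- c(2:nChords, 1L); prv <- c(nChords, 1:(nChords - 1L))
    for (j in seq_len(nChords)) {
      tang <- centerline[nxt[j], ] - centerline[prv[j], ]
      nrm <- c(-tang[2], tang[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      if (sum(nrm * (centerline[j, ] - ctr)) < 0) nrm <- -nrm
      sEn <- rayPolygonIntersections(centerline[j, ], -nrm, s$endo)
      sEp <- rayPolygonIntersections(centerline[j, ], nrm, s$epi)
      if (!length(sEn) || !length(sEp))
        stop(sprintf("geometry error: chord at %.1f deg (slice %d) misses a contour",
                     theta[j], k - 1L), call. = FALSE)
      pEn <- centerline[j, ] - min(sEn) * nrm
      pEp <- centerline[j, ] + min(sEp) * nrm
      thick <- sqrt(((pEp[1] - pEn[1]) * geom@spacingMm[1])^2 +
                      ((pEp[2] - pEn[2]) * geom@spacingMm[2])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = k - 1L, chord = j, angleDeg = theta[j],
        cx = centerline[j, 1], cy = centerline[j, 2],
        dirX = nrm[1], dirY = nrm[2],
        endoX = pEn[1], endoY = pEn[2], epiX = pEp[1], epiY = pEp[2],
        thicknessMm = thick)
    }
  }
  new("ChordSet", chords = do.call(rbind, rows), geometry = geom)
}

#' Per-chord scar transmurality
#'
#' Each chord segment is sampled at `stepPx`-pixel sub-steps from its
#' endocardial to its epicardial endpoint (nearest-pixel lookup); the
#' transmurality is the scar thickness over the wall thickness along the
#' chord, i.e. the fraction of within-wall samples falling inside the scar
#' mask, clamped to [0, 1]. Restricting the denominator to within-wall
#' samples keeps boundary samples that round into the cavity or outside
#' the epicardium from diluting the ratio. When no myocardium mask is
#' supplied all samples count.
#'
#' @param scar a [ScarMask-class].
#' @param chords a [ChordSet-class] on the same geometry.
#' @param myo optional [MyocardiumMask-class] restricting the denominator.
#' @param stepPx sampling step along the chord, in pixels.
#' @return a [TransmuralityProfile-class].
#' @export
chordTransmurality <- function(scar, chords, myo = NULL, stepPx = 0.25) {
  cb <- chords@chords
  g <- scar@geometry
  tv <- numeric(nrow(cb))
  for (i in seq_len(nrow(cb))) {
    len <- sqrt((cb$epiX[i] - cb$endoX[i])^2 + (cb$epiY[i] - cb$endoY[i])^2)
    npts <- max(2L, as.integer(ceiling(len / stepPx)) + 1L)
    t <- seq(0, 1, length.out = npts)
    x <- cb$endoX[i] + t * (cb$epiX[i] - cb$endoX[i])
    y <- cb$endoY[i] + t * (cb$epiY[i] - cb$endoY[i])
    r <- pmin(pmax(as.integer(round(y)) + 1L, 1L), g@rows)
    cc <- pmin(pmax(as.integer(round(x)) + 1L, 1L), g@cols)
    idx <- cbind(r, cc, cb$slice[i] + 1L)
    inScar <- scar@mask[idx]
    if (!is.null(myo)) {
      inWall <- myo@mask[idx]
      tv[i] <- if (any(inWall)) sum(inScar & inWall) / sum(inWall) else 0
    } else {
      tv[i] <- mean(inScar)
    }
    tv[i] <- min(max(tv[i], 0), 1)
  }
  new("TransmuralityProfile",
      values = data.frame(slice = cb$slice, chord = cb$chord,
                          angleDeg = cb$angleDeg, transmurality = tv))
}

#' Per-slice transmurality summary
#' @param profile a [TransmuralityProfile-class].
#' @return data.frame with per-slice mean and max transmurality.
#' @export
profileSummary <- function(profile) {
  v <- profile@values
  agg <- aggregate(transmurality ~ slice, v,
                   function(z) c(mean = mean(z), max = max(z)))
  data.frame(slice = agg$slice, mean = agg$transmurality[, "mean"],
             max = agg$transmurality[, "max"])
}

#' Global scar metrics
#'
#' Volumes are voxel counts times the voxel volume (mm^3, reported in mL);
#' scar mass is the scar volume (cm^3) times the myocardial density
#' (1.05 g/cm^3 by default); extent is scar volume as a percentage of
#' myocardial volume; mean and max transmurality are taken over all chords
#' of all quantified slices.
#'
#' @param myo a [MyocardiumMask-class] (must be non-empty).
#' @param scar a [ScarMask-class].
#' @param profile a [TransmuralityProfile-class].
#' @param extents a [SegmentExtent-class].
#' @param densityGPerCm3 myocardial density for the mass.
#' @return a [ScarMetrics-class].
#' @export
globalMetrics <- function(myo, scar, profile, extents,
                          densityGPerCm3 = MYOCARDIAL_DENSITY_G_PER_CM3) {
  if (!sameGeometry(myo@geometry, scar@geometry))
    stop("geometry mismatch between myocardium and scar masks", call. = FALSE)
  myoPx <- sum(myo@mask)
  if (myoPx == 0) stop("empty myocardium", call. = FALSE)
  voxMm3 <- voxelVolumeMm3(myo@geometry)
  scarPx <- sum(scar@mask)
  tv <- profile@values$transmurality
  new("ScarMetrics",
      myocardialVolumeMl = myoPx * voxMm3 / 1000,
      scarVolumeMl = scarPx * voxMm3 / 1000,
      scarMassG = scarPx * voxMm3 / 1000 * densityGPerCm3,
      scarExtentPercent = 100 * scarPx / myoPx,
      meanTransmurality = if (length(tv)) mean(tv) else 0,
      maxTransmurality = if (length(tv)) max(tv) else 0,
      densityGPerCm3 = densityGPerCm3,
      segmentExtents = extents)
}
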