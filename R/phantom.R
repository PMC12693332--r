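## Synthetic co-registered BR/BL phantom with analytic ground truth.
##
## The phantom emulates the contrast regime of black-blood LGE: scar at the
## intensity ceiling (255), healthy myocardium in a dark 0-30 band, an
## optional gray-zone rim at mid-intensity (128); and of bright-blood LGE:
## bright blood pool, mid-gray myocardium. Geometry follows a typical
## short-axis acquisition (1.5 x 1.5 mm in-plane, 8 mm slices).

BL_SCAR <- 255
BL_RIM <- 128
BL_HEALTHY_BASE <- 15   # healthy band is BL_HEALTHY_BASE +/- BL_HEALTHY_AMP
BL_HEALTHY_AMP <- 10    # deterministic angular texture, keeps >= 4 distinct values
BL_BACKGROUND <- 5
BR_BLOOD <- 230
BR_MYO <- 110
BR_BACKGROUND <- 40

#' Myocardial tissue density used for scar mass
#'
#' Conventional myocardial density, 1.05 g/cm^3. Configurable wherever a
#' mass is computed.
#' @export
MYOCARDIAL_DENSITY_G_PER_CM3 <- 1.05

#' Specify a synthetic phantom case
#'
#' Builds a validated [PhantomSpec-class]. Scar regions are annular sectors:
#' each row of `scarSectors` names a slice (0-based), an angular interval in
#' degrees (counterclockwise from `thetaStartDeg` to `thetaEndDeg`) and a
#' radial interval expressed as fractions of the wall depth (0 =
#' endocardium, 1 = epicardium), so `fStart = 0, fEnd = 1` is a transmural
#' scar and `fStart = 0, fEnd = 0.5` a subendocardial half-wall scar.
#'
#' @param rows,cols,nSlices grid dimensions.
#' @param spacingMm,thicknessMm voxel geometry in mm.
#' @param endoRadiusPx,epiRadiusPx per-slice radii in pixels (recycled).
#' @param scarSectors data.frame with columns slice, thetaStartDeg,
#'   thetaEndDeg, fStart, fEnd; zero rows for a scar-free phantom.
#' @param grayZoneRimPx width (pixels) of the mid-intensity rim dilated
#'   around the scar.
#' @param noiseSd additive Gaussian noise SD on the 0-255 scale.
#' @param landmarkAnglesDeg anterior and inferior RV-insertion angles.
#' @param rngSeed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' sp <- phantomSpec(noiseSd = 0)
#' case <- generatePhantom(sp)
#' case@truthMetrics
#' @export
phantomSpec <- function(rows = 128, cols = 128, nSlices = 6,
                        spacingMm = c(1.5, 1.5), thicknessMm = 8,
                        endoRadiusPx = 18, epiRadiusPx = 30,
                        scarSectors = data.frame(
                          slice = 0:(nSlices - 1), thetaStartDeg = 150,
                          thetaEndDeg = 240, fStart = 0, fEnd = 1),
                        grayZoneRimPx = 2, noiseSd = 0,
                        landmarkAnglesDeg = c(60, 120), rngSeed = 42L) {
  new("PhantomSpec", rows = as.integer(rows), cols = as.integer(cols),
      nSlices = as.integer(nSlices), spacingMm = as.numeric(spacingMm),
      thicknessMm = as.numeric(thicknessMm),
      endoRadiusPx = rep_len(as.numeric(endoRadiusPx), nSlices),
      epiRadiusPx = rep_len(as.numeric(epiRadiusPx), nSlices),
      scarSectors = as.data.frame(scarSectors),
      grayZoneRimPx = as.numeric(grayZoneRimPx), noiseSd = as.numeric(noiseSd),
      landmarkAnglesDeg = as.numeric(landmarkAnglesDeg),
      rngSeed = as.integer(rngSeed))
}

phantomGeometry <- function(spec)
  imageGeometry(spec@rows, spec@cols, spec@nSlices, spec@spacingMm, spec@thicknessMm)

phantomCenter <- function(spec) c((spec@cols - 1) / 2, (spec@rows - 1) / 2)

## Pixel-center membership of the annular-sector scar construction for one
## slice, evaluated directly from the circle inequalities (independent of
## the polygon rasterizer).
phantomSliceMasks <- function(spec, k) {
  ctr <- phantomCenter(spec)
  gr <- pixelGrid(spec@rows, spec@cols)
  d <- sqrt((gr$x - ctr[1])^2 + (gr$y - ctr[2])^2)
  re <- spec@endoRadiusPx[k]; Re <- spec@epiRadiusPx[k]
  myo <- d > re & d <= Re
  cavity <- d <= re
  scar <- matrix(FALSE, spec@rows, spec@cols)
  ss <- spec@scarSectors
  ss <- ss[ss$slice == k - 1L, , drop = FALSE]
  if (nrow(ss)) {
    th <- angleDeg(gr$x, gr$y, ctr[1], ctr[2])
    f <- (d - re) / (Re - re)
    for (i in seq_len(nrow(ss))) {
      width <- modDeg(ss$thetaEndDeg[i] - ss$thetaStartDeg[i])
      inAngle <- modDeg(th - ss$thetaStartDeg[i]) < width
      scar <- scar | (myo & inAngle & f >= ss$fStart[i] & f <= ss$fEnd[i])
    }
  }
  list(myo = myo, cavity = cavity, scar = scar)
}

## Chebyshev dilation of a logical matrix by k steps (8-connectivity).
dilateChebyshev <- function(m, k) {
  if (k <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (step in seq_len(k)) {
    d <- out
    d[-1, ] <- d[-1, ] | out[-nr, ]
    d[-nr, ] <- d[-nr, ] | out[-1, ]
    d[, -1] <- d[, -1] | out[, -nc]
    d[, -nc] <- d[, -nc] | out[, -1]
    d[-1, -1] <- d[-1, -1] | out[-nr, -nc]
    d[-1, -nc] <- d[-1, -nc] | out[-nr, -1]
    d[-nr, -1] <- d[-nr, -1] | out[-1, -nc]
    d[-nr, -nc] <- d[-nr, -nc] | out[-1, -1]
    out <- d
  }
  out
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic co-registered phantom case
#'
#' Rasterizes the specified annulus geometry, paints BL and BR stacks from
#' the ground-truth masks (scar 255, gray rim 128, healthy myocardium a
#' deterministic dark band within 5-25, bright blood pool on BR), adds
#' seeded Gaussian noise clamped to [0, 255], and attaches the exact circle
#' contours, RV-insertion landmarks on the epicardial circle, truth masks
#' and analytically derived truth metrics.
#'
#' Identical spec and seed reproduce the case bit-for-bit.
#'
#' @param spec a [PhantomSpec-class] (see [phantomSpec()]).
#' @return a [PhantomCase-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  geom <- phantomGeometry(spec)
  ctr <- phantomCenter(spec)
  gr <- pixelGrid(spec@rows, spec@cols)
  th <- angleDeg(gr$x, gr$y, ctr[1], ctr[2])

  slices <- vector("list", spec@nSlices)
  ant <- matrix(NA_real_, spec@nSlices, 2)
  inf <- matrix(NA_real_, spec@nSlices, 2)
  for (k in seq_len(spec@nSlices)) {
    slices[[k]] <- list(endo = circlePolygon(ctr[1], ctr[2], spec@endoRadiusPx[k]),
                        epi = circlePolygon(ctr[1], ctr[2], spec@epiRadiusPx[k]))
    la <- spec@landmarkAnglesDeg * pi / 180
    ant[k, ] <- ctr + spec@epiRadiusPx[k] * c(cos(la[1]), sin(la[1]))
    inf[k, ] <- ctr + spec@epiRadiusPx[k] * c(cos(la[2]), sin(la[2]))
  }
  contours <- contourSet(slices)
  landmarks <- landmarkSet(ant, inf)

  ## truth myocardium through the pipeline rasterizer (the contours ARE the
  ## construction); truth scar restricted to it so downstream containment
  ## invariants hold exactly
  myoMask <- rasterizeMyocardium(contours, geom)

  bl <- array(BL_BACKGROUND, c(spec@rows, spec@cols, spec@nSlices))
  br <- array(BR_BACKGROUND, c(spec@rows, spec@cols, spec@nSlices))
  scarArr <- array(FALSE, c(spec@rows, spec@cols, spec@nSlices))
  healthyTexture <- BL_HEALTHY_BASE + BL_HEALTHY_AMP * cos(2 * th * pi / 180)
  rimSteps <- ceiling(spec@grayZoneRimPx)
  for (k in seq_len(spec@nSlices)) {
    mk <- phantomSliceMasks(spec, k)
    myo <- myoMask@mask[, , k]
    scar <- mk$scar & myo
    rim <- if (rimSteps > 0 && any(scar)) dilateChebyshev(scar, rimSteps) & myo & !scar
           else matrix(FALSE, spec@rows, spec@cols)
    blk <- matrix(BL_BACKGROUND, spec@rows, spec@cols)
    blk[myo] <- healthyTexture[myo]
    blk[rim] <- BL_RIM
    blk[scar] <- BL_SCAR
    brk <- matrix(BR_BACKGROUND, spec@rows, spec@cols)
    brk[myo] <- BR_MYO
    brk[mk$cavity] <- BR_BLOOD
    bl[, , k] <- blk
    br[, , k] <- brk
    scarArr[, , k] <- scar
  }
  if (spec@noiseSd > 0) {
    n <- length(bl)
    noise <- withSeed(spec@rngSeed, rnorm(2L * n, sd = spec@noiseSd))
    bl <- pmin(pmax(bl + noise[seq_len(n)], 0), 255)
    br <- pmin(pmax(br + noise[n + seq_len(n)], 0), 255)
  }

  pair <- coRegisteredPair(
    br = new("ImageStack", voxels = br, geometry = geom, contrast = "BR"),
    bl = new("ImageStack", voxels = bl, geometry = geom, contrast = "BL"))
  new("PhantomCase", pair = pair, contours = contours, landmarks = landmarks,
      truthMyocardium = myoMask, truthScar = scarMask(scarArr, geom),
      truthMetrics = truthMetricsAnalytic(spec), spec = spec)
}

## Independent re-statement of the sector-boundary rule used for truth
## segment extents (kept local so truth metrics do not route through the
## quantification engine).
phantomSectorBoundaries <- function(a, b, level) {
  wAB <- modDeg(b - a)
  m <- modDeg(a + wAB / 2)
  if (level == "apex") {
    bounds <- c(modDeg(a + 180), modDeg(b + 180), m, modDeg(m + 180))
  } else {
    rest <- 360 - wAB
    bounds <- c(a, m, b, modDeg(b + rest / 4 * (1:3)))
  }
  bounds[order(modDeg(bounds - a))]
}

phantomLevels <- function(nSlices) {
  q <- nSlices %/% 3L; r <- nSlices %% 3L
  counts <- c(q + (r >= 1L), q + (r >= 2L), q)
  rep(c("base", "mid", "apex"), counts)
}

#' Analytic truth metrics of a phantom specification
#'
#' Computes the ground-truth scar metrics directly from the construction,
#' without the detection or chord machinery: voxel counts by direct
#' circle-inequality membership tests at pixel centers, volumes as counts
#' times voxel volume, mass under the 1.05 g/cm^3 density convention,
#' chord transmurality from the radial-fraction construction (a chord at
#' angle theta inside a sector crosses exactly `fEnd - fStart` of the wall)
#' averaged over the continuous angle, and per-segment extents by direct
#' angular bookkeeping.
#'
#' @param spec a [PhantomSpec-class].
#' @param densityGPerCm3 myocardial density for the mass.
#' @return a [ScarMetrics-class].
#' @export
truthMetricsAnalytic <- function(spec, densityGPerCm3 = MYOCARDIAL_DENSITY_G_PER_CM3) {
  validObject(spec)
  voxMm3 <- spec@spacingMm[1] * spec@spacingMm[2] * spec@thicknessMm
  ctr <- phantomCenter(spec)
  gr <- pixelGrid(spec@rows, spec@cols)
  th <- angleDeg(gr$x, gr$y, ctr[1], ctr[2])
  levels <- phantomLevels(spec@nSlices)
  a <- spec@landmarkAnglesDeg[1]; b <- spec@landmarkAnglesDeg[2]

  myoPx <- 0L; scarPx <- 0L
  segScar <- integer(16); segTotal <- integer(16)
  sliceMeanT <- numeric(spec@nSlices)
  maxT <- 0
  for (k in seq_len(spec@nSlices)) {
    mk <- phantomSliceMasks(spec, k)
    myoPx <- myoPx + sum(mk$myo)
    scarPx <- scarPx + sum(mk$scar)
    lev <- levels[k]
    nSeg <- if (lev == "apex") 4L else 6L
    offset <- c(base = 0L, mid = 6L, apex = 12L)[[lev]]
    bounds <- phantomSectorBoundaries(a, b, lev)
    rel <- modDeg(th - bounds[1])
    relBounds <- modDeg(bounds - bounds[1])
    sector <- findInterval(rel, c(relBounds, 360), rightmost.closed = FALSE)
    for (s in seq_len(nSeg)) {
      inSeg <- sector == s
      segTotal[offset + s] <- segTotal[offset + s] + sum(mk$myo & inSeg)
      segScar[offset + s] <- segScar[offset + s] + sum(mk$scar & inSeg)
    }
    ss <- spec@scarSectors
    ss <- ss[ss$slice == k - 1L, , drop = FALSE]
    if (nrow(ss)) {
      w <- modDeg(ss$thetaEndDeg - ss$thetaStartDeg)
      sliceMeanT[k] <- sum(w / 360 * (ss$fEnd - ss$fStart))
      maxT <- max(maxT, ss$fEnd - ss$fStart)
    }
  }
  ext <- data.frame(segment = 1:16,
                    level = rep(c("base", "mid", "apex"), c(6, 6, 4)),
                    scarPx = segScar, totalPx = segTotal,
                    percent = ifelse(segTotal > 0, 100 * segScar / segTotal, NA_real_))
  myoMl <- myoPx * voxMm3 / 1000
  scarMl <- scarPx * voxMm3 / 1000
  new("ScarMetrics",
      myocardialVolumeMl = myoMl, scarVolumeMl = scarMl,
      scarMassG = scarMl * densityGPerCm3,
      scarExtentPercent = if (myoPx > 0) 100 * scarPx / myoPx else 0,
      meanTransmurality = mean(sliceMeanT),
      maxTransmurality = min(maxT, 1),
      densityGPerCm3 = densityGPerCm3,
      segmentExtents = new("SegmentExtent", extents = ext))
}

#' Phantom grid for parameter-recovery studies
#'
#' A grid of phantom specifications crossing scar transmurality
#' (0.25, 0.5, 0.75, 1.0), scar extent and noise (0 and 10 on the 0-255
#' scale). A subendocardial annular-sector scar of transmurality `T` in a
#' wall of inner radius `r` and thickness `w` cannot exceed an extent of
#' `100 T (2 r + T w) / (2 r + w)` percent even at full 360-degree
#' coverage, so the three extent levels per transmurality are 5 percent,
#' and half and 0.9 of the attainable maximum, capped at 25 and 50
#' percent: the grid spans 5-50 percent where the geometry admits it.
#'
#' @param noiseLevels noise SDs to cross with the scar grid.
#' @param seed base RNG seed; each case derives its own seed from it.
#' @return a list of [PhantomSpec-class] objects with attributes
#'   `transmurality`, `extent`, `noise` on each element.
#' @export
recoveryGridSpecs <- function(noiseLevels = c(0, 10), seed = 42L) {
  re <- 14; w <- 10
  ratio <- function(T) T * (2 * re + T * w) / (2 * re + w)
  specs <- list()
  for (T in c(0.25, 0.5, 0.75, 1.0)) {
    maxE <- 100 * ratio(T)
    for (E in c(5, min(0.5 * maxE, 25), min(0.9 * maxE, 50))) {
      for (ns in noiseLevels) {
        dth <- E / 100 * 360 / ratio(T)
        sp <- phantomSpec(rows = 96, cols = 96, nSlices = 5,
                          endoRadiusPx = re, epiRadiusPx = re + w,
                          scarSectors = data.frame(
                            slice = 0:4, thetaStartDeg = 150,
                            thetaEndDeg = 150 + dth, fStart = 0, fEnd = T),
                          noiseSd = ns,
                          rngSeed = (seed + round(1000 * T) + round(10 * E) + ns) %% .Machine$integer.max)
        attr(sp, "transmurality") <- T
        attr(sp, "extent") <- E
        attr(sp, "noise") <- ns
        specs[[length(specs) + 1L]] <- sp
      }
    }
  }
  specs
}

#' Quantify a phantom case through the full pipeline
#'
#' Convenience wrapper running detection and quantification on a generated
#' case (in memory, no file I/O) and returning the measured metrics
#' together with the analytic truth.
#'
#' @param case a [PhantomCase-class].
#' @param method detection method passed to [detectScar()].
#' @param ... further arguments to [detectScar()].
#' @return list with `metrics`, `truth`, `dice`, `detection`.
#' @export
quantifyPhantom <- function(case, method = "otsu", ...) {
  myo <- case@truthMyocardium
  det <- detectScar(case@pair, myo, method, ...)
  levels <- assignLevels(myo)
  segmap <- buildSegmentMap(myo, case@landmarks, levels, case@contours)
  extents <- segmentExtent(det$scar, segmap)
  chords <- buildCenterlineChords(case@contours, case@landmarks, geometry(myo))
  profile <- chordTransmurality(det$scar, chords, myo)
  metrics <- globalMetrics(myo, det$scar, profile, extents)
  list(metrics = metrics, truth = case@truthMetrics,
       dice = diceCoefficient(det$scar, case@truthScar), detection = det)
}

#' Write a phantom case to disk
#'
#' Serializes a [PhantomCase-class] in the pipeline's input formats: BR/BL
#' stacks as NIfTI, contours and landmarks as JSON, truth scar mask as
#' NIfTI, truth metrics as JSON.
#'
#' @param case a [PhantomCase-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStack(case@pair@br, file.path(dir, "br.nii.gz"))
  writeStack(case@pair@bl, file.path(dir, "bl.nii.gz"))
  writeContours(case@contours, file.path(dir, "contours.json"))
  writeLandmarks(case@landmarks, file.path(dir, "landmarks.json"))
  writeMask(case@truthScar, file.path(dir, "truth_scar.nii.gz"))
  jsonlite::write_json(metricsAsList(case@truthMetrics),
                       file.path(dir, "truth_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
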