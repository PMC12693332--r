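annulusMask <- function(n, nSlices, re, Re) {
  g <- imageGeometry(n, n, nSlices)
  ctr <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - ctr)^2, (0:(n - 1) - ctr)^2, "+"))
  m <- t(d) > re & t(d) <= Re  # symmetric, t() for clarity of (row,col)
  myocardiumMask(array(rep(m, nSlices), c(n, n, nSlices)), g)
}

test_that("level assignment follows base-first terciles", {
  m12 <- annulusMask(48, 12, 8, 16)
  lv <- assignLevels(m12)
  expect_equal(as.vector(table(factor(lv, c("base", "mid", "apex")))), c(4, 4, 4))
  expect_equal(lv[1], "base"); expect_equal(lv[12], "apex")

  m10 <- annulusMask(48, 10, 8, 16)
  lv10 <- assignLevels(m10)
  expect_equal(as.vector(table(factor(lv10, c("base", "mid", "apex")))), c(4, 3, 3))

  ov <- rep(c("apex", "mid", "base"), c(3, 3, 4))
  expect_identical(assignLevels(m10, override = ov), ov)

  m2 <- annulusMask(48, 2, 8, 16)
  expect_error(assignLevels(m2), "level-assignment error")
})

test_that("sector boundaries follow the landmark bisection rule", {
  ctr <- c(0, 0)
  ant <- 10 * c(cos(pi / 3), sin(pi / 3))       # 60 deg
  inf <- 10 * c(cos(2 * pi / 3), sin(2 * pi / 3))  # 120 deg
  # independent angle arithmetic: septal arc [60, 120] bisected at 90;
  # complementary 300-deg arc split into 4 equal 75-deg parts
  expected <- c(60, 90, 120, 120 + 75, 120 + 150, 120 + 225) %% 360
  got <- sectorBoundaries(ant, inf, ctr, "base")
  expect_equal(got, expected, tolerance = 1e-9)
  expect_length(got, 6)
  expect_length(sectorBoundaries(ant, inf, ctr, "mid"), 6)

  # apex: reversed landmark vectors plus the septal bisector axis
  apex <- sectorBoundaries(ant, inf, ctr, "apex")
  expect_length(apex, 4)
  expect_setequal(round(apex, 6), round(c(240, 300, 90, 270), 6))

  expect_error(sectorBoundaries(ant, ant, ctr, "base"), "landmark error")
})

test_that("rotating the landmarks rotates every boundary", {
  ctr <- c(0, 0)
  rot <- function(a) 10 * c(cos(a * pi / 180), sin(a * pi / 180))
  b0 <- sectorBoundaries(rot(60), rot(120), ctr, "base")
  b15 <- sectorBoundaries(rot(75), rot(135), ctr, "base")
  expect_equal(b15, (b0 + 15) %% 360, tolerance = 1e-9)
})

test_that("the segment map partitions the myocardium into the 16 AHA segments", {
  case <- generatePhantom(tinyPhantomSpec())
  myo <- case@truthMyocardium
  lv <- assignLevels(myo)
  sm <- buildSegmentMap(myo, case@landmarks, lv, case@contours)
  lab <- labelArray(sm)
  expect_identical(lab > 0L, maskArray(myo))
  expect_setequal(unique(lab[lab > 0]), 1:16)
  for (k in seq_len(nSlices(myo))) {
    labs <- unique(lab[, , k][lab[, , k] > 0])
    rng <- list(base = 1:6, mid = 7:12, apex = 13:16)[[lv[k]]]
    expect_true(all(labs %in% rng))
    expect_equal(length(labs), length(rng))
  }
})

test_that("per-segment extent counts pixels and flags empty segments", {
  case <- generatePhantom(tinyPhantomSpec())
  myo <- case@truthMyocardium
  sm <- buildSegmentMap(myo, case@landmarks, assignLevels(myo), case@contours)

  none <- scarMask(array(FALSE, dim(maskArray(myo))), geometry(myo))
  e0 <- extentTable(segmentExtent(none, sm))
  expect_true(all(e0$percent[e0$totalPx > 0] == 0))

  full <- scarMask(maskArray(myo), geometry(myo))
  e100 <- extentTable(segmentExtent(full, sm))
  expect_true(all(e100$percent[e100$totalPx > 0] == 100))

  et <- extentTable(segmentExtent(case@truthScar, sm))
  expect_equal(et$percent[et$totalPx > 0],
               100 * et$scarPx[et$totalPx > 0] / et$totalPx[et$totalPx > 0])
  expect_equal(sum(et$totalPx), sum(maskArray(myo)))
  expect_equal(sum(et$scarPx), sum(maskArray(case@truthScar)))

  # scar escaping the myocardium is a containment error
  out <- array(FALSE, dim(maskArray(myo))); out[1, 1, 1] <- TRUE
  expect_error(segmentExtent(scarMask(out, geometry(myo)), sm), "containment error")
})

test_that("concentric circles yield 100 radial chords of uniform thickness", {
  sp <- tinyPhantomSpec(endoRadiusPx = 14, epiRadiusPx = 24)
  case <- generatePhantom(sp)
  ch <- chordTable(buildCenterlineChords(case@contours, case@landmarks,
                                         geometry(case@pair@bl)))
  expect_true(all(table(ch$slice) == 100L))
  # wall 10 px at 1.5 mm spacing = 15 mm everywhere (polygonal contour
  # approximation stays well under 1%)
  expect_equal(ch$thicknessMm, rep(15, nrow(ch)), tolerance = 0.01)
  # radial: chord direction parallel to the centerline-to-centroid ray
  ctr <- c((sp@cols - 1) / 2, (sp@rows - 1) / 2)
  cosang <- abs((ch$cx - ctr[1]) * ch$dirX + (ch$cy - ctr[2]) * ch$dirY) /
    sqrt((ch$cx - ctr[1])^2 + (ch$cy - ctr[2])^2)
  expect_true(all(cosang > 0.999))
  # chord 1 starts at the anterior insertion ray
  expect_equal(ch$angleDeg[ch$chord == 1], rep(60, 5), tolerance = 1e-6)
})

test_that("elliptical walls: chord endpoints lie on the contours", {
  ellipse <- function(a, b, ctr) {
    t <- 2 * pi * (0:255) / 256
    cbind(ctr + a * cos(t), ctr + b * sin(t))
  }
  g <- imageGeometry(128, 128, 1)
  cs <- contourSet(list(list(endo = ellipse(40, 25, 63.5), epi = ellipse(55, 40, 63.5))))
  lm <- landmarkSet(cbind(63.5 + 55 * cos(pi / 3), 63.5 + 55 * sin(pi / 3) * 40 / 55),
                    cbind(63.5 + 55 * cos(2 * pi / 3), 63.5 + 40 * sin(2 * pi / 3)))
  ch <- chordTable(buildCenterlineChords(cs, lm, g))
  expect_equal(nrow(ch), 100L)
  # endpoint-on-contour: implicit ellipse equation within 0.5 px tolerance
  endoRes <- abs(sqrt(((ch$endoX - 63.5) / 40)^2 + ((ch$endoY - 63.5) / 25)^2) - 1)
  epiRes <- abs(sqrt(((ch$epiX - 63.5) / 55)^2 + ((ch$epiY - 63.5) / 40)^2) - 1)
  expect_lt(max(endoRes) * 40, 0.5)
  expect_lt(max(epiRes) * 55, 0.5)
  # thickness within 5% of a dense brute-force search along each chord line
  for (i in seq(1, 100, by = 7)) {
    s <- seq(-60, 60, by = 0.02)
    lx <- ch$cx[i] + s * ch$dirX[i]; ly <- ch$cy[i] + s * ch$dirY[i]
    fEndo <- ((lx - 63.5) / 40)^2 + ((ly - 63.5) / 25)^2 - 1
    fEpi <- ((lx - 63.5) / 55)^2 + ((ly - 63.5) / 40)^2 - 1
    # nearest sign change on each side of the centerline point
    sgn <- function(f, ss, side) {
      cross <- which(diff(sign(f)) != 0)
      sc <- ss[cross]
      if (side < 0) max(sc[sc < 0]) else min(sc[sc >= 0])
    }
    sEndo <- sgn(fEndo, s, -1)
    sEpi <- sgn(fEpi, s, +1)
    brute <- (sEpi - sEndo) * 1.5
    expect_lt(abs(ch$thicknessMm[i] - brute) / brute, 0.05)
  }
})

test_that("chord transmurality matches the phantom construction", {
  # transmural 90-deg sector: interior chords 1.0, exterior 0.0
  case <- generatePhantom(tinyPhantomSpec())
  ch <- buildCenterlineChords(case@contours, case@landmarks, geometry(case@pair@bl))
  pr <- profileTable(chordTransmurality(case@truthScar, ch, case@truthMyocardium))
  inside <- pr$transmurality[pr$angleDeg > 155 & pr$angleDeg < 235]
  outside <- pr$transmurality[pr$angleDeg < 145 | pr$angleDeg > 245]
  expect_true(all(inside == 1.0))
  expect_true(all(outside == 0.0))

  # no scar: all zero
  none <- scarMask(array(FALSE, dim(maskArray(case@truthScar))), geometry(case@pair@bl))
  expect_true(all(profileTable(chordTransmurality(none, ch, case@truthMyocardium))$transmurality == 0))

  # subendocardial half-wall: interior chords 0.50 +/- 0.05. A 20 px wall
  # keeps the half-pixel mask quantization per chord under the band.
  sp2 <- tinyPhantomSpec(endoRadiusPx = 16, epiRadiusPx = 36,
                         scarSectors = data.frame(
    slice = 0:4, thetaStartDeg = 150, thetaEndDeg = 240, fStart = 0, fEnd = 0.5))
  c2 <- generatePhantom(sp2)
  p2 <- profileTable(chordTransmurality(
    c2@truthScar, buildCenterlineChords(c2@contours, c2@landmarks, geometry(c2@pair@bl)),
    c2@truthMyocardium))
  int2 <- p2$transmurality[p2$angleDeg > 155 & p2$angleDeg < 235]
  expect_true(all(abs(int2 - 0.5) <= 0.05))
})

test_that("global metrics follow the voxel arithmetic", {
  g <- imageGeometry(50, 50, 1)  # voxel 18 mm^3
  myoM <- array(FALSE, c(50, 50, 1)); myoM[seq_len(1000)] <- TRUE
  scarM <- array(FALSE, c(50, 50, 1)); scarM[seq_len(100)] <- TRUE
  prof <- new("TransmuralityProfile",
              values = data.frame(slice = 0, chord = 1:4, angleDeg = 1:4,
                                  transmurality = c(0, 0.5, 1, 0.5)))
  ext <- segmentExtentStub <- new("SegmentExtent", extents = data.frame(
    segment = 1:16, level = rep(c("base", "mid", "apex"), c(6, 6, 4)),
    scarPx = 0L, totalPx = 1L, percent = 0))
  m <- globalMetrics(myocardiumMask(myoM, g), scarMask(scarM, g), prof, ext)
  expect_equal(m@myocardialVolumeMl, 18)
  expect_equal(m@scarVolumeMl, 1.8)
  expect_equal(m@scarMassG, 1.89)
  expect_equal(m@scarExtentPercent, 10)
  expect_equal(m@meanTransmurality, 0.5)
  expect_equal(m@maxTransmurality, 1)
  empty <- myocardiumMask(array(FALSE, c(50, 50, 1)), g)
  expect_error(globalMetrics(empty, scarMask(scarM, g), prof, ext), "empty myocardium")
})

test_that("pipeline metrics agree with analytic truth on the noise-free phantom", {
  sp <- tinyPhantomSpec()
  case <- generatePhantom(sp)
  myo <- case@truthMyocardium
  det <- detectScar(case@pair, myo, "otsu")
  sm <- buildSegmentMap(myo, case@landmarks, assignLevels(myo), case@contours)
  ext <- segmentExtent(det$scar, sm)
  ch <- buildCenterlineChords(case@contours, case@landmarks, geometry(myo))
  pr <- chordTransmurality(det$scar, ch, myo)
  m <- globalMetrics(myo, det$scar, pr, ext)
  tm <- case@truthMetrics
  voxMl <- 18 / 1000
  expect_lte(abs(m@scarVolumeMl - tm@scarVolumeMl), voxMl)
  expect_lte(abs(m@myocardialVolumeMl - tm@myocardialVolumeMl), voxMl)
  expect_lt(abs(m@meanTransmurality - tm@meanTransmurality), 0.05)
})

test_that("rotating the case by 90 degrees permutes segments and preserves values", {
  sp <- tinyPhantomSpec()
  case <- generatePhantom(sp)
  myo <- case@truthMyocardium
  n <- sp@rows
  sm <- buildSegmentMap(myo, case@landmarks, assignLevels(myo), case@contours)
  e <- extentTable(segmentExtent(case@truthScar, sm))

  rotArr <- function(a) {
    out <- array(FALSE, dim(a))
    for (k in seq_len(dim(a)[3])) out[, , k] <- rotateSlice90(a[, , k])
    out
  }
  myoR <- myocardiumMask(rotArr(maskArray(myo)), geometry(myo))
  scarR <- scarMask(rotArr(maskArray(case@truthScar)), geometry(myo))
  csR <- contourSet(lapply(case@contours@slices, function(s)
    list(endo = rotateXY90(s$endo, n), epi = rotateXY90(s$epi, n))))
  lmR <- landmarkSet(rotateXY90(case@landmarks@anterior, n),
                     rotateXY90(case@landmarks@inferior, n))
  smR <- buildSegmentMap(myoR, lmR, assignLevels(myoR), csR)
  eR <- extentTable(segmentExtent(scarR, smR))
  # same multiset of per-segment extents within each level, within 1%
  for (lev in c("base", "mid", "apex")) {
    a <- sort(e$percent[e$level == lev])
    b <- sort(eR$percent[eR$level == lev])
    expect_equal(a, b, tolerance = 0.01)
  }
  # per-segment pixel totals are permuted, not changed
  expect_equal(sort(e$totalPx), sort(eR$totalPx))

  chR <- buildCenterlineChords(csR, lmR, geometry(myo))
  prR <- profileTable(chordTransmurality(scarR, chR, myoR))
  pr <- profileTable(chordTransmurality(
    case@truthScar, buildCenterlineChords(case@contours, case@landmarks, geometry(myo)), myo))
  expect_equal(mean(prR$transmurality), mean(pr$transmurality), tolerance = 0.01)
})

test_that("landmarks missing on a slice propagate from the nearest slice", {
  case <- generatePhantom(tinyPhantomSpec())
  ant <- case@landmarks@anterior; inf <- case@landmarks@inferior
  ant[2:5, ] <- NA; inf[2:5, ] <- NA  # only slice 0 has landmarks
  lm <- landmarkSet(ant, inf)
  myo <- case@truthMyocardium
  sm <- buildSegmentMap(myo, lm, assignLevels(myo), case@contours)
  smFull <- buildSegmentMap(myo, case@landmarks, assignLevels(myo), case@contours)
  expect_identical(labelArray(sm), labelArray(smFull))
})
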