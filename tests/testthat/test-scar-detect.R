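test_that("four well-separated spikes land one per class, smallest triple", {
  v <- rep(c(10, 90, 170, 250), each = 50)
  thr <- multiotsuThresholds(v)
  expect_true(thr[1] >= 10 && thr[1] < 90)
  expect_true(thr[2] >= 90 && thr[2] < 170)
  expect_true(thr[3] >= 170 && thr[3] < 250)
  # the smallest triple separating the spikes
  expect_equal(thr, c(10, 90, 170))
})

test_that("multi-Otsu matches exhaustive brute force on random histograms", {
  set.seed(29)
  for (r in 1:40) {
    n <- sample(30:250, 1)
    vals <- sample(0:27, n, replace = TRUE, prob = runif(28))
    while (length(unique(vals)) < 4) vals <- sample(0:27, n, replace = TRUE)
    expect_equal(multiotsuThresholds(vals), bruteForceMultiOtsu(vals),
                 info = sprintf("instance %d", r))
  }
})

test_that("thresholds are equivariant under intensity shifts", {
  set.seed(31)
  vals <- sample(0:40, 300, replace = TRUE, prob = runif(41))
  thr <- multiotsuThresholds(vals)
  expect_equal(multiotsuThresholds(vals + 5), thr + 5)
  expect_equal(bruteForceMultiOtsu(vals + 5), bruteForceMultiOtsu(vals) + 5)
})

test_that("fewer than four distinct values is a degenerate histogram", {
  expect_error(multiotsuThresholds(rep(c(10, 200, 255), 20)), "degenerate-histogram")
})

test_that("tissue classification partitions the myocardium", {
  case <- generatePhantom(tinyPhantomSpec())
  myo <- case@truthMyocardium
  work <- normalize255(case@pair@bl)
  thr <- multiotsuThresholds(voxels(work)[maskArray(myo)])
  cm <- classifyTissue(work, myo, thr)
  lab <- labelArray(cm)
  for (k in seq_len(dim(lab)[3]))
    expect_identical(sum(lab[, , k] > 0L), sum(maskArray(myo)[, , k]))
  expect_true(all(lab[!maskArray(myo)] == 0L))
  # noise-free phantom: scar class recovers truth exactly
  expect_identical(lab == 3L, maskArray(case@truthScar))
})

test_that("a constant-zero myocardium is classified entirely healthy", {
  g <- imageGeometry(10, 10, 1)
  st <- imageStack(array(0, c(10, 10, 1)), g, "BL")
  myo <- myocardiumMask(array(TRUE, c(10, 10, 1)), g)
  cm <- classifyTissue(st, myo, c(50, 100, 150))
  expect_true(all(labelArray(cm) == 1L))
})

test_that("default seed is the centroid of the largest scar component", {
  g <- imageGeometry(12, 12, 1)
  lab <- array(0L, c(12, 12, 1))
  lab[3:6, 4:9, 1] <- 3L  # rectangular blob: centroid (row 4.5, col 6.5)
  cm <- new("TissueClassMap", labels = lab, thresholds = c(1, 2, 3),
            method = "otsu", geometry = g)
  sd <- defaultSeed(cm)
  expect_equal(nrow(sd), 1L)
  # centroid at 0-based (row 3.5, col 5.5); snapping resolves ties row-major
  expect_true(sd$row %in% c(3, 4) && sd$col %in% c(5, 6))
  d2 <- (sd$row - 3.5)^2 + (sd$col - 5.5)^2
  expect_equal(d2, 0.5)
})

test_that("slices with no scar class yield no seed", {
  g <- imageGeometry(8, 8, 2)
  lab <- array(0L, c(8, 8, 2))
  lab[2:3, 2:3, 2] <- 3L
  cm <- new("TissueClassMap", labels = lab, thresholds = c(1, 2, 3),
            method = "otsu", geometry = g)
  sd <- defaultSeed(cm)
  expect_equal(sd$slice, 1L)
})

test_that("a C-shaped blob snaps the seed to the nearest blob pixel", {
  g <- imageGeometry(16, 16, 1)
  lab <- array(0L, c(16, 16, 1))
  cshape <- matrix(FALSE, 16, 16)
  cshape[4:12, 4:6] <- TRUE    # left bar
  cshape[4:6, 7:12] <- TRUE    # top bar
  cshape[10:12, 7:12] <- TRUE  # bottom bar
  lab[, , 1][cshape] <- 3L
  cm <- new("TissueClassMap", labels = lab, thresholds = c(1, 2, 3),
            method = "otsu", geometry = g)
  sd <- defaultSeed(cm)
  # oracle: exhaustive nearest-pixel search from the exact centroid
  idx <- which(cshape, arr.ind = TRUE)
  cent <- colMeans(idx)
  d2 <- (idx[, 1] - cent[1])^2 + (idx[, 2] - cent[2])^2
  best <- idx[order(d2, idx[, 1], idx[, 2])[1], ]
  expect_equal(c(sd$row, sd$col), unname(best) - 1L)
  expect_true(cshape[sd$row + 1, sd$col + 1])
})

test_that("region growing reproduces the hand-traced 3x3 example", {
  g <- imageGeometry(3, 3, 1)
  v <- matrix(c(10, 200, 210,
                12, 205, 60,
                11, 15, 14), 3, 3, byrow = TRUE)
  st <- imageStack(array(v, c(3, 3, 1)), g, "BL")
  myo <- myocardiumMask(array(TRUE, c(3, 3, 1)), g)
  m <- regionGrow(st, myo, c(0, 0, 2), maxDeviation = 30)
  expected <- array(FALSE, c(3, 3, 1))
  expected[1, 2, 1] <- TRUE; expected[1, 3, 1] <- TRUE; expected[2, 2, 1] <- TRUE
  expect_identical(maskArray(m), expected)
  expect_equal(mean(voxels(st)[maskArray(m)]), 205)
})

test_that("region growing floods constant myocardium and freezes at zero deviation", {
  g <- imageGeometry(10, 10, 1)
  myoM <- array(FALSE, c(10, 10, 1)); myoM[3:8, 3:8, 1] <- TRUE
  myo <- myocardiumMask(myoM, g)
  cst <- imageStack(array(42, c(10, 10, 1)), g, "BL")
  m <- regionGrow(cst, myo, c(0, 4, 4), maxDeviation = 0)
  expect_identical(maskArray(m), myoM)

  set.seed(5)
  distinct <- imageStack(array(sample(1000, 100), c(10, 10, 1)) * 1.0, g, "BL")
  m0 <- regionGrow(distinct, myo, c(0, 4, 4), maxDeviation = 0)
  expect_equal(sum(maskArray(m0)), 1L)
  expect_true(maskArray(m0)[5, 5, 1])
})

test_that("region growing matches the step-by-step simulation oracle", {
  set.seed(17)
  g <- imageGeometry(8, 8, 1)
  for (r in 1:8) {
    v <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    myoM <- matrix(runif(64) < 0.8, 8, 8)
    seeds <- which(myoM, arr.ind = TRUE)
    s <- seeds[sample(nrow(seeds), 1), ]
    maxDev <- sample(c(10, 40, 90), 1)
    got <- regionGrow(imageStack(array(v, c(8, 8, 1)), g, "BL"),
                      myocardiumMask(array(myoM, c(8, 8, 1)), g),
                      c(0, s[1] - 1, s[2] - 1), maxDev)
    expect_identical(maskArray(got)[, , 1],
                     simulateRegionGrow(v, myoM, s[1], s[2], maxDev),
                     info = sprintf("instance %d", r))
  }
})

test_that("region growth is monotone in maxDeviation and stays in the myocardium", {
  set.seed(23)
  g <- imageGeometry(12, 12, 1)
  v <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  myoM <- matrix(runif(144) < 0.85, 12, 12)
  s <- which(myoM, arr.ind = TRUE)[1, ]
  st <- imageStack(array(v, c(12, 12, 1)), g, "BL")
  myo <- myocardiumMask(array(myoM, c(12, 12, 1)), g)
  prev <- NULL
  for (maxDev in c(0, 10, 25, 60, 120, 255)) {
    m <- maskArray(regionGrow(st, myo, c(0, s[1] - 1, s[2] - 1), maxDev))
    expect_true(all(!m | array(myoM, c(12, 12, 1))))
    if (!is.null(prev)) expect_true(all(!prev | m))  # prev subset of m
    prev <- m
  }
})

test_that("a seed outside the myocardium is rejected", {
  g <- imageGeometry(6, 6, 1)
  myoM <- array(FALSE, c(6, 6, 1)); myoM[2:4, 2:4, 1] <- TRUE
  st <- imageStack(array(1, c(6, 6, 1)), g, "BL")
  expect_error(regionGrow(st, myocardiumMask(myoM, g), c(0, 5, 5), 10), "seed error")
})

test_that("both detectors recover the noise-free transmural scar exactly", {
  case <- generatePhantom(tinyPhantomSpec())
  myo <- case@truthMyocardium
  otsu <- detectScar(case@pair, myo, "otsu")
  expect_equal(diceCoefficient(otsu$scar, case@truthScar), 1.0)
  rg <- detectScar(case@pair, myo, "region_growing")
  expect_equal(diceCoefficient(rg$scar, case@truthScar), 1.0)
})

test_that("moderate noise keeps Dice above 0.95 on a large transmural scar", {
  case <- generatePhantom(tinyPhantomSpec(noiseSd = 10))
  expect_gt(sum(maskArray(case@truthScar)), 200)
  det <- detectScar(case@pair, case@truthMyocardium, "otsu")
  expect_gte(diceCoefficient(det$scar, case@truthScar), 0.95)
})

test_that("the external detector slot passes masks through with containment checks", {
  case <- generatePhantom(tinyPhantomSpec())
  myo <- case@truthMyocardium
  d <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(case@truthScar, d)
  det <- detectScar(case@pair, myo, "external", external = d)
  expect_identical(maskArray(det$scar), maskArray(case@truthScar))
  # a mask escaping the myocardium is rejected
  bad <- array(TRUE, dim(maskArray(myo)))
  expect_error(detectScar(case@pair, myo, "external", external = bad),
               "containment error")
  expect_error(detectScar(case@pair, myo, "fancy_net"), "'arg' should be one of")
})
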