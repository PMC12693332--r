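mkStack <- function(v, contrast = "BL") {
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  imageStack(v * 1.0, imageGeometry(dim(v)[1], dim(v)[2], dim(v)[3]), contrast)
}

test_that("center crop keeps the centered window with floor offsets", {
  st <- mkStack(matrix(seq_len(192 * 192), 192, 192))
  cr <- centerCrop(st, 160)
  # rows/cols 16..175 (0-based) retained
  expect_identical(voxels(cr)[, , 1], voxels(st)[17:176, 17:176, 1])
  expect_equal(geometry(cr)@rows, 160L)

  # odd remainder: offset floor((161-160)/2) = 0, window [0, 160)
  st2 <- mkStack(matrix(seq_len(161 * 161), 161, 161))
  cr2 <- centerCrop(st2, 160)
  expect_identical(voxels(cr2)[, , 1], voxels(st2)[1:160, 1:160, 1])

  # crop at the input size is the identity; oversize errors
  expect_identical(voxels(centerCrop(st, 192)), voxels(st))
  expect_error(centerCrop(st, 200), "dimension error")
})

test_that("top-percent clip alters exactly the expected pixel count", {
  set.seed(3)
  vals <- sample(seq_len(10000))  # 10,000 distinct values
  st <- mkStack(matrix(vals, 100, 100))
  cl <- clipTopPercent(st, 2)
  # oracle: count values strictly above the interpolated 98th percentile
  tau <- quantile(vals, 0.98, type = 7, names = FALSE)
  expect_identical(sum(voxels(cl) != voxels(st)), sum(vals > tau))
  expect_identical(sum(voxels(cl) != voxels(st)), 200L)
  expect_equal(max(voxels(cl)), tau)
})

test_that("clip is the identity for p = 0 and for constant slices", {
  st <- mkStack(matrix(rnorm(400), 20, 20))
  expect_identical(voxels(clipTopPercent(st, 0)), voxels(st))
  cst <- mkStack(matrix(7, 20, 20))
  expect_identical(voxels(clipTopPercent(cst, 5)), voxels(cst))
})

test_that("clip operates per slice, not per stack", {
  v <- array(0, c(10, 10, 2))
  v[, , 1] <- 1:100          # bright slice
  v[, , 2] <- (1:100) / 100  # dark slice
  cl <- clipTopPercent(mkStack(v), 10)
  # each slice clipped at its own percentile
  expect_equal(max(voxels(cl)[, , 1]), quantile(1:100, 0.9, type = 7, names = FALSE))
  expect_equal(max(voxels(cl)[, , 2]), quantile((1:100) / 100, 0.9, type = 7, names = FALSE))
})

test_that("standardization and unit normalization behave as linear maps", {
  st <- mkStack(matrix(rnorm(900, 50, 9), 30, 30))
  sz <- standardizeStack(st)
  expect_equal(mean(voxels(sz)), 0, tolerance = 1e-9)
  expect_equal(sd(voxels(sz)), 1, tolerance = 1e-9)

  un <- normalizeUnit(st)
  expect_equal(min(voxels(un)), 0)
  expect_equal(max(voxels(un)), 1)
  two <- normalizeUnit(mkStack(matrix(c(10, 20), 1, 2)))
  expect_equal(sort(as.vector(voxels(two))), c(0, 1))
  expect_error(normalizeUnit(mkStack(matrix(5, 3, 3))), "degenerate-range")
})

test_that("contrast stretch maps the percentile window to 0-255", {
  ramp <- mkStack(matrix(0:1023, 32, 32))
  n <- normalize255(ramp, stretchPercentiles = c(0, 100))
  expect_equal(voxels(n), voxels(ramp) * 255 / 1023, tolerance = 1e-12)

  # default window clamps the top percentile to 255
  st <- mkStack(matrix(c(rep(10, 990), seq(200, 255, length.out = 10)), 100, 10))
  n2 <- normalize255(st)
  expect_equal(max(voxels(n2)), 255)
  expect_equal(min(voxels(n2)), 0)
})

test_that("phantom BL stretch keeps scar and healthy bands separated", {
  case <- generatePhantom(tinyPhantomSpec())
  n <- normalize255(case@pair@bl)
  v <- voxels(n)
  expect_true(all(v[maskArray(case@truthScar)] > 225))
  healthy <- maskArray(case@truthMyocardium) & !maskArray(case@truthScar) &
    voxels(case@pair@bl) != 128
  expect_true(all(v[healthy] < 30))
})

test_that("mask propagation is an identity transfer with geometry checks", {
  case <- generatePhantom(tinyPhantomSpec())
  m <- propagateMask(case@truthMyocardium, case@pair@br, case@pair@bl)
  expect_identical(maskArray(m), maskArray(case@truthMyocardium))
  # contours propagated then rasterized = rasterized directly (identity grid)
  cs <- propagateMask(case@contours, case@pair@br, case@pair@bl)
  expect_identical(maskArray(rasterizeMyocardium(cs, geometry(case@pair@bl))),
                   maskArray(rasterizeMyocardium(case@contours, geometry(case@pair@br))))
  other <- imageStack(array(0, c(96, 96, 3)), imageGeometry(96, 96, 3), "BL")
  expect_error(propagateMask(case@truthMyocardium, case@pair@br, other),
               "co-registration error")
})

test_that("masked scar input has support exactly on the myocardium", {
  case <- generatePhantom(tinyPhantomSpec())
  x <- buildMaskedScarInput(case@pair@bl, case@truthMyocardium)
  expect_identical(voxels(x) != 0, maskArray(case@truthMyocardium) &
                     voxels(case@pair@bl) != 0)
  ones <- myocardiumMask(array(TRUE, dim(voxels(case@pair@bl))), geometry(case@pair@bl))
  expect_identical(voxels(buildMaskedScarInput(case@pair@bl, ones)),
                   voxels(case@pair@bl))
  zeros <- myocardiumMask(array(FALSE, dim(voxels(case@pair@bl))), geometry(case@pair@bl))
  expect_true(all(voxels(buildMaskedScarInput(case@pair@bl, zeros)) == 0))
})

test_that("the preprocessing chain preserves intensity ordering per slice", {
  case <- generatePhantom(tinyPhantomSpec(noiseSd = 6))
  st <- centerCrop(case@pair@bl, 80)
  st <- clipTopPercent(st, 2)
  st <- standardizeStack(st)
  st <- normalizeUnit(st)
  raw <- centerCrop(case@pair@bl, 80)
  for (k in 1:2) {
    o <- order(voxels(raw)[, , k])
    expect_true(!is.unsorted(voxels(st)[, , k][o]))
  }
  expect_true(min(voxels(st)) >= 0 && max(voxels(st)) <= 1)
})

test_that("idempotent operations are idempotent", {
  case <- generatePhantom(tinyPhantomSpec(noiseSd = 4))
  cr <- centerCrop(case@pair@bl, 80)
  expect_identical(voxels(centerCrop(cr, 80)), voxels(cr))
  un <- normalizeUnit(case@pair@bl)
  expect_equal(voxels(normalizeUnit(un)), voxels(un), tolerance = 1e-12)
})
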