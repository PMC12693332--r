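## Intensity preprocessing chain: center crop, top-percentile clipping,
## standardization, [0,1] normalization, percentile contrast stretch to
## 0-255, and the co-registration transfer / masked-input construction.
##
## Percentiles are computed by linear interpolation between order
## statistics (stats::quantile type 7) -- pinned so that the top-percent
## clip is exactly testable.

#' Center-crop a stack
#'
#' Keeps the `size x size` window centered on the image center; for odd
#' remainders the extra row/column is dropped from the bottom/right (floor
#' offset convention). Typical use crops acquisitions to 160 x 160.
#'
#' @param stack an [ImageStack-class].
#' @param size output side length in pixels.
#' @return the cropped [ImageStack-class] with updated geometry.
#' @export
centerCrop <- function(stack, size = 160) {
  g <- stack@geometry
  size <- as.integer(size)
  if (size > g@rows || size > g@cols)
    stop(sprintf("dimension error: crop size %d exceeds image %d x %d",
                 size, g@rows, g@cols), call. = FALSE)
  r0 <- (g@rows - size) %/% 2L
  c0 <- (g@cols - size) %/% 2L
  v <- stack@voxels[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
  new("ImageStack", voxels = v,
      geometry = imageGeometry(size, size, g@nSlices, g@spacingMm, g@thicknessMm),
      contrast = stack@contrast)
}

#' Clip the brightest percentage of pixels
#'
#' Per slice, computes the `(100 - p)`-th percentile (linear interpolation)
#' and sets every value above it to that threshold, suppressing bright
#' outliers before standardization.
#'
#' @param stack an [ImageStack-class].
#' @param p percentage of brightest pixels to clip, `0 <= p < 100`.
#' @return the clipped [ImageStack-class].
#' @export
clipTopPercent <- function(stack, p = 2) {
  stopifnot(p >= 0, p < 100)
  if (p == 0) return(stack)
  v <- stack@voxels
  for (k in seq_len(dim(v)[3])) {
    tau <- stats::quantile(v[, , k], probs = (100 - p) / 100, type = 7, names = FALSE)
    sl <- v[, , k]
    sl[sl > tau] <- tau
    v[, , k] <- sl
  }
  new("ImageStack", voxels = v, geometry = stack@geometry, contrast = stack@contrast)
}

#' Standardize intensities
#'
#' `(v - mean) / sd`; by default the stack's own statistics are used, or
#' fixed dataset statistics can be supplied.
#'
#' @param stack an [ImageStack-class].
#' @param mean,sd statistics to standardize with; default: computed from
#'   the stack.
#' @return the standardized [ImageStack-class].
#' @export
standardizeStack <- function(stack, mean = NULL, sd = NULL) {
  if (is.null(mean)) mean <- base::mean(stack@voxels)
  if (is.null(sd)) sd <- stats::sd(stack@voxels)
  if (sd <= 0) stop("standardization requires sd > 0", call. = FALSE)
  new("ImageStack", voxels = (stack@voxels - mean) / sd,
      geometry = stack@geometry, contrast = stack@contrast)
}

#' Normalize to the unit interval
#'
#' Linear map of the whole stack's `[min, max]` to `[0, 1]`.
#'
#' @param stack an [ImageStack-class] with non-constant intensities.
#' @return the normalized [ImageStack-class].
#' @export
normalizeUnit <- function(stack) {
  r <- range(stack@voxels)
  if (r[1] == r[2])
    stop("degenerate-range error: constant stack cannot be normalized", call. = FALSE)
  new("ImageStack", voxels = (stack@voxels - r[1]) / (r[2] - r[1]),
      geometry = stack@geometry, contrast = stack@contrast)
}

#' Adaptive contrast stretch to the 0-255 working scale
#'
#' Per slice, linearly maps the window between the two `stretchPercentiles`
#' (default 1st and 99th) to [0, 255], clamping values outside the window.
#' This is the adaptive pre-processing applied before multi-level Otsu
#' thresholding. When a mask is given the window is estimated from the
#' masked pixels only (the map is still applied to the whole slice):
#' detection masked to the LV wall uses the myocardial histogram, so that
#' background-dominated slices cannot collapse the high-intensity window.
#'
#' @param stack an [ImageStack-class].
#' @param stretchPercentiles lower/upper percentiles of the stretch window.
#' @param mask optional logical array (same dimensions) restricting the
#'   window estimation.
#' @return the stretched [ImageStack-class] with values in [0, 255].
#' @export
normalize255 <- function(stack, stretchPercentiles = c(1, 99), mask = NULL) {
  v <- stack@voxels
  for (k in seq_len(dim(v)[3])) {
    sl <- v[, , k]
    sel <- if (is.null(mask)) sl else sl[mask[, , k]]
    if (!length(sel)) next
    w <- stats::quantile(sel, probs = stretchPercentiles / 100, type = 7, names = FALSE)
    if (w[1] == w[2])
      stop("degenerate-range error: stretch window is empty", call. = FALSE)
    sl <- (sl - w[1]) / (w[2] - w[1]) * 255
    v[, , k] <- pmin(pmax(sl, 0), 255)
  }
  new("ImageStack", voxels = v, geometry = stack@geometry, contrast = stack@contrast)
}

#' Transfer masks or contours across a co-registered pair
#'
#' The BR and BL stacks of a joint acquisition share one grid, so contours
#' segmented on the anatomical BR images transfer to the BL images by an
#' identity coordinate mapping. The geometries are checked and the object
#' is re-attached to the target stack's geometry.
#'
#' @param x a [VoxelMask-class] or [ContourSet-class].
#' @param from,to the source and target [ImageStack-class] objects.
#' @return `x`, referencing the target geometry.
#' @export
propagateMask <- function(x, from, to) {
  if (!sameGeometry(from@geometry, to@geometry))
    stop("co-registration error: source and target stacks have different geometries",
         call. = FALSE)
  if (is(x, "VoxelMask")) {
    x@geometry <- to@geometry
    return(x)
  }
  if (is(x, "ContourSet")) {
    if (length(x@slices) != to@geometry@nSlices)
      stop("co-registration error: contour slice count disagrees with target stack",
           call. = FALSE)
    return(x)
  }
  stop("propagateMask expects a VoxelMask or ContourSet", call. = FALSE)
}

#' Build the myocardium-masked scar-detector input
#'
#' Voxelwise product of a preprocessed BL stack with the LV wall mask:
#' zero outside the myocardium, the BL intensity inside. This is the input
#' construction for pluggable scar detectors.
#'
#' @param bl a (preprocessed) BL [ImageStack-class].
#' @param myo a [MyocardiumMask-class] on the same grid.
#' @return an [ImageStack-class].
#' @export
buildMaskedScarInput <- function(bl, myo) {
  if (!sameGeometry(bl@geometry, myo@geometry))
    stop("geometry mismatch between BL stack and myocardium mask", call. = FALSE)
  new("ImageStack", voxels = bl@voxels * myo@mask,
      geometry = bl@geometry, contrast = bl@contrast)
}
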