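## Central S4 containers. Conventions used throughout:
##  - voxel arrays are dim c(rows, cols, nSlices), R column-major
##  - pixel coordinates are 0-based (x = col - 1, y = row - 1), continuous,
##    with the pixel center at integer coordinates
##  - angles are degrees in [0, 360), measured from the +x axis towards +y
##    (counterclockwise in the (x, y) pixel frame)

#' Image geometry of a short-axis stack
#'
#' Pixel grid dimensions and physical voxel size shared by every image,
#' mask and label map of a case. Typical LGE short-axis acquisitions use
#' 1.5 x 1.5 mm in-plane resolution and 8 mm slice thickness.
#'
#' @slot rows,cols,nSlices integer grid dimensions.
#' @slot spacingMm numeric length 2, in-plane pixel spacing (x, y) in mm.
#' @slot thicknessMm slice thickness in mm.
#' @export
setClass("ImageGeometry",
  representation(rows = "integer", cols = "integer", nSlices = "integer",
                 spacingMm = "numeric", thicknessMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rows) != 1L || object@rows < 1L) msg <- c(msg, "rows must be a positive integer")
    if (length(object@cols) != 1L || object@cols < 1L) msg <- c(msg, "cols must be a positive integer")
    if (length(object@nSlices) != 1L || object@nSlices < 1L) msg <- c(msg, "nSlices must be a positive integer")
    if (length(object@spacingMm) != 2L || any(object@spacingMm <= 0)) msg <- c(msg, "spacingMm must be two positive lengths")
    if (length(object@thicknessMm) != 1L || object@thicknessMm <= 0) msg <- c(msg, "thicknessMm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageGeometry
#'
#' @param rows,cols,nSlices grid dimensions.
#' @param spacingMm in-plane spacing in mm (length 2, x then y).
#' @param thicknessMm slice thickness in mm.
#' @return an [ImageGeometry-class] object.
#' @examples
#' g <- imageGeometry(160, 160, 10, c(1.5, 1.5), 8)
#' voxelVolumeMm3(g)  # 18 mm^3
#' @export
imageGeometry <- function(rows, cols, nSlices, spacingMm = c(1.5, 1.5), thicknessMm = 8) {
  new("ImageGeometry", rows = as.integer(rows), cols = as.integer(cols),
      nSlices = as.integer(nSlices), spacingMm = as.numeric(spacingMm),
      thicknessMm = as.numeric(thicknessMm))
}

#' @rdname accessors
#' @export
setMethod("voxelVolumeMm3", "ImageGeometry", function(x)
  x@spacingMm[1] * x@spacingMm[2] * x@thicknessMm)

#' @rdname accessors
#' @export
setMethod("nSlices", "ImageGeometry", function(x) x@nSlices)

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf("ImageGeometry: %d x %d x %d slices, %.3g x %.3g mm in-plane, %.3g mm thick\n",
              object@rows, object@cols, object@nSlices,
              object@spacingMm[1], object@spacingMm[2], object@thicknessMm))
})

sameGeometry <- function(a, b) {
  isTRUE(all.equal(a@rows, b@rows)) && isTRUE(all.equal(a@cols, b@cols)) &&
    isTRUE(all.equal(a@nSlices, b@nSlices)) &&
    isTRUE(all.equal(a@spacingMm, b@spacingMm)) &&
    isTRUE(all.equal(a@thicknessMm, b@thicknessMm))
}

#' A single-contrast short-axis image stack
#'
#' @slot voxels numeric array `rows x cols x nSlices` of finite intensities.
#' @slot geometry the shared [ImageGeometry-class].
#' @slot contrast `"BR"` (bright-blood, anatomical) or `"BL"` (black-blood,
#'   scar contrast).
#' @export
setClass("ImageStack",
  representation(voxels = "array", geometry = "ImageGeometry", contrast = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@voxels)
    g <- object@geometry
    if (length(d) != 3L || d[1] != g@rows || d[2] != g@cols || d[3] != g@nSlices)
      msg <- c(msg, "voxel array dimensions must equal (rows, cols, nSlices)")
    if (!all(is.finite(object@voxels))) msg <- c(msg, "voxels contain non-finite values")
    if (!(length(object@contrast) == 1L && object@contrast %in% c("BR", "BL")))
      msg <- c(msg, "contrast must be 'BR' or 'BL'")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageStack
#'
#' @param voxels 3-D numeric array (rows x cols x slices).
#' @param geometry an [ImageGeometry-class]; defaults to unit 1.5/8 mm
#'   spacing inferred from the array dimensions.
#' @param contrast `"BR"` or `"BL"`.
#' @return an [ImageStack-class].
#' @export
imageStack <- function(voxels, geometry = NULL, contrast = c("BL", "BR")) {
  contrast <- match.arg(contrast)
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (is.null(geometry)) {
    d <- dim(voxels)
    geometry <- imageGeometry(d[1], d[2], d[3])
  }
  new("ImageStack", voxels = voxels, geometry = geometry, contrast = contrast)
}

#' @rdname accessors
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("geometry", "ImageStack", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("contrast", "ImageStack", function(x) x@contrast)

#' @rdname accessors
#' @export
setMethod("nSlices", "ImageStack", function(x) x@geometry@nSlices)

setMethod("show", "ImageStack", function(object) {
  r <- range(object@voxels)
  cat(sprintf("ImageStack (%s): %d x %d x %d, intensities [%.4g, %.4g]\n",
              object@contrast, object@geometry@rows, object@geometry@cols,
              object@geometry@nSlices, r[1], r[2]))
})

#' A co-registered bright-/black-blood pair
#'
#' Joint acquisition yields BR and BL stacks on one grid; contours drawn on
#' the BR images transfer to the BL images by identity.
#'
#' @slot br,bl the two [ImageStack-class] objects (identical geometry).
#' @export
setClass("CoRegisteredPair",
  representation(br = "ImageStack", bl = "ImageStack"),
  validity = function(object) {
    msg <- character()
    if (object@br@contrast != "BR") msg <- c(msg, "br slot must have contrast 'BR'")
    if (object@bl@contrast != "BL") msg <- c(msg, "bl slot must have contrast 'BL'")
    if (!sameGeometry(object@br@geometry, object@bl@geometry))
      msg <- c(msg, "br and bl stacks must share one geometry")
    if (length(msg)) msg else TRUE
  })

#' Construct a CoRegisteredPair
#' @param br,bl BR and BL [ImageStack-class] objects on the same grid.
#' @return a [CoRegisteredPair-class].
#' @export
coRegisteredPair <- function(br, bl) new("CoRegisteredPair", br = br, bl = bl)

#' @rdname accessors
#' @export
setMethod("geometry", "CoRegisteredPair", function(x) x@br@geometry)

setMethod("show", "CoRegisteredPair", function(object) {
  cat("CoRegisteredPair of BR + BL stacks\n")
  show(object@br@geometry)
})

#' Per-slice LV wall contours
#'
#' One endocardial and one epicardial closed polygon per slice, in 0-based
#' continuous pixel coordinates (x = col, y = row), implicitly closed.
#' Slices without contours hold `NULL`.
#'
#' @slot slices list (one per slice) of `NULL` or `list(endo = , epi = )`
#'   with Nx2 vertex matrices.
#' @export
setClass("ContourSet",
  representation(slices = "list"),
  validity = function(object) {
    for (i in seq_along(object@slices)) {
      s <- object@slices[[i]]
      if (is.null(s)) next
      for (nm in c("endo", "epi")) {
        p <- s[[nm]]
        if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
          return(sprintf("slice %d: %s contour must be a matrix with >= 3 vertices", i - 1L, nm))
        if (!all(is.finite(p)))
          return(sprintf("slice %d: %s contour has non-finite vertices", i - 1L, nm))
        if (!polygonIsSimple(p))
          return(sprintf("slice %d: %s contour is self-intersecting", i - 1L, nm))
      }
      if (!polygonInsidePolygon(s$endo, s$epi))
        return(sprintf("slice %d: endocardial contour is not strictly inside the epicardial contour", i - 1L))
    }
    TRUE
  })

#' Construct a ContourSet
#' @param slices list of per-slice `list(endo, epi)` vertex matrices (or
#'   `NULL` for slices without contours).
#' @return a [ContourSet-class].
#' @export
contourSet <- function(slices) new("ContourSet", slices = slices)

#' @rdname accessors
#' @export
setMethod("nSlices", "ContourSet", function(x) length(x@slices))

setMethod("show", "ContourSet", function(object) {
  n <- sum(!vapply(object@slices, is.null, logical(1)))
  cat(sprintf("ContourSet: %d of %d slices contoured\n", n, length(object@slices)))
})

#' Per-slice RV insertion landmarks
#'
#' The anterior and inferior right-ventricular insertion points, per slice,
#' in 0-based pixel coordinates. They anchor the angular origin of both the
#' AHA sectors and the chord analysis. Slices without landmarks hold NA.
#'
#' @slot anterior,inferior numeric nSlices x 2 matrices (x, y); NA rows mark
#'   slices without landmarks.
#' @export
setClass("LandmarkSet",
  representation(anterior = "matrix", inferior = "matrix"),
  validity = function(object) {
    a <- object@anterior; b <- object@inferior
    if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 2L || ncol(b) != 2L || nrow(a) != nrow(b))
      return("anterior and inferior must be numeric n x 2 matrices of equal length")
    ok <- stats::complete.cases(a) & stats::complete.cases(b)
    if (any(ok & (a[, 1] == b[, 1]) & (a[, 2] == b[, 2])))
      return("anterior and inferior landmarks coincide on at least one slice")
    TRUE
  })

#' Construct a LandmarkSet
#' @param anterior,inferior n x 2 matrices of (x, y) landmark coordinates;
#'   rows of NA mark slices without landmarks.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(anterior, inferior)
  new("LandmarkSet", anterior = as.matrix(anterior), inferior = as.matrix(inferior))

#' @rdname accessors
#' @export
setMethod("nSlices", "LandmarkSet", function(x) nrow(x@anterior))

setMethod("show", "LandmarkSet", function(object) {
  n <- sum(stats::complete.cases(object@anterior))
  cat(sprintf("LandmarkSet: landmarks on %d of %d slices\n", n, nrow(object@anterior)))
})

#' Binary voxel masks
#'
#' `VoxelMask` is a logical array tied to a geometry; `MyocardiumMask` marks
#' the LV wall (epicardial interior minus endocardial interior) and
#' `ScarMask` marks detected or ground-truth scar, always a subset of the
#' myocardium.
#'
#' @slot mask logical array rows x cols x nSlices.
#' @slot geometry the [ImageGeometry-class].
#' @aliases MyocardiumMask-class ScarMask-class
#' @export
setClass("VoxelMask",
  representation(mask = "array", geometry = "ImageGeometry"),
  validity = function(object) {
    d <- dim(object@mask)
    g <- object@geometry
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(d) != 3L || d[1] != g@rows || d[2] != g@cols || d[3] != g@nSlices)
      return("mask dimensions must equal (rows, cols, nSlices)")
    TRUE
  })

#' @export
setClass("MyocardiumMask", contains = "VoxelMask")

#' @export
setClass("ScarMask", contains = "VoxelMask")

#' Construct masks
#' @param mask logical 3-D array (rows x cols x slices).
#' @param geometry an [ImageGeometry-class].
#' @return a [VoxelMask-class] subclass.
#' @name masks
#' @export
myocardiumMask <- function(mask, geometry) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  new("MyocardiumMask", mask = mask, geometry = geometry)
}

#' @rdname masks
#' @export
scarMask <- function(mask, geometry) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  new("ScarMask", mask = mask, geometry = geometry)
}

#' @rdname accessors
#' @export
setMethod("maskArray", "VoxelMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("geometry", "VoxelMask", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("nSlices", "VoxelMask", function(x) x@geometry@nSlices)

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("%s: %d of %d voxels set\n", class(object),
              sum(object@mask), length(object@mask)))
})

#' Four-class tissue map from multi-level Otsu thresholding
#'
#' Labels: 0 outside myocardium, 1 healthy, 2 gray zone, 3 scar. The three
#' thresholds (t1 < t2 < t3, 0-255 scale) that produced the map and the
#' detection method tag are retained for provenance.
#'
#' @slot labels integer array rows x cols x nSlices with values 0..3.
#' @slot thresholds numeric length 3 (t1, t2, t3).
#' @slot method character tag of the producing method.
#' @slot geometry the [ImageGeometry-class].
#' @export
setClass("TissueClassMap",
  representation(labels = "array", thresholds = "numeric",
                 method = "character", geometry = "ImageGeometry"),
  validity = function(object) {
    d <- dim(object@labels); g <- object@geometry
    if (length(d) != 3L || d[1] != g@rows || d[2] != g@cols || d[3] != g@nSlices)
      return("label array dimensions must equal (rows, cols, nSlices)")
    if (!all(object@labels %in% 0:3)) return("labels must be in 0..3")
    t <- object@thresholds
    if (length(t) != 3L || !(t[1] < t[2] && t[2] < t[3]))
      return("thresholds must satisfy t1 < t2 < t3")
    TRUE
  })

#' @rdname accessors
#' @export
setMethod("labelArray", "TissueClassMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("geometry", "TissueClassMap", function(x) x@geometry)

#' Thresholds of a tissue class map
#' @param x a [TissueClassMap-class].
#' @return numeric length 3 `(t1, t2, t3)`.
#' @export
classThresholds <- function(x) x@thresholds

setMethod("show", "TissueClassMap", function(object) {
  tb <- tabulate(object@labels + 1L, nbins = 4L)
  cat(sprintf("TissueClassMap (%s): healthy %d, gray zone %d, scar %d px; thresholds (%g, %g, %g)\n",
              object@method, tb[2], tb[3], tb[4],
              object@thresholds[1], object@thresholds[2], object@thresholds[3]))
})

#' AHA 16-segment label map
#'
#' Per-pixel segment labels (0 = none, 1-6 basal, 7-12 mid, 13-16 apical)
#' together with the per-slice anatomical level and the angular sector
#' boundaries used on each slice.
#'
#' @slot labels integer array rows x cols x nSlices, values 0..16.
#' @slot levels character per slice: "base", "mid", "apex" or "none".
#' @slot boundaries list per slice of boundary angles (degrees) or `NULL`.
#' @slot geometry the [ImageGeometry-class].
#' @export
setClass("SegmentMap",
  representation(labels = "array", levels = "character",
                 boundaries = "list", geometry = "ImageGeometry"),
  validity = function(object) {
    d <- dim(object@labels); g <- object@geometry
    if (length(d) != 3L || d[1] != g@rows || d[2] != g@cols || d[3] != g@nSlices)
      return("label array dimensions must equal (rows, cols, nSlices)")
    if (!all(object@labels %in% 0:16)) return("segment labels must be in 0..16")
    if (length(object@levels) != g@nSlices) return("one level per slice required")
    if (!all(object@levels %in% c("base", "mid", "apex", "none")))
      return("levels must be base/mid/apex/none")
    rngFor <- list(base = 1:6, mid = 7:12, apex = 13:16, none = integer())
    for (k in seq_len(g@nSlices)) {
      lab <- object@labels[, , k]
      present <- sort(unique(lab[lab > 0L]))
      if (!all(present %in% rngFor[[object@levels[k]]]))
        return(sprintf("slice %d carries labels outside its anatomical level", k - 1L))
    }
    TRUE
  })

#' @rdname accessors
#' @export
setMethod("labelArray", "SegmentMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("geometry", "SegmentMap", function(x) x@geometry)

#' Per-slice anatomical levels of a SegmentMap
#' @param x a [SegmentMap-class].
#' @return character vector, one of base/mid/apex/none per slice.
#' @export
sliceLevels <- function(x) x@levels

setMethod("show", "SegmentMap", function(object) {
  cat(sprintf("SegmentMap: %d labelled px; levels: %s\n",
              sum(object@labels > 0L), paste(object@levels, collapse = " ")))
})

#' Centerline chords of a slice stack
#'
#' Exactly 100 chords per quantified slice, each perpendicular to the
#' mid-wall centerline, running from the endocardial to the epicardial
#' contour. Stored as a data frame with one row per chord.
#'
#' @slot chords data.frame with columns slice, chord, angleDeg, cx, cy,
#'   dirX, dirY, endoX, endoY, epiX, epiY, thicknessMm.
#' @slot geometry the [ImageGeometry-class].
#' @export
setClass("ChordSet",
  representation(chords = "data.frame", geometry = "ImageGeometry"),
  validity = function(object) {
    need <- c("slice", "chord", "angleDeg", "cx", "cy", "dirX", "dirY",
              "endoX", "endoY", "epiX", "epiY", "thicknessMm")
    if (!all(need %in% names(object@chords))) return("missing chord columns")
    cnt <- table(object@chords$slice)
    if (length(cnt) && !all(cnt == 100L)) return("each quantified slice must carry exactly 100 chords")
    if (any(object@chords$thicknessMm <= 0)) return("chord thickness must be positive")
    TRUE
  })

#' Chord table of a ChordSet
#' @param x a [ChordSet-class].
#' @return the underlying data.frame (one row per chord).
#' @export
chordTable <- function(x) x@chords

#' @rdname accessors
#' @export
setMethod("geometry", "ChordSet", function(x) x@geometry)

setMethod("show", "ChordSet", function(object) {
  cat(sprintf("ChordSet: %d chords on %d slices\n",
              nrow(object@chords), length(unique(object@chords$slice))))
})

#' Per-chord scar transmurality
#'
#' For every chord, the fraction of the wall thickness occupied by scar
#' along the chord (0 = none, 1 = transmural).
#'
#' @slot values data.frame with columns slice, chord, angleDeg, transmurality.
#' @export
setClass("TransmuralityProfile",
  representation(values = "data.frame"),
  validity = function(object) {
    if (!all(c("slice", "chord", "transmurality") %in% names(object@values)))
      return("missing profile columns")
    tv <- object@values$transmurality
    if (any(tv < 0 | tv > 1)) return("transmurality values must lie in [0, 1]")
    TRUE
  })

#' Transmurality table of a profile
#' @param x a [TransmuralityProfile-class].
#' @return data.frame with per-chord transmurality values.
#' @export
profileTable <- function(x) x@values

setMethod("show", "TransmuralityProfile", function(object) {
  cat(sprintf("TransmuralityProfile: %d chords, mean %.3f, max %.3f\n",
              nrow(object@values), mean(object@values$transmurality),
              max(c(0, object@values$transmurality))))
})

#' Per-segment scar extent
#'
#' Scar pixel percentage per AHA segment. Segments without myocardial
#' pixels are reported with `NA` percent (missing, not zero).
#'
#' @slot extents data.frame with columns segment, level, scarPx, totalPx,
#'   percent.
#' @export
setClass("SegmentExtent",
  representation(extents = "data.frame"),
  validity = function(object) {
    e <- object@extents
    if (!all(c("segment", "level", "scarPx", "totalPx", "percent") %in% names(e)))
      return("missing extent columns")
    ok <- e$totalPx > 0L
    if (any(abs(e$percent[ok] - 100 * e$scarPx[ok] / e$totalPx[ok]) > 1e-9))
      return("percent must equal 100 * scarPx / totalPx")
    if (any(!is.na(e$percent[!ok]))) return("empty segments must report NA percent")
    TRUE
  })

#' Extent table of a SegmentExtent
#' @param x a [SegmentExtent-class].
#' @return data.frame with one row per AHA segment.
#' @export
extentTable <- function(x) x@extents

setMethod("show", "SegmentExtent", function(object) {
  cat("SegmentExtent (percent scar per AHA segment):\n")
  print(object@extents, row.names = FALSE)
})

#' Global scar metrics
#'
#' The clinical summary numbers: myocardial and scar volume (mL), scar mass
#' (g, using a configurable myocardial density, default 1.05 g/cm^3), scar
#' extent (% of myocardial volume), mean and maximum chord transmurality,
#' and the per-segment extents.
#'
#' @slot myocardialVolumeMl,scarVolumeMl volumes in mL.
#' @slot scarMassG scar mass in grams.
#' @slot scarExtentPercent scar volume as % of myocardial volume.
#' @slot meanTransmurality,maxTransmurality fractions in [0, 1].
#' @slot densityGPerCm3 myocardial density used for the mass.
#' @slot segmentExtents a [SegmentExtent-class].
#' @export
setClass("ScarMetrics",
  representation(myocardialVolumeMl = "numeric", scarVolumeMl = "numeric",
                 scarMassG = "numeric", scarExtentPercent = "numeric",
                 meanTransmurality = "numeric", maxTransmurality = "numeric",
                 densityGPerCm3 = "numeric", segmentExtents = "SegmentExtent"),
  validity = function(object) {
    msg <- character()
    if (object@scarVolumeMl < 0 || object@scarVolumeMl > object@myocardialVolumeMl + 1e-9)
      msg <- c(msg, "scar volume must lie in [0, myocardial volume]")
    if (object@scarExtentPercent < 0 || object@scarExtentPercent > 100 + 1e-9)
      msg <- c(msg, "extent must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ScarMetrics", function(object) {
  cat(sprintf(paste0(
    "ScarMetrics:\n  myocardial volume %.2f mL\n  scar volume       %.2f mL\n",
    "  scar mass         %.2f g (density %.2f g/cm^3)\n  scar extent       %.1f %%\n",
    "  transmurality     mean %.3f, max %.3f\n"),
    object@myocardialVolumeMl, object@scarVolumeMl, object@scarMassG,
    object@densityGPerCm3, object@scarExtentPercent,
    object@meanTransmurality, object@maxTransmurality))
})

#' Phantom specification
#'
#' Fully describes a synthetic co-registered BR/BL case: grid and voxel
#' geometry, per-slice endo-/epicardial radii, scar sectors (slice, angular
#' interval in degrees, radial interval as fractions of wall depth), the
#' gray-zone rim width, additive noise level, landmark angles and RNG seed.
#'
#' @slot rows,cols,nSlices grid dimensions.
#' @slot spacingMm,thicknessMm voxel geometry (mm).
#' @slot endoRadiusPx,epiRadiusPx per-slice radii in pixels.
#' @slot scarSectors data.frame: slice (0-based), thetaStartDeg, thetaEndDeg,
#'   fStart, fEnd (radial wall-depth fractions in [0, 1]).
#' @slot grayZoneRimPx width of the intermediate-intensity rim around scar.
#' @slot noiseSd additive Gaussian noise SD on the 0-255 scale.
#' @slot landmarkAnglesDeg anterior and inferior insertion angles.
#' @slot rngSeed integer seed.
#' @export
setClass("PhantomSpec",
  representation(rows = "integer", cols = "integer", nSlices = "integer",
                 spacingMm = "numeric", thicknessMm = "numeric",
                 endoRadiusPx = "numeric", epiRadiusPx = "numeric",
                 scarSectors = "data.frame", grayZoneRimPx = "numeric",
                 noiseSd = "numeric", landmarkAnglesDeg = "numeric",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    ns <- object@nSlices
    if (length(object@endoRadiusPx) != ns || length(object@epiRadiusPx) != ns)
      msg <- c(msg, "endoRadiusPx/epiRadiusPx must give one radius per slice")
    else {
      if (any(object@endoRadiusPx <= 0)) msg <- c(msg, "endoRadiusPx must be positive")
      if (any(object@endoRadiusPx >= object@epiRadiusPx))
        msg <- c(msg, "endoRadiusPx must be strictly smaller than epiRadiusPx on every slice")
      if (object@rows < 2 * max(object@epiRadiusPx) || object@cols < 2 * max(object@epiRadiusPx))
        msg <- c(msg, "rows and cols must be at least twice epiRadiusPx")
    }
    ss <- object@scarSectors
    if (nrow(ss)) {
      if (!all(c("slice", "thetaStartDeg", "thetaEndDeg", "fStart", "fEnd") %in% names(ss)))
        msg <- c(msg, "scarSectors must have columns slice, thetaStartDeg, thetaEndDeg, fStart, fEnd")
      else {
        if (any(ss$fStart < 0 | ss$fEnd > 1 | ss$fStart >= ss$fEnd))
          msg <- c(msg, "scarSectors radial fractions must satisfy 0 <= fStart < fEnd <= 1")
        if (any(ss$slice < 0 | ss$slice >= ns)) msg <- c(msg, "scarSectors slice index out of range")
      }
    }
    if (object@grayZoneRimPx < 0) msg <- c(msg, "grayZoneRimPx must be nonnegative")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
    if (length(object@landmarkAnglesDeg) != 2L ||
        object@landmarkAnglesDeg[1] %% 360 == object@landmarkAnglesDeg[2] %% 360)
      msg <- c(msg, "landmarkAnglesDeg must be two distinct angles")
    if (length(msg)) msg else TRUE
  })

#' A generated phantom case with ground truth
#'
#' @slot pair the synthetic [CoRegisteredPair-class].
#' @slot contours the exact circles used for rasterization, as polygons.
#' @slot landmarks per-slice RV insertion landmarks.
#' @slot truthMyocardium,truthScar ground-truth masks.
#' @slot truthMetrics analytically derived [ScarMetrics-class].
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomCase",
  representation(pair = "CoRegisteredPair", contours = "ContourSet",
                 landmarks = "LandmarkSet", truthMyocardium = "MyocardiumMask",
                 truthScar = "ScarMask", truthMetrics = "ScarMetrics",
                 spec = "PhantomSpec"),
  validity = function(object) {
    if (any(object@truthScar@mask & !object@truthMyocardium@mask))
      return("truth scar must be a subset of the truth myocardium")
    TRUE
  })

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase\n")
  show(object@pair@br@geometry)
  cat(sprintf("  truth scar: %d px, extent %.1f %%\n",
              sum(object@truthScar@mask), object@truthMetrics@scarExtentPercent))
})
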