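#' Accessors for ScarQuant objects
#'
#' Small accessor generics shared across the package's S4 containers:
#' `geometry()` returns the [ImageGeometry-class] attached to an object,
#' `voxels()` the raw intensity array of an [ImageStack-class],
#' `maskArray()` the logical array of a mask, and `labelArray()` the integer
#' label array of a [TissueClassMap-class] or [SegmentMap-class].
#'
#' @param x an object of one of the package's S4 classes.
#' @return `geometry()`: an `ImageGeometry`; `voxels()`/`maskArray()`/
#'   `labelArray()`: a 3-D array with dimensions `rows x cols x nSlices`.
#' @name accessors
#' @aliases geometry voxels maskArray labelArray
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("contrast", function(x) standardGeneric("contrast"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeMm3", function(x) standardGeneric("voxelVolumeMm3"))
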