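#' @import methods
#' @importFrom stats quantile rnorm sd complete.cases aggregate
#' @importFrom grDevices png dev.off hcl.colors
#' @importFrom graphics polygon text par plot.new plot.window
#' @importFrom utils write.csv packageVersion
#' @importFrom tools md5sum
NULL

formatError <- function(path, why) {
  stop(sprintf("format error for '%s': %s", path, why), call. = FALSE)
}

#' Read and write image stacks
#'
#' Stacks are stored either as NIfTI-1 files (geometry taken from the
#' header `pixdim`) or as a directory of per-slice 16-bit grayscale PNG
#' files (`slice_000.png`, ...) with a JSON geometry sidecar
#' (`geometry.json`). Integer data round-trip losslessly.
#'
#' @param path a `.nii`/`.nii.gz` file or a PNG slice directory.
#' @param contrast `"BR"` or `"BL"`.
#' @param stack an [ImageStack-class] to write.
#' @param format `"nifti"` or `"png"`; inferred from `path` on read.
#' @return `readStack()` an [ImageStack-class]; `writeStack()` the path,
#'   invisibly.
#' @examples
#' g <- imageGeometry(16, 16, 2)
#' st <- imageStack(array(0:511, c(16, 16, 2)), g, "BL")
#' f <- tempfile(fileext = ".nii.gz")
#' writeStack(st, f)
#' identical(voxels(readStack(f, "BL")), voxels(st))
#' @export
readStack <- function(path, contrast = c("BL", "BR")) {
  contrast <- match.arg(contrast)
  if (dir.exists(path)) return(readStackPng(path, contrast))
  if (!file.exists(path)) formatError(path, "file does not exist")
  img <- tryCatch(RNifti::readNifti(path), error = function(e) formatError(path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) formatError(path, "expected a 3-D volume")
  pd <- RNifti::pixdim(img)
  ## NIfTI is (x=col, y=row, z=slice); internal arrays are (row, col, slice)
  arr <- aperm(arr, c(2L, 1L, 3L))
  geom <- imageGeometry(dim(arr)[1], dim(arr)[2], dim(arr)[3],
                        spacingMm = pd[1:2], thicknessMm = pd[3])
  new("ImageStack", voxels = arr * 1.0, geometry = geom, contrast = contrast)
}

#' @rdname readStack
#' @export
writeStack <- function(stack, path, format = c("auto", "nifti", "png")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "png"
  if (format == "nifti") {
    arr <- aperm(stack@voxels, c(2L, 1L, 3L))
    g <- stack@geometry
    img <- RNifti::asNifti(arr, reference = list(pixdim = c(1, g@spacingMm, g@thicknessMm, 0, 0, 0, 0)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
  } else {
    writeStackPng(stack, path)
  }
  invisible(path)
}

readStackPng <- function(path, contrast) {
  sidecar <- file.path(path, "geometry.json")
  if (!file.exists(sidecar)) formatError(path, "missing geometry.json sidecar")
  g <- jsonlite::fromJSON(sidecar)
  files <- sort(list.files(path, pattern = "^slice_\\d+\\.png$", full.names = TRUE))
  if (length(files) != g$n_slices)
    formatError(path, sprintf("sidecar declares %d slices but %d PNG files found",
                              g$n_slices, length(files)))
  arr <- array(0, c(g$rows, g$cols, g$n_slices))
  for (k in seq_along(files)) {
    m <- png::readPNG(files[k])
    if (length(dim(m)) != 2L) formatError(files[k], "expected single-channel grayscale")
    if (nrow(m) != g$rows || ncol(m) != g$cols)
      formatError(files[k], "slice dimensions disagree with sidecar")
    arr[, , k] <- round(m * 65535)
  }
  geom <- imageGeometry(g$rows, g$cols, g$n_slices, g$spacing_mm, g$thickness_mm)
  new("ImageStack", voxels = arr, geometry = geom, contrast = contrast)
}

## CRC-32 (PNG chunk checksum), table-driven.
crc32Env <- new.env(parent = emptyenv())

crc32 <- function(bytes) {
  if (is.null(crc32Env$table)) {
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
      tab[n + 1L] <- c
    }
    crc32Env$table <- tab
  }
  tab <- crc32Env$table
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L], bitwShiftR(crc, 8))
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

## Minimal 16-bit grayscale PNG encoder (the installed png bindings write
## 8-bit only; reading 16-bit files works through png::readPNG).
writePng16 <- function(m, path) {
  m <- round(m)
  nr <- nrow(m); nc <- ncol(m)
  ihdr <- c(u32be(nc), u32be(nr), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  ## scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  hi <- as.raw(t(m) %/% 256)
  lo <- as.raw(t(m) %% 256)
  px <- as.vector(rbind(hi, lo))
  rowsRaw <- split(px, rep(seq_len(nr), each = 2L * nc))
  payload <- unlist(lapply(rowsRaw, function(r) c(as.raw(0L), r)), use.names = FALSE)
  idat <- memCompress(payload, "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(pngChunk("IHDR", ihdr), con)
  writeBin(pngChunk("IDAT", idat), con)
  writeBin(pngChunk("IEND", raw(0)), con)
  invisible(path)
}

writeStackPng <- function(stack, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- stack@geometry
  v <- stack@voxels
  if (min(v) < 0 || max(v) > 65535)
    stop("PNG output requires intensities within [0, 65535]", call. = FALSE)
  for (k in seq_len(g@nSlices))
    writePng16(v[, , k], file.path(path, sprintf("slice_%03d.png", k - 1L)))
  jsonlite::write_json(
    list(rows = g@rows, cols = g@cols, n_slices = g@nSlices,
         spacing_mm = g@spacingMm, thickness_mm = g@thicknessMm),
    file.path(path, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write masks
#'
#' Binary masks use the same containers as stacks: NIfTI-1 with 0/1 values
#' or per-slice PNG.
#'
#' @param path file or directory path.
#' @param geometry optional [ImageGeometry-class] to validate against.
#' @param mask a [VoxelMask-class] to write.
#' @param role `"myocardium"` or `"scar"` (selects the returned class).
#' @return `readMask()` a [VoxelMask-class] subclass; `writeMask()` the
#'   path, invisibly.
#' @export
readMask <- function(path, role = c("scar", "myocardium"), geometry = NULL) {
  role <- match.arg(role)
  st <- readStack(path, "BL")
  if (!is.null(geometry) && !sameGeometry(st@geometry, geometry))
    stop("mask geometry disagrees with the expected geometry", call. = FALSE)
  m <- st@voxels != 0
  if (role == "scar") scarMask(m, st@geometry) else myocardiumMask(m, st@geometry)
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  st <- new("ImageStack", voxels = mask@mask * 1.0, geometry = mask@geometry, contrast = "BL")
  writeStack(st, path)
}

#' Read and write contour sets
#'
#' JSON schema: `{"slices": [{"index": 0, "endo": [[x, y], ...],
#' "epi": [[x, y], ...]}, ...]}` with 0-based slice indices and 0-based
#' pixel coordinates. Coordinates round-trip exactly (decimal
#' serialization).
#'
#' @param path JSON file path.
#' @param contours a [ContourSet-class] to write.
#' @param nSlices total slice count of the stack the contours belong to;
#'   defaults to the largest slice index present plus one.
#' @return `readContours()` a [ContourSet-class]; `writeContours()` the
#'   path, invisibly.
#' @export
readContours <- function(path, nSlices = NULL) {
  if (!file.exists(path)) formatError(path, "file does not exist")
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$slices)) formatError(path, "missing 'slices' array")
  idx <- vapply(doc$slices, function(s) as.integer(s$index), integer(1))
  if (is.null(nSlices)) nSlices <- max(idx) + 1L
  slices <- vector("list", nSlices)
  for (s in doc$slices) {
    endo <- matrix(as.numeric(s$endo), ncol = 2)
    epi <- matrix(as.numeric(s$epi), ncol = 2)
    if (nrow(endo) < 3L || nrow(epi) < 3L)
      stop(sprintf("schema error in '%s': slice %d contour has fewer than 3 vertices",
                   path, s$index), call. = FALSE)
    slices[[s$index + 1L]] <- list(endo = endo, epi = epi)
  }
  tryCatch(contourSet(slices), error = function(e)
    stop(sprintf("geometry error in '%s': %s", path, conditionMessage(e)), call. = FALSE))
}

#' @rdname readContours
#' @export
writeContours <- function(contours, path) {
  out <- list(slices = list())
  for (i in seq_along(contours@slices)) {
    s <- contours@slices[[i]]
    if (is.null(s)) next
    out$slices[[length(out$slices) + 1L]] <-
      list(index = i - 1L, endo = unname(s$endo), epi = unname(s$epi))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write landmark sets
#'
#' JSON schema: `{"slices": [{"index": 0, "anterior": [x, y],
#' "inferior": [x, y]}, ...]}`, 0-based.
#'
#' @param path JSON file path.
#' @param landmarks a [LandmarkSet-class] to write.
#' @param nSlices total slice count; defaults to max index + 1.
#' @return `readLandmarks()` a [LandmarkSet-class]; `writeLandmarks()` the
#'   path, invisibly.
#' @export
readLandmarks <- function(path, nSlices = NULL) {
  if (!file.exists(path)) formatError(path, "file does not exist")
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$slices)) formatError(path, "missing 'slices' array")
  idx <- vapply(doc$slices, function(s) as.integer(s$index), integer(1))
  if (is.null(nSlices)) nSlices <- max(idx) + 1L
  ant <- matrix(NA_real_, nSlices, 2)
  inf <- matrix(NA_real_, nSlices, 2)
  for (s in doc$slices) {
    ant[s$index + 1L, ] <- as.numeric(s$anterior)
    inf[s$index + 1L, ] <- as.numeric(s$inferior)
  }
  landmarkSet(ant, inf)
}

#' @rdname readLandmarks
#' @export
writeLandmarks <- function(landmarks, path) {
  out <- list(slices = list())
  for (i in seq_len(nrow(landmarks@anterior))) {
    if (anyNA(landmarks@anterior[i, ])) next
    out$slices[[length(out$slices) + 1L]] <-
      list(index = i - 1L, anterior = landmarks@anterior[i, ],
           inferior = landmarks@inferior[i, ])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize the myocardium from contours
#'
#' A pixel belongs to the myocardium iff its center lies inside the
#' epicardial polygon and not inside the endocardial polygon (even-odd
#' rule; the center-in test decides boundary pixels). Slices without
#' contours yield an empty mask.
#'
#' @param contours a [ContourSet-class].
#' @param geom an [ImageGeometry-class] giving the pixel grid.
#' @return a [MyocardiumMask-class].
#' @examples
#' g <- imageGeometry(80, 80, 1)
#' cs <- contourSet(list(list(endo = circlePoly(40, 40, 20),
#'                            epi = circlePoly(40, 40, 35))))
#' sum(maskArray(rasterizeMyocardium(cs, g)))  # ~ pi * (35^2 - 20^2)
#' @export
rasterizeMyocardium <- function(contours, geom) {
  mask <- array(FALSE, c(geom@rows, geom@cols, geom@nSlices))
  gr <- pixelGrid(geom@rows, geom@cols)
  for (k in seq_len(min(length(contours@slices), geom@nSlices))) {
    s <- contours@slices[[k]]
    if (is.null(s)) next
    ## restrict the point-in-polygon tests to the epi bounding box
    bb <- apply(s$epi, 2, range)
    sel <- gr$x >= floor(bb[1, 1]) & gr$x <= ceiling(bb[2, 1]) &
      gr$y >= floor(bb[1, 2]) & gr$y <= ceiling(bb[2, 2])
    px <- gr$x[sel]; py <- gr$y[sel]
    inEpi <- pointInPolygon(px, py, s$epi)
    inEndo <- pointInPolygon(px, py, s$endo)
    m <- matrix(FALSE, geom@rows, geom@cols)
    m[sel] <- inEpi & !inEndo
    mask[, , k] <- m
  }
  myocardiumMask(mask, geom)
}

#' Circle as a closed polygon
#'
#' Convenience constructor for contour polygons: a regular `nVertices`-gon
#' inscribed in the circle of radius `r` (pixels) about `(cx, cy)`.
#'
#' @param cx,cy center, 0-based pixel coordinates.
#' @param r radius in pixels.
#' @param nVertices vertex count.
#' @return an `nVertices` x 2 matrix of (x, y) vertices.
#' @export
circlePoly <- function(cx, cy, r, nVertices = 256L) circlePolygon(cx, cy, r, nVertices)
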