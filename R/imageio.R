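#' Construct a CalibratedImage from pixel data
#'
#' @param pixels H x W x 3 array of 8-bit values, or an H x W matrix
#'   (replicated to three channels)
#' @param mpp microns per pixel (isotropic, > 0)
#' @param organLabel organ label text
#' @param slideId unique slide identifier
#' @return a \code{\linkS4class{CalibratedImage}}
#' @export
CalibratedImage <- function(pixels, mpp, organLabel = "unknown",
                            slideId = "slide") {
  if (is.matrix(pixels))
    pixels <- array(pixels, c(dim(pixels), 3L))
  storage.mode(pixels) <- "integer"
  new("CalibratedImage", pixels = pixels, mpp = as.numeric(mpp),
      organLabel = as.character(organLabel), slideId = as.character(slideId))
}

#' Construct a BinaryMask
#'
#' @param mask logical H x W matrix (numeric input is coerced via \code{> 0})
#' @param provenance one of "ground_truth", "weak_label", "predicted"
#' @return a \code{\linkS4class{BinaryMask}}
#' @export
BinaryMask <- function(mask, provenance = c("weak_label", "ground_truth",
                                            "predicted")) {
  provenance <- match.arg(provenance)
  if (!is.logical(mask)) mask <- mask > 0
  new("BinaryMask", mask = mask, provenance = provenance)
}

.png_header <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  if (length(hdr) < 26L ||
      !identical(as.integer(hdr[1:4]), c(137L, 80L, 78L, 71L)))
    stop("not a PNG file: ", path)
  list(bitDepth = as.integer(hdr[25]), colorType = as.integer(hdr[26]))
}

.is_tiff <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  identical(as.integer(magic[1:2]), c(73L, 73L)) ||
    identical(as.integer(magic[1:2]), c(77L, 77L))
}

#' Load a calibrated 8-bit RGB section image
#'
#' Reads a TIFF or PNG section image exported from a slide scanner and
#' attaches the physical calibration. Grayscale input is replicated to
#' three channels; inputs deeper than 8 bits or wider than 3 channels are
#' rejected, since the whole pipeline is defined on 8-bit RGB.
#'
#' @param path path to an 8-bit RGB or grayscale TIFF/PNG
#' @param mpp microns per pixel (required metadata; never inferred)
#' @param organLabel organ label
#' @param slideId slide identifier; defaults to the file name sans extension
#' @return a \code{\linkS4class{CalibratedImage}}
#' @export
loadImage <- function(path, mpp, organLabel = "unknown",
                      slideId = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  if (mpp <= 0) stop("mpp must be positive, got ", mpp)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff") || (!ext %in% "png" && .is_tiff(path))) {
    meta <- tiff::readTIFF(path, payload = FALSE)
    if (meta$bits.per.sample[1] != 8L)
      stop("unsupported bit depth: ", meta$bits.per.sample[1],
           " bits per sample (8-bit required)")
    if (meta$samples.per.pixel[1] > 3L)
      stop("unsupported channel count: ", meta$samples.per.pixel[1],
           " channels (at most 3 supported)")
    img <- tiff::readTIFF(path)
  } else {
    hdr <- .png_header(path)
    if (hdr$bitDepth != 8L)
      stop("unsupported bit depth: ", hdr$bitDepth, " (8-bit required)")
    if (hdr$colorType %in% c(4L, 6L)) {
      nch <- if (hdr$colorType == 6L) 4L else 2L
      stop("unsupported channel count: ", nch,
           " channels (at most 3 supported)")
    }
    img <- png::readPNG(path)
  }
  px <- round(img * 255)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] > 3L)
    stop("unsupported channel count: ", dim(px)[3], " channels")
  CalibratedImage(px, mpp = mpp, organLabel = organLabel, slideId = slideId)
}

#' Save a binary mask as a lossless single-channel PNG
#'
#' Positive pixels are written as 255, negative as 0; the round trip through
#' \code{\link{loadMask}} is bit-exact.
#'
#' @param mask a \code{\linkS4class{BinaryMask}} (or logical matrix)
#' @param path output PNG path
#' @export
saveMask <- function(mask, path) {
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write mask: no such directory ", dir)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Load a binary mask from a single-channel PNG
#'
#' @param path PNG path written by \code{\link{saveMask}}
#' @param provenance provenance to attach
#' @return a \code{\linkS4class{BinaryMask}}
#' @export
loadMask <- function(path, provenance = "weak_label") {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  BinaryMask(m >= 0.5, provenance = provenance)
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the region when its center -- at integer coordinate
#' + 0.5 in both axes -- lies inside the closed polygon under the even-odd
#' rule. Vertices are (x = col, y = row) pairs in pixel units;
#' self-intersecting polygons are accepted (the even-odd rule applies).
#'
#' @param vertices n x 2 matrix of (x, y) vertex coordinates, n >= 3
#' @param imageDims H, W of the target image
#' @return an \code{\linkS4class{ROIMask}}
#' @export
rasterizeROI <- function(vertices, imageDims) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L)
    stop("polygon needs at least 3 vertices, got ", nrow(vertices))
  H <- as.integer(imageDims[1]); W <- as.integer(imageDims[2])
  if (any(vertices[, 1] < 0) || any(vertices[, 1] > W) ||
      any(vertices[, 2] < 0) || any(vertices[, 2] > H))
    stop("polygon vertices must lie within [0, W] x [0, H]")
  # scanline even-odd fill: for each pixel-row center y, find x-crossings
  mask <- matrix(FALSE, H, W)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- nrow(vertices)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])  # previous vertex
  xc <- seq_len(W) - 0.5
  for (r in seq_len(H)) {
    y <- r - 0.5
    crosses <- (vy > y) != (jy > y)
    if (!any(crosses)) next
    xint <- jx[crosses] + (y - jy[crosses]) / (vy[crosses] - jy[crosses]) *
      (vx[crosses] - jx[crosses])
    # even-odd: pixel center inside iff an odd number of crossings right of it
    counts <- colSums(outer(xint, xc, ">"))
    mask[r, ] <- counts %% 2L == 1L
  }
  new("ROIMask", mask = mask, source = "polygon")
}

#' Read an ROI delineation from JSON
#'
#' Expected fields: \code{slide_id}, \code{vertices} (list of [x, y] pairs),
#' \code{units} ("pixel").
#'
#' @param path JSON file path
#' @param imageDims H, W of the image the ROI belongs to
#' @return an \code{\linkS4class{ROIMask}}
#' @export
readROI <- function(path, imageDims) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$units) && obj$units != "pixel")
    stop("ROI units must be 'pixel', got '", obj$units, "'")
  rasterizeROI(as.matrix(obj$vertices), imageDims)
}

#' Write an ROI polygon to JSON
#'
#' @param vertices n x 2 (x, y) vertex matrix
#' @param slideId slide identifier recorded in the file
#' @param path output path
#' @export
writeROI <- function(vertices, slideId, path) {
  jsonlite::write_json(
    list(slide_id = slideId, units = "pixel",
         vertices = unname(as.matrix(vertices))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Wrap a raster mask as an ROI
#'
#' @param mask logical H x W matrix
#' @return an \code{\linkS4class{ROIMask}} with source "raster"
#' @export
rasterROI <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  new("ROIMask", mask = mask, source = "raster")
}

#' Save a CalibratedImage to PNG
#'
#' @param image a \code{\linkS4class{CalibratedImage}}
#' @param path output PNG path
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "CalibratedImage"))
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}
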