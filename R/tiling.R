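#' Construct a TilingSpec
#'
#' @param patchSize patch edge in pixels (default 1000)
#' @param overlap overlap between adjacent patches in pixels (default 100)
#' @param padValue RGB triple filling out-of-image area (default white)
#' @return a \code{\linkS4class{TilingSpec}}
#' @export
tilingSpec <- function(patchSize = 1000L, overlap = 100L,
                       padValue = c(255L, 255L, 255L)) {
  new("TilingSpec", patchSize = as.integer(patchSize),
      overlap = as.integer(overlap), padValue = as.integer(padValue))
}

# per-axis anchor set: stride = patchSize - overlap, clamped so the last
# patch ends at the (padded) image edge
.axis_anchors <- function(dimPadded, patchSize, overlap) {
  stride <- patchSize - overlap
  last <- dimPadded - patchSize
  a <- seq.int(0L, last, by = stride)
  if (tail(a, 1L) != last) a <- c(a, last)
  as.integer(a)
}

#' Plan an overlapping patch tiling over an ROI
#'
#' Anchors advance with stride \code{patchSize - overlap}; the final anchor
#' per axis is clamped so the patch ends at the image edge. Images smaller
#' than one patch are padded (bottom/right) to the patch size with
#' \code{padValue}. Patches whose extent lies fully outside the ROI
#' bounding box are omitted; because the bounding box is rectangular, the
#' retained anchors remain a full row-major grid, which is what makes
#' stitching exact.
#'
#' @param imageDims H, W of the image
#' @param roi an \code{\linkS4class{ROIMask}} (non-empty)
#' @param spec a \code{\linkS4class{TilingSpec}}
#' @param slideId slide identifier carried into the grid
#' @return a \code{\linkS4class{PatchGrid}}
#' @export
planTiles <- function(imageDims, roi, spec = tilingSpec(),
                      slideId = "slide") {
  stopifnot(is(spec, "TilingSpec"))
  m <- if (is(roi, "ROIMask")) roi@mask else roi
  if (!any(m)) stop("ROI is empty: no pixels to tile")
  H <- as.integer(imageDims[1]); W <- as.integer(imageDims[2])
  stopifnot(all(dim(m) == c(H, W)))
  padded <- pmax(c(H, W), spec@patchSize)
  ar <- .axis_anchors(padded[1], spec@patchSize, spec@overlap)
  ac <- .axis_anchors(padded[2], spec@patchSize, spec@overlap)
  # ROI bounding box (0-based, inclusive)
  rows <- which(rowSums(m) > 0); cols <- which(colSums(m) > 0)
  rmin <- min(rows) - 1L; rmax <- max(rows) - 1L
  cmin <- min(cols) - 1L; cmax <- max(cols) - 1L
  ar <- ar[ar + spec@patchSize > rmin & ar <= rmax]
  ac <- ac[ac + spec@patchSize > cmin & ac <= cmax]
  anchors <- cbind(row = rep(ar, each = length(ac)),
                   col = rep(ac, times = length(ar)))
  new("PatchGrid", slideId = slideId, anchors = anchors,
      patchSize = spec@patchSize, overlap = spec@overlap,
      imageDims = c(H, W), paddedDims = as.integer(padded),
      padValue = spec@padValue)
}

#' Extract one patch from an image according to a grid
#'
#' @param image a \code{\linkS4class{CalibratedImage}} or H x W x 3 array
#' @param grid a \code{\linkS4class{PatchGrid}}
#' @param index 1-based anchor index (row-major order)
#' @return patchSize x patchSize x 3 integer array; out-of-image area is
#'   filled with the grid's pad value
#' @export
extractPatch <- function(image, grid, index) {
  stopifnot(is(grid, "PatchGrid"))
  if (index < 1L || index > nrow(grid@anchors))
    stop("patch index out of range: ", index, " (grid has ",
         nrow(grid@anchors), " patches)")
  px <- if (is(image, "CalibratedImage")) image@pixels else image
  P <- grid@patchSize
  a <- grid@anchors[index, ]
  out <- array(rep(grid@padValue, each = P * P), c(P, P, 3L))
  r0 <- a[1]; c0 <- a[2]
  nr <- min(P, dim(px)[1] - r0); nc <- min(P, dim(px)[2] - c0)
  if (nr > 0 && nc > 0)
    out[seq_len(nr), seq_len(nc), ] <-
      px[r0 + seq_len(nr), c0 + seq_len(nc), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Extract the patch of a single-channel mask under a grid anchor
#'
#' @param mask logical or numeric H x W matrix
#' @param grid a \code{\linkS4class{PatchGrid}}
#' @param index 1-based anchor index
#' @param pad fill value outside the image (default FALSE/0)
#' @return patchSize x patchSize matrix
#' @export
extractMaskPatch <- function(mask, grid, index, pad = FALSE) {
  stopifnot(is(grid, "PatchGrid"))
  if (index < 1L || index > nrow(grid@anchors))
    stop("patch index out of range: ", index)
  P <- grid@patchSize
  a <- grid@anchors[index, ]
  out <- matrix(pad, P, P)
  r0 <- a[1]; c0 <- a[2]
  nr <- min(P, nrow(mask) - r0); nc <- min(P, ncol(mask) - c0)
  if (nr > 0 && nc > 0)
    out[seq_len(nr), seq_len(nc)] <- mask[r0 + seq_len(nr), c0 + seq_len(nc)]
  out
}
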