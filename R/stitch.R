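#' Stitch patch masks back into a section mask
#'
#' Re-concatenates (possibly overlapping) patch masks without boundary
#' effects or double counting: every section pixel takes its value from
#' exactly one source patch -- the one whose center is nearest to the
#' pixel, with ties resolved toward the earlier anchor in row-major order.
#' Equivalently, overlap margins are center-cropped. The result is cropped
#' to the original (pre-padding) image dims and binarized.
#'
#' @param grid the \code{\linkS4class{PatchGrid}} the patches were cut with
#' @param patchMasks list with one entry per grid anchor (same order):
#'   \code{\linkS4class{ProbabilityMask}}, \code{\linkS4class{BinaryMask}}
#'   or plain matrix
#' @param threshold binarization threshold applied to probability values
#'   (ignored for already-binary input)
#' @return a \code{\linkS4class{BinaryMask}} with provenance
#'   \code{predicted}
#' @export
stitchMasks <- function(grid, patchMasks, threshold = 0.5) {
  stopifnot(is(grid, "PatchGrid"))
  n <- nrow(grid@anchors)
  if (length(patchMasks) != n || any(vapply(patchMasks, is.null, logical(1)))) {
    missing <- if (length(patchMasks) < n)
      seq.int(length(patchMasks) + 1L, n)
    else which(vapply(patchMasks, is.null, logical(1)))
    stop("missing patch masks for anchors: ",
         paste(apply(grid@anchors[missing, , drop = FALSE], 1L, paste,
                     collapse = ","), collapse = "; "))
  }
  P <- grid@patchSize
  H <- grid@imageDims[1]; W <- grid@imageDims[2]
  ar <- sort(unique(grid@anchors[, 1]))
  ac <- sort(unique(grid@anchors[, 2]))
  out <- matrix(FALSE, H, W)

  # per-axis ownership: cut between consecutive anchors at the midpoint of
  # their patch centers; a pixel exactly on the cut goes to the earlier
  # anchor (row-major tie rule)
  .owned <- function(a, dimLen) {
    centers <- a + P / 2
    cuts <- (head(centers, -1L) + tail(centers, -1L)) / 2
    lo <- c(a[1], ceiling(cuts))                  # first owned pixel (0-based)
    hi <- c(ceiling(cuts) - 1L, min(a[length(a)] + P - 1L, dimLen - 1L))
    lo[1] <- max(lo[1], 0L)
    cbind(lo = lo, hi = pmin(hi, dimLen - 1L))
  }
  ownR <- .owned(ar, H)
  ownC <- .owned(ac, W)

  for (i in seq_len(n)) {
    a <- grid@anchors[i, ]
    m <- patchMasks[[i]]
    bin <- if (is(m, "ProbabilityMask")) m@probs >= threshold
           else if (is(m, "BinaryMask")) m@mask
           else if (is.logical(m)) m
           else m >= threshold
    if (!all(dim(bin) == c(P, P)))
      stop("patch mask ", i, " has wrong shape")
    ri <- match(a[1], ar); ci <- match(a[2], ac)
    r0 <- ownR[ri, "lo"]; r1 <- ownR[ri, "hi"]
    c0 <- ownC[ci, "lo"]; c1 <- ownC[ci, "hi"]
    if (r1 < r0 || c1 < c0) next
    out[seq.int(r0 + 1L, r1 + 1L), seq.int(c0 + 1L, c1 + 1L)] <-
      bin[seq.int(r0 - a[1] + 1L, r1 - a[1] + 1L),
          seq.int(c0 - a[2] + 1L, c1 - a[2] + 1L)]
  }
  BinaryMask(out, provenance = "predicted")
}
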