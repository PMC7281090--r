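#' Construct ThresholdParams for the weak-label bootstrap
#'
#' @param luminancePercentile per-patch dark-pixel percentile cut (default 5)
#' @param maxLuminance absolute luminance cap, 8-bit units (default 110)
#' @param minChannelRatio red/green ratio at or above which dark pixels are
#'   treated as counterstain rather than silver (default 1.35)
#' @param openKernel square opening kernel side in px (odd, default 3)
#' @param closeKernel square closing kernel side in px (odd, default 3)
#' @return a \code{\linkS4class{ThresholdParams}}
#' @export
thresholdParams <- function(luminancePercentile = 5, maxLuminance = 110,
                            minChannelRatio = 1.35, openKernel = 3L,
                            closeKernel = 3L) {
  new("ThresholdParams", luminancePercentile = luminancePercentile,
      maxLuminance = maxLuminance, minChannelRatio = minChannelRatio,
      openKernel = as.integer(openKernel), closeKernel = as.integer(closeKernel))
}

#' Default threshold-parameter grid for consensus selection
#'
#' Candidate parameterizations standing in for the manually tuned set from
#' which masks are selected. The candidates vary the dynamic-percentile
#' cut: on signal-dense patches a low percentile truncates genuine
#' deposits (the cut lands inside the deposit luminance range), making the
#' truncated mask the odd one out, so consensus selection recovers the
#' fuller mask — the reproducible analogue of discarding visibly
#' undersegmented candidates by eye.
#'
#' @return list of \code{\linkS4class{ThresholdParams}}
#' @export
defaultThresholdGrid <- function() {
  list(thresholdParams(),
       thresholdParams(luminancePercentile = 15),
       thresholdParams(luminancePercentile = 30, maxLuminance = 125,
                       minChannelRatio = 1.5))
}

# red/green ratio with the 0/0 case defined as achromatic (ratio 1);
# x/0 with x > 0 is Inf, i.e. always vetoed
.red_green_ratio <- function(R, G) {
  r <- R / G
  r[R == 0 & G == 0] <- 1
  r
}

# binary morphology via EBImage; square box kernels
.morph_open_close <- function(m, openK, closeK) {
  x <- m * 1
  if (openK > 1L)
    x <- EBImage::opening(x, EBImage::makeBrush(openK, "box"))
  if (closeK > 1L)
    x <- EBImage::closing(x, EBImage::makeBrush(closeK, "box"))
  matrix(as.logical(x > 0.5), nrow(m), ncol(m))
}

#' Weak-label a patch by dynamic thresholding plus morphology
#'
#' A pixel is raw-positive iff its luminance (R+G+B)/3 is at most
#' min(dynamic cut, maxLuminance) -- the dynamic cut being the patch's
#' \code{luminancePercentile} luminance quantile -- and its red/green
#' ratio is below \code{minChannelRatio} (dark red-dominant pixels are
#' Nuclear-Fast-Red counterstain, not silver). Morphological opening then
#' closing with the square kernels cleans the raw mask.
#'
#' @param patch 8-bit RGB array (H x W x 3, integer values in [0, 255])
#' @param params a \code{\linkS4class{ThresholdParams}}
#' @return a \code{\linkS4class{BinaryMask}} with provenance
#'   \code{weak_label}
#' @export
weakLabel <- function(patch, params = thresholdParams()) {
  stopifnot(is(params, "ThresholdParams"))
  if (length(dim(patch)) != 3L || dim(patch)[3] != 3L)
    stop("patch must be H x W x 3")
  if (any(patch < 0) || any(patch > 255) || any(patch != round(patch)))
    stop("patch must be 8-bit (integer values in [0, 255])")
  lum <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  cut <- min(quantile(lum, params@luminancePercentile / 100, names = FALSE),
             params@maxLuminance)
  ratio <- .red_green_ratio(patch[, , 1], patch[, , 2])
  raw <- lum <= cut & ratio < params@minChannelRatio
  BinaryMask(.morph_open_close(raw, params@openKernel, params@closeKernel),
             provenance = "weak_label")
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#'
#' @param a,b \code{\linkS4class{BinaryMask}} objects or logical matrices
#' @return IoU in [0, 1]
#' @export
maskIoU <- function(a, b) {
  ma <- if (is(a, "BinaryMask")) a@mask else a
  mb <- if (is(b, "BinaryMask")) b@mask else b
  if (!all(dim(ma) == dim(mb)))
    stop("mask shapes differ: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  u <- sum(ma | mb)
  if (u == 0L) return(1)
  sum(ma & mb) / u
}

#' Select the best weak-label mask per patch by consensus
#'
#' An automated proxy for manual mask selection: among the candidate masks
#' of one patch, pick the one maximizing mean pairwise IoU with the other
#' candidates (consensus score); ties are broken by smallest positive-pixel
#' count, then first occurrence. An explicit correction mask, when
#' provided, overrides the selection verbatim (the hook through which
#' manual corrections re-enter the pipeline as data).
#'
#' @param candidates non-empty list of \code{\linkS4class{BinaryMask}}
#'   objects (or logical matrices) for one patch
#' @param correction optional override mask returned verbatim
#' @return list with \code{mask} (a \code{BinaryMask}), \code{index} of the
#'   chosen candidate (NA under override) and its \code{score}
#' @export
selectMask <- function(candidates, correction = NULL) {
  if (!is.null(correction)) {
    m <- if (is(correction, "BinaryMask")) correction@mask else correction
    return(list(mask = BinaryMask(m, provenance = "weak_label"),
                index = NA_integer_, score = NA_real_))
  }
  n <- length(candidates)
  if (n == 0L) stop("candidate list must be non-empty")
  ms <- lapply(candidates,
               function(x) if (is(x, "BinaryMask")) x@mask else x)
  if (n == 1L)
    return(list(mask = BinaryMask(ms[[1]], provenance = "weak_label"),
                index = 1L, score = 1))
  iou <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    v <- maskIoU(ms[[i]], ms[[j]])
    iou[i, j] <- v; iou[j, i] <- v
  }
  score <- (rowSums(iou) - 1) / (n - 1)           # mean IoU with the others
  pos <- vapply(ms, sum, numeric(1))
  best <- order(-score, pos, seq_len(n))[1]
  list(mask = BinaryMask(ms[[best]], provenance = "weak_label"),
       index = best, score = score[best])
}

#' Select masks for a list of patches
#'
#' Applies \code{\link{selectMask}} patch-wise.
#'
#' @param candidatesPerPatch list (per patch) of candidate-mask lists
#' @param corrections optional list of override masks (NULL entries mean no
#'   override)
#' @return list of selection results as from \code{\link{selectMask}}
#' @export
selectMasks <- function(candidatesPerPatch, corrections = NULL) {
  lapply(seq_along(candidatesPerPatch), function(i) {
    corr <- if (!is.null(corrections) && length(corrections) >= i)
      corrections[[i]] else NULL
    selectMask(candidatesPerPatch[[i]], corr)
  })
}
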