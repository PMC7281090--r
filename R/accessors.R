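#' @name accessors
#' @title Accessors for AuNPquant classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param object an AuNPquant object
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "CalibratedImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("mpp", function(object) standardGeneric("mpp"))
#' @rdname accessors
#' @export
setMethod("mpp", "CalibratedImage", function(object) object@mpp)

#' @rdname accessors
#' @export
setGeneric("organLabel", function(object) standardGeneric("organLabel"))
#' @rdname accessors
#' @export
setMethod("organLabel", "CalibratedImage", function(object) object@organLabel)

#' @rdname accessors
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setMethod("slideId", "CalibratedImage", function(object) object@slideId)
#' @rdname accessors
#' @export
setMethod("slideId", "PatchGrid", function(object) object@slideId)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "BinaryMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ROIMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ProbabilityMask",
          function(object) object@probs >= object@threshold)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "BinaryMask", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))
#' @rdname accessors
#' @export
setMethod("probs", "ProbabilityMask", function(object) object@probs)

#' @rdname accessors
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))
#' @rdname accessors
#' @export
setMethod("anchors", "PatchGrid", function(object) object@anchors)

#' @rdname accessors
#' @export
setGeneric("patchSize", function(object) standardGeneric("patchSize"))
#' @rdname accessors
#' @export
setMethod("patchSize", "PatchGrid", function(object) object@patchSize)
#' @rdname accessors
#' @export
setMethod("patchSize", "TilingSpec", function(object) object@patchSize)

#' @rdname accessors
#' @export
setGeneric("imageDims", function(object) standardGeneric("imageDims"))
#' @rdname accessors
#' @export
setMethod("imageDims", "PatchGrid", function(object) object@imageDims)
#' @rdname accessors
#' @export
setMethod("imageDims", "CalibratedImage",
          function(object) dim(object@pixels)[1:2])

#' @rdname accessors
#' @export
setGeneric("foldOf", function(object) standardGeneric("foldOf"))
#' @rdname accessors
#' @export
setMethod("foldOf", "FoldAssignment", function(object) object@folds)

#' @rdname accessors
#' @export
setGeneric("nFolds", function(object) standardGeneric("nFolds"))
#' @rdname accessors
#' @export
setMethod("nFolds", "FoldAssignment", function(object) object@k)

#' Train/test slide lists for one rotation of a fold assignment
#'
#' In rotation \code{r}, the test set is fold \code{r} and the training set
#' is every other fold; over all rotations each slide is tested exactly once.
#'
#' @param assignment a \code{FoldAssignment}
#' @param rotation rotation index in 1..k
#' @return list with character vectors \code{train} and \code{test}
#' @export
rotationSlides <- function(assignment, rotation) {
  stopifnot(is(assignment, "FoldAssignment"))
  if (rotation < 1L || rotation > assignment@k)
    stop("rotation must lie in 1..k")
  f <- assignment@folds
  list(train = names(f)[f != rotation], test = names(f)[f == rotation])
}

#' @rdname accessors
#' @export
setGeneric("lossLog", function(object) standardGeneric("lossLog"))
#' @rdname accessors
#' @export
setMethod("lossLog", "Segmenter", function(object) object@lossLog)

#' @rdname accessors
#' @export
setGeneric("trainSlides", function(object) standardGeneric("trainSlides"))
#' @rdname accessors
#' @export
setMethod("trainSlides", "Segmenter", function(object) object@trainSlides)

#' @rdname accessors
#' @export
setGeneric("organStats", function(object) standardGeneric("organStats"))
#' @rdname accessors
#' @export
setMethod("organStats", "BiodistributionReport",
          function(object) object@organStats)

#' @rdname accessors
#' @export
setGeneric("sizeHistograms", function(object) standardGeneric("sizeHistograms"))
#' @rdname accessors
#' @export
setMethod("sizeHistograms", "BiodistributionReport",
          function(object) object@histograms)

#' @rdname accessors
#' @export
setGeneric("dominantBin", function(object) standardGeneric("dominantBin"))
#' @rdname accessors
#' @export
setMethod("dominantBin", "BiodistributionReport",
          function(object) object@dominantBin)

#' @rdname accessors
#' @export
setGeneric("slideStats", function(object) standardGeneric("slideStats"))
#' @rdname accessors
#' @export
setMethod("slideStats", "BiodistributionReport",
          function(object) object@slideStats)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage '%s' (%s): %d x %d px, mpp = %g um/px (%.4g mm^2)\n",
              object@slideId, object@organLabel, d[1], d[2], object@mpp,
              d[1] * d[2] * object@mpp^2 / 1e6))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask [%s]: %d x %d, %d positive px (%.3f%%)\n",
              object@provenance, nrow(object@mask), ncol(object@mask),
              sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf(
    "PatchGrid '%s': %d patches of %d px (overlap %d) on %d x %d (padded %d x %d)\n",
    object@slideId, nrow(object@anchors), object@patchSize, object@overlap,
    object@imageDims[1], object@imageDims[2],
    object@paddedDims[1], object@paddedDims[2]))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d slides in %d folds (sizes: %s)\n",
              length(object@folds), object@k,
              paste(tabulate(object@folds, object@k), collapse = ", ")))
})

setMethod("show", "Segmenter", function(object) {
  ms <- object@modelSpec
  cat(sprintf(
    "Segmenter: U-Net-like, %d levels, %d base channels; trained on %d slides; final loss %.4g\n",
    ms@levels, ms@baseChannels, length(object@trainSlides),
    tail(object@lossLog, 1)))
})

setMethod("show", "BiodistributionReport", function(object) {
  cat("BiodistributionReport\n")
  df <- object@organStats
  ord <- order(-df$mean_px_per_mm2)
  for (i in ord)
    cat(sprintf("  %-10s %10.1f +/- %8.1f px/mm^2  %6.3f%% positive  dominant bin %s\n",
                df$organ[i], df$mean_px_per_mm2[i], df$sd_px_per_mm2[i],
                df$mean_percent_positive[i],
                object@dominantBin[df$organ[i]]))
})
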