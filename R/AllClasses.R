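#' @import methods
#' @importFrom stats quantile rnorm runif rpois rlnorm sd setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib AuNPquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Pixel conventions used throughout the package:
#  - arrays are indexed [row, col(, channel)], 0-based anchors, row-major order;
#  - polygon vertices are (x = col, y = row) in pixel units;
#  - pixel centers sit at integer coordinate + 0.5;
#  - channel values are 8-bit integers in [0, 255];
#  - mpp (microns per pixel) is isotropic and strictly positive.

#' CalibratedImage: an 8-bit RGB section image with physical calibration
#'
#' The unit every downstream quantity is measured against: pixel data plus
#' the microns-per-pixel scale that converts pixel counts into areas
#' (um^2) and densities (per mm^2), and the slide identity that drives
#' slide-level fold rotation.
#'
#' @slot pixels integer array H x W x 3, values in [0, 255]
#' @slot mpp microns per pixel, isotropic, > 0
#' @slot organLabel free-text organ label (e.g. "tumor", "spleen")
#' @slot slideId unique slide identifier
#' @exportClass CalibratedImage
setClass("CalibratedImage",
  representation(pixels = "array", mpp = "numeric",
                 organLabel = "character", slideId = "character"))

setValidity("CalibratedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image must be at least 1 x 1")
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a single positive number")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 255) return("channel values must lie in [0, 255]")
  if (length(object@slideId) != 1L || !nzchar(object@slideId))
    return("slideId must be a non-empty string")
  TRUE
})

#' ROIMask: a region-of-interest delineation aligned to an image
#'
#' @slot mask logical H x W matrix
#' @slot source "polygon" or "raster"
#' @exportClass ROIMask
setClass("ROIMask", representation(mask = "matrix", source = "character"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!object@source %in% c("polygon", "raster"))
    return("source must be 'polygon' or 'raster'")
  TRUE
})

#' BinaryMask: per-pixel AuNP-positive labels
#'
#' @slot mask logical H x W matrix
#' @slot provenance one of "ground_truth", "weak_label", "predicted"
#' @exportClass BinaryMask
setClass("BinaryMask", representation(mask = "matrix", provenance = "character"))

.mask_provenances <- c("ground_truth", "weak_label", "predicted")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!object@provenance %in% .mask_provenances)
    return(paste("provenance must be one of:",
                 paste(.mask_provenances, collapse = ", ")))
  TRUE
})

#' ProbabilityMask: per-pixel AuNP probabilities from the segmenter
#'
#' @slot probs numeric H x W matrix in [0, 1]
#' @slot threshold binarization threshold (default 0.5)
#' @exportClass ProbabilityMask
setClass("ProbabilityMask",
  representation(probs = "matrix", threshold = "numeric"))

setValidity("ProbabilityMask", function(object) {
  if (!is.numeric(object@probs)) return("probs must be numeric")
  rng <- range(object@probs)
  if (rng[1] < 0 || rng[2] > 1) return("probabilities must lie in [0, 1]")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' TilingSpec: fixed-size overlapping patch plan parameters
#'
#' @slot patchSize patch edge in pixels (default 1000)
#' @slot overlap overlap between adjacent patches in pixels (default 100)
#' @slot padValue RGB triple used to fill out-of-image area
#' @exportClass TilingSpec
setClass("TilingSpec",
  representation(patchSize = "integer", overlap = "integer",
                 padValue = "integer"))

setValidity("TilingSpec", function(object) {
  if (object@patchSize < 1L) return("patchSize must be >= 1")
  if (object@overlap <= 0L || object@overlap >= object@patchSize)
    return("overlap must satisfy 0 < overlap < patchSize")
  if (length(object@padValue) != 3L || any(object@padValue < 0L) ||
      any(object@padValue > 255L))
    return("padValue must be an RGB triple in [0, 255]")
  TRUE
})

#' PatchGrid: the tiling plan for one slide
#'
#' Carries the bookkeeping (anchors, overlap, padding extents) that lets
#' \code{\link{stitchMasks}} re-concatenate patch masks without boundary
#' effects or double counting.
#'
#' @slot slideId slide identifier
#' @slot anchors n x 2 integer matrix of 0-based (row, col) top-left positions,
#'   sorted row-major
#' @slot patchSize patch edge in pixels
#' @slot overlap nominal overlap in pixels
#' @slot imageDims original (pre-padding) H, W
#' @slot paddedDims H, W after bottom/right padding
#' @slot padValue RGB fill for out-of-image area
#' @exportClass PatchGrid
setClass("PatchGrid",
  representation(slideId = "character", anchors = "matrix",
                 patchSize = "integer", overlap = "integer",
                 imageDims = "integer", paddedDims = "integer",
                 padValue = "integer"))

setValidity("PatchGrid", function(object) {
  if (ncol(object@anchors) != 2L) return("anchors must be n x 2")
  if (nrow(object@anchors) < 1L) return("at least one anchor required")
  if (any(object@anchors < 0L)) return("anchors must be non-negative")
  if (any(object@anchors[, 1] + object@patchSize > object@paddedDims[1]) ||
      any(object@anchors[, 2] + object@patchSize > object@paddedDims[2]))
    return("anchors must keep patches inside the padded image")
  TRUE
})

#' ThresholdParams: weak-label thresholding and morphology parameters
#'
#' The weak-supervision bootstrap classifies a pixel as raw-positive when
#' its luminance (R+G+B)/3 falls at or below min(dynamic cut, maxLuminance)
#' -- the dynamic cut being the patch's \code{luminancePercentile} luminance
#' quantile -- AND its red/green ratio stays below \code{minChannelRatio}
#' (dark but red-dominant pixels are counterstain, not silver). Morphological
#' opening then closing with square kernels cleans the raw mask.
#'
#' @slot luminancePercentile per-patch dark-pixel percentile cut, in (0, 50]
#' @slot maxLuminance absolute luminance cap in 8-bit units
#' @slot minChannelRatio red/green ratio at or above which dark pixels are
#'   vetoed as counterstain
#' @slot openKernel square opening kernel side (odd, >= 1)
#' @slot closeKernel square closing kernel side (odd, >= 1)
#' @exportClass ThresholdParams
setClass("ThresholdParams",
  representation(luminancePercentile = "numeric", maxLuminance = "numeric",
                 minChannelRatio = "numeric", openKernel = "integer",
                 closeKernel = "integer"))

setValidity("ThresholdParams", function(object) {
  if (object@luminancePercentile <= 0 || object@luminancePercentile > 50)
    return("luminancePercentile must lie in (0, 50]")
  if (object@maxLuminance <= 0 || object@maxLuminance >= 255)
    return("maxLuminance must lie in (0, 255)")
  if (object@minChannelRatio <= 0) return("minChannelRatio must be > 0")
  for (k in c(object@openKernel, object@closeKernel))
    if (k < 1L || k %% 2L == 0L) return("kernels must be odd and >= 1")
  TRUE
})

#' DepositMixture: log-normal mixture over deposit areas (um^2)
#'
#' Deposit areas are drawn from a mixture of log-normal components; each
#' component is given by a weight, the median area in um^2 (the geometric
#' mean of the log-normal), and the log-scale standard deviation.
#'
#' @slot weights component weights, positive, summing to 1
#' @slot medianArea per-component median area in um^2, > 0
#' @slot sdLog per-component log-scale sd, >= 0
#' @exportClass DepositMixture
setClass("DepositMixture",
  representation(weights = "numeric", medianArea = "numeric",
                 sdLog = "numeric"))

setValidity("DepositMixture", function(object) {
  n <- length(object@weights)
  if (n < 1L) return("at least one component required")
  if (length(object@medianArea) != n || length(object@sdLog) != n)
    return("weights, medianArea, sdLog must have equal length")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@medianArea <= 0)) return("medianArea must be positive")
  if (any(object@sdLog < 0)) return("sdLog must be non-negative")
  TRUE
})

#' SyntheticSpec: parameters of one synthetic pseudo-histology section
#'
#' Emulates a silver-enhancement-stained, Nuclear-Fast-Red-counterstained
#' section: dark achromatic deposits on a pale tissue background scattered
#' with red-pink nuclei.
#'
#' @slot dims H, W in pixels
#' @slot mpp microns per pixel
#' @slot depositDensity expected deposits per mm^2 (>= 0)
#' @slot mixture a \code{DepositMixture} over deposit areas
#' @slot palette 3 x 3 integer matrix, rows = tissue background, nuclear
#'   counterstain, deposit; columns = R, G, B
#' @slot noiseSd additive Gaussian channel noise sd (8-bit units)
#' @slot nucleiDensity expected nuclei per mm^2 (counterstain blobs)
#' @slot seed integer RNG seed
#' @slot fixedCount exact deposit count override (NA = Poisson draw)
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(dims = "integer", mpp = "numeric", depositDensity = "numeric",
                 mixture = "DepositMixture", palette = "matrix",
                 noiseSd = "numeric", nucleiDensity = "numeric",
                 seed = "integer", fixedCount = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@dims) != 2L || any(object@dims < 8L))
    return("dims must be H, W with both >= 8")
  if (object@mpp <= 0) return("mpp must be positive")
  if (object@depositDensity < 0) return("depositDensity must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!all(dim(object@palette) == c(3L, 3L)))
    return("palette must be 3 x 3 (background, counterstain, deposit) x RGB")
  lum <- rowMeans(object@palette)
  if (lum[3] >= lum[1] || lum[3] >= lum[2])
    return("deposit colour must be darker (lower luminance) than both background colours")
  TRUE
})

#' GroundTruth: the exact truth behind one synthetic section
#'
#' @slot mask a \code{BinaryMask} with provenance \code{ground_truth}
#' @slot components the planted-deposit \code{ComponentTable} (data.frame)
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(mask = "BinaryMask", components = "data.frame"))

#' OrganPreset: a named synthetic spec within the ranked organ family
#'
#' @slot name organ label
#' @slot spec the organ's \code{SyntheticSpec}
#' @exportClass OrganPreset
setClass("OrganPreset",
  representation(name = "character", spec = "SyntheticSpec"))

#' ModelSpec: U-Net-like architecture hyperparameters
#'
#' The network has \code{levels} encoder/decoder stages; each encoder stage
#' doubles the feature channels starting from \code{baseChannels}, so the
#' deepest (bottleneck) stage carries baseChannels x 2^levels channels.
#'
#' @slot levels encoder/decoder depth (default 4)
#' @slot baseChannels first-level feature channels (default 16)
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(levels = "integer", baseChannels = "integer"))

setValidity("ModelSpec", function(object) {
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  TRUE
})

#' TrainingSpec: segmenter training hyperparameters
#'
#' @slot epochs training epochs (default 10)
#' @slot batchSize mini-batch size
#' @slot learningRate Adam step size
#' @slot seed integer RNG seed for init and shuffling
#' @slot targetTrainPatches approximate training-set size, achieved by
#'   sub-tile crop sampling (with flips) when the cohort supplies fewer
#'   patches, or by subsampling when it supplies more
#' @slot trainPatchEdge edge of the (square) training crops in pixels
#' @exportClass TrainingSpec
setClass("TrainingSpec",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer",
                 targetTrainPatches = "integer", trainPatchEdge = "integer"))

setValidity("TrainingSpec", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@targetTrainPatches < 1L) return("targetTrainPatches must be >= 1")
  TRUE
})

#' FoldAssignment: slide-level k-fold partition
#'
#' Folds partition the slide set (disjoint, exhaustive); splitting is by
#' slide, never by patch, so that in rotation r the model segments only
#' slides it never trained on.
#'
#' @slot k fold count
#' @slot folds named integer vector mapping slide_id -> fold index (1..k)
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(k = "integer", folds = "integer"))

setValidity("FoldAssignment", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (is.null(names(object@folds))) return("folds must be named by slide_id")
  if (anyDuplicated(names(object@folds))) return("duplicate slide ids")
  if (!all(object@folds %in% seq_len(object@k)))
    return("fold indices must lie in 1..k")
  if (length(unique(object@folds)) != object@k)
    return("every fold must contain at least one slide")
  TRUE
})

#' Segmenter: a trained U-Net-like model handle
#'
#' @slot weights list of weight tensors (conv kernels and biases)
#' @slot modelSpec the \code{ModelSpec} it was built from
#' @slot trainSlides slide ids the model has seen (fold-leak guard)
#' @slot lossLog per-epoch mean training loss
#' @slot threshold default binarization threshold for its probability masks
#' @exportClass Segmenter
setClass("Segmenter",
  representation(weights = "list", modelSpec = "ModelSpec",
                 trainSlides = "character", lossLog = "numeric",
                 threshold = "numeric"))

#' BiodistributionReport: per-organ densities and size histograms
#'
#' The end product of the pipeline: for each organ, the mean and sd of
#' positive-pixel density (per mm^2) and percent-positive signal over its
#' replicate slides, the pooled deposit-size histogram, and the dominant
#' size bin.
#'
#' @slot organStats data.frame: organ, n_slides, mean_px_per_mm2,
#'   sd_px_per_mm2, mean_percent_positive, sd_percent_positive
#' @slot histograms named list (by organ) of size-histogram data.frames
#' @slot dominantBin named character vector: per-organ dominant bin label
#'   (NA when an organ has no deposits)
#' @slot slideStats per-slide density data.frame
#' @exportClass BiodistributionReport
setClass("BiodistributionReport",
  representation(organStats = "data.frame", histograms = "list",
                 dominantBin = "character", slideStats = "data.frame"))
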