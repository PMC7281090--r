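#' RunRecord: provenance of one pipeline run
#'
#' @slot config the config list the run executed
#' @slot foldAssignment the slide-level fold partition used
#' @slot report the measured \code{\linkS4class{BiodistributionReport}}
#' @slot truthReport the same report computed from ground-truth masks
#' @slot evaluation per-slide data.frame: organ, fold, weak-label and
#'   network IoU against ground truth, measured and true densities
#' @slot timings named stage timings in seconds
#' @slot outDir output directory ("" when nothing was written)
#' @exportClass RunRecord
setClass("RunRecord",
  representation(config = "list", foldAssignment = "FoldAssignment",
                 report = "BiodistributionReport",
                 truthReport = "BiodistributionReport",
                 evaluation = "data.frame", timings = "numeric",
                 outDir = "character"))

setMethod("show", "RunRecord", function(object) {
  cat(sprintf("RunRecord: %d slides, k = %d; stages [%s]\n",
              nrow(object@evaluation), object@foldAssignment@k,
              paste(sprintf("%s %.1fs", names(object@timings),
                            object@timings), collapse = ", ")))
  cat(sprintf("  mean held-out IoU: weak %.3f, network %.3f\n",
              mean(object@evaluation$iou_weak),
              mean(object@evaluation$iou_net)))
})

#' Assemble a pipeline configuration
#'
#' Defaults are the package's simulation-scale study conditions: a
#' 42-slide synthetic cohort (7 ranked organ presets x 6 replicates) of
#' 512 x 512 px sections at 0.25 um/px, tiled into 256-px patches with
#' 32 px overlap, weak-labelled with the default threshold grid, and
#' segmented by a compact U-Net-like model (2 levels, 4 base channels)
#' trained 10 epochs on 150 sampled patches per rotation under a k = 3
#' slide-level rotation.
#'
#' @param outDir output directory (NULL writes nothing)
#' @param seed master seed; all stage seeds derive from it
#' @param dims per-slide H, W
#' @param mpp microns per pixel
#' @param slidesPerOrgan replicates per organ preset
#' @param noiseSd synthetic channel noise sd
#' @param tiling a \code{\linkS4class{TilingSpec}}
#' @param thresholdGrid list of \code{\linkS4class{ThresholdParams}}
#'   candidates for consensus selection
#' @param model a \code{\linkS4class{ModelSpec}}
#' @param training a \code{\linkS4class{TrainingSpec}} (its seed is
#'   overridden per rotation from the master seed)
#' @param k fold count
#' @param binarizeThreshold probability binarization threshold
#' @param connectivity component connectivity (8 or 4)
#' @param binEdges size-histogram bin edges (um^2)
#' @return config list for \code{\link{runPipeline}}
#' @export
pipelineConfig <- function(outDir = NULL, seed = 1L,
                           dims = c(512L, 512L), mpp = 0.25,
                           slidesPerOrgan = 6L, noiseSd = 8,
                           tiling = tilingSpec(256L, 32L),
                           thresholdGrid = defaultThresholdGrid(),
                           model = modelSpec(2L, 4L),
                           training = trainingSpec(epochs = 10L,
                                                   batchSize = 2L,
                                                   learningRate = 1e-2,
                                                   targetTrainPatches = 150L,
                                                   trainPatchEdge = 256L),
                           k = 3L, binarizeThreshold = 0.5,
                           connectivity = 8L,
                           binEdges = defaultBinEdges()) {
  list(outDir = outDir, seed = as.integer(seed), dims = as.integer(dims),
       mpp = mpp, slidesPerOrgan = as.integer(slidesPerOrgan),
       noiseSd = noiseSd, tiling = tiling, thresholdGrid = thresholdGrid,
       model = model, training = training, k = as.integer(k),
       binarizeThreshold = binarizeThreshold,
       connectivity = as.integer(connectivity), binEdges = binEdges)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar keys mirror the arguments of \code{\link{pipelineConfig}};
#' nested keys \code{tiling}, \code{model}, \code{training} hold their
#' constructors' arguments.
#'
#' @param path YAML file
#' @param outDir output directory override
#' @return config list
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "dims", "mpp", "slidesPerOrgan", "noiseSd", "k",
               "binarizeThreshold", "connectivity", "binEdges"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$tiling)) args$tiling <- do.call(tilingSpec, y$tiling)
  if (!is.null(y$model)) args$model <- do.call(modelSpec, y$model)
  if (!is.null(y$training)) args$training <- do.call(trainingSpec, y$training)
  if (!is.null(outDir)) args$outDir <- outDir
  do.call(pipelineConfig, args)
}

.stage_seeds <- function(seed, k) {
  s <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L + k))
  list(cohort = s[1], folds = s[2], train = s[2L + seq_len(k)])
}

#' Run the full quantification pipeline on a synthetic cohort
#'
#' Executes simulate -> tile -> weak-label -> select -> folds -> train per
#' rotation -> segment held-out slides -> stitch -> quantify -> report.
#' All randomness flows from the master seed through named child seeds per
#' stage, so rerunning with one config reproduces all masks bit-exactly.
#' Because the cohort is synthetic, the run also evaluates itself: weak
#' and network IoU per held-out slide against ground truth, and a
#' ground-truth twin of the biodistribution report.
#'
#' @param config a config list from \code{\link{pipelineConfig}}
#' @param resume reuse stitched masks found in \code{outDir} from an
#'   earlier identical run instead of recomputing them
#' @param verbose print stage progress
#' @return a \code{\linkS4class{RunRecord}}
#' @export
runPipeline <- function(config = pipelineConfig(), resume = FALSE,
                        verbose = FALSE) {
  t_all <- list()
  tick <- function() Sys.time()
  tock <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say <- function(...) if (verbose) message(sprintf(...))
  out <- config$outDir
  writeOut <- !is.null(out)
  if (writeOut) {
    dir.create(file.path(out, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out, "report"), recursive = TRUE,
               showWarnings = FALSE)
  }
  maskPath <- function(sid, kind)
    file.path(out, "masks", sprintf("%s_%s.png", sid, kind))

  # -- simulate -------------------------------------------------------------
  seeds <- .stage_seeds(config$seed, config$k)
  t0 <- tick()
  presets <- organPresets(dims = config$dims, mpp = config$mpp,
                          noiseSd = config$noiseSd)
  cohort <- makeCohort(presets, config$slidesPerOrgan, seeds$cohort)
  ids <- vapply(cohort, function(s) slideId(s$image), character(1))
  organs <- vapply(cohort, function(s) organLabel(s$image), character(1))
  names(cohort) <- ids
  t_all$simulate <- tock(t0)
  say("simulated %d slides (%.1fs)", length(ids), t_all$simulate)

  roi <- rasterROI(matrix(TRUE, config$dims[1], config$dims[2]))
  grids <- lapply(ids, function(sid)
    planTiles(config$dims, roi, config$tiling, slideId = sid))
  names(grids) <- ids

  canResume <- resume && writeOut &&
    all(file.exists(vapply(ids, maskPath, character(1), kind = "weak"))) &&
    all(file.exists(vapply(ids, maskPath, character(1), kind = "pred"))) &&
    file.exists(file.path(out, "folds.csv"))

  # -- weak labels ----------------------------------------------------------
  t0 <- tick()
  weakMasks <- list()
  if (canResume) {
    for (sid in ids)
      weakMasks[[sid]] <- loadMask(maskPath(sid, "weak"), "weak_label")@mask
  } else {
    for (sid in ids) {
      grid <- grids[[sid]]
      sel <- vector("list", nrow(anchors(grid)))
      for (i in seq_along(sel)) {
        patch <- extractPatch(cohort[[sid]]$image, grid, i)
        cand <- lapply(config$thresholdGrid, function(p) weakLabel(patch, p))
        sel[[i]] <- selectMask(cand)$mask
      }
      weakMasks[[sid]] <- stitchMasks(grid, sel)@mask
      if (writeOut) saveMask(weakMasks[[sid]], maskPath(sid, "weak"))
    }
  }
  t_all$weak_label <- tock(t0)
  say("weak labels done (%.1fs)", t_all$weak_label)

  # -- folds ----------------------------------------------------------------
  foldsA <- if (canResume) {
    fdf <- read.csv(file.path(out, "folds.csv"))
    new("FoldAssignment", k = config$k,
        folds = setNames(as.integer(fdf$fold), fdf$slide_id)[ids])
  } else makeFolds(ids, config$k, seeds$folds)
  if (writeOut && !canResume)
    write.csv(data.frame(slide_id = ids, fold = foldOf(foldsA)[ids]),
              file.path(out, "folds.csv"), row.names = FALSE)

  # -- train + segment per rotation ----------------------------------------
  t0 <- tick()
  predMasks <- list()
  if (canResume) {
    for (sid in ids)
      predMasks[[sid]] <- loadMask(maskPath(sid, "pred"), "predicted")@mask
    t_all$segment <- tock(t0); t_all$train <- 0
  } else {
    t_train <- 0
    for (r in seq_len(config$k)) {
      rot <- rotationSlides(foldsA, r)
      combos <- do.call(rbind, lapply(rot$train, function(sid)
        data.frame(sid = sid, idx = seq_len(nrow(anchors(grids[[sid]]))))))
      tspec <- config$training
      tspec@seed <- seeds$train[r]
      nPick <- min(tspec@targetTrainPatches, nrow(combos))
      pick <- .with_seed(seeds$train[r] + 1L,
                         sample.int(nrow(combos), nPick))
      patches <- vector("list", nPick); labels <- vector("list", nPick)
      for (j in seq_len(nPick)) {
        sid <- combos$sid[pick[j]]; i <- combos$idx[pick[j]]
        patches[[j]] <- extractPatch(cohort[[sid]]$image, grids[[sid]], i)
        labels[[j]] <- extractMaskPatch(weakMasks[[sid]], grids[[sid]], i)
      }
      tspec@targetTrainPatches <- nPick
      tt <- tick()
      seg <- trainSegmenter(patches, labels, config$model, tspec,
                            trainSlides = rot$train,
                            threshold = config$binarizeThreshold)
      t_train <- t_train + tock(tt)
      say("rotation %d/%d trained (final loss %.4f)", r, config$k,
          tail(lossLog(seg), 1))
      for (sid in rot$test) {
        grid <- grids[[sid]]
        pm <- lapply(seq_len(nrow(anchors(grid))), function(i)
          segmentPatch(extractPatch(cohort[[sid]]$image, grid, i), seg,
                       slideId = sid))
        predMasks[[sid]] <- stitchMasks(grid, pm,
                                        config$binarizeThreshold)@mask
        if (writeOut) saveMask(predMasks[[sid]], maskPath(sid, "pred"))
      }
    }
    t_all$train <- t_train
    t_all$segment <- tock(t0) - t_train
  }
  say("training %.1fs, inference %.1fs", t_all$train, t_all$segment)

  # -- quantify -------------------------------------------------------------
  t0 <- tick()
  quantifyAll <- function(masks, provenanceTables = NULL) {
    stats <- do.call(rbind, lapply(ids, function(sid)
      quantifyDensity(masks[[sid]], roi, config$mpp,
                      organLabel = organs[match(sid, ids)], slideId = sid)))
    tables <- if (is.null(provenanceTables))
      lapply(ids, function(sid)
        findComponents(masks[[sid]] & roi@mask, config$mpp, slideId = sid,
                       connectivity = config$connectivity))
    else provenanceTables
    buildReport(stats, tables, config$binEdges)
  }
  report <- quantifyAll(predMasks)
  truthMasks <- lapply(cohort, function(s) s$truth@mask@mask)
  truthReport <- quantifyAll(truthMasks,
                             lapply(cohort, function(s) s$truth@components))
  evaluation <- do.call(rbind, lapply(ids, function(sid) {
    tm <- truthMasks[[sid]]
    data.frame(slide_id = sid, organ = organs[match(sid, ids)],
               fold = foldOf(foldsA)[[sid]],
               iou_weak = maskIoU(weakMasks[[sid]], tm),
               iou_net = maskIoU(predMasks[[sid]], tm),
               px_per_mm2_net =
                 report@slideStats$positive_px_per_mm2[
                   report@slideStats$slide_id == sid],
               px_per_mm2_truth =
                 truthReport@slideStats$positive_px_per_mm2[
                   truthReport@slideStats$slide_id == sid])
  }))
  t_all$quantify <- tock(t0)

  if (writeOut) {
    write.csv(report@slideStats,
              file.path(out, "report", "slide_density.csv"),
              row.names = FALSE)
    write.csv(report@organStats,
              file.path(out, "report", "organ_density.csv"),
              row.names = FALSE)
    write.csv(evaluation, file.path(out, "report", "evaluation.csv"),
              row.names = FALSE)
    histDf <- do.call(rbind, lapply(names(report@histograms), function(o)
      cbind(organ = o, report@histograms[[o]])))
    write.csv(histDf, file.path(out, "report", "size_histograms.csv"),
              row.names = FALSE)
    snap <- config
    snap$tiling <- list(patchSize = config$tiling@patchSize,
                        overlap = config$tiling@overlap)
    snap$model <- list(levels = config$model@levels,
                       baseChannels = config$model@baseChannels)
    snap$training <- list(epochs = config$training@epochs,
                          batchSize = config$training@batchSize,
                          learningRate = config$training@learningRate,
                          targetTrainPatches =
                            config$training@targetTrainPatches,
                          trainPatchEdge = config$training@trainPatchEdge)
    snap$thresholdGrid <- lapply(config$thresholdGrid, function(p)
      list(luminancePercentile = p@luminancePercentile,
           maxLuminance = p@maxLuminance,
           minChannelRatio = p@minChannelRatio,
           openKernel = p@openKernel, closeKernel = p@closeKernel))
    snap$outDir <- NULL
    jsonlite::write_json(list(config = snap, timings = t_all,
                              version = as.character(
                                utils::packageVersion("AuNPquant"))),
                         file.path(out, "run_record.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  new("RunRecord", config = config, foldAssignment = foldsA,
      report = report, truthReport = truthReport, evaluation = evaluation,
      timings = unlist(t_all), outDir = if (writeOut) out else "")
}
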