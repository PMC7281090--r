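#' Identify individual deposits by connected-component analysis
#'
#' Labels connected sets of positive pixels (8-connectivity by default:
#' silver deposits are compact, so diagonal contact means one physical
#' aggregate) and returns one record per component with its physical area.
#' Component ids are deterministic, ordered by bounding-box top-left
#' (row, then col).
#'
#' @param mask a \code{\linkS4class{BinaryMask}} or logical matrix
#' @param mpp microns per pixel (> 0)
#' @param slideId slide identifier recorded per row
#' @param connectivity 8 (default) or 4
#' @return data.frame with columns component_id, slide_id, pixel_count,
#'   area_um2 (pixel_count x mpp^2), centroid_row, centroid_col,
#'   bbox_rmin, bbox_cmin, bbox_rmax, bbox_cmax (0-based, inclusive)
#' @export
findComponents <- function(mask, mpp, slideId = "slide", connectivity = 8L) {
  if (mpp <= 0) stop("mpp must be positive, got ", mpp)
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  empty <- data.frame(component_id = integer(), slide_id = character(),
                      pixel_count = integer(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_rmin = integer(), bbox_cmin = integer(),
                      bbox_rmax = integer(), bbox_cmax = integer())
  if (!any(m)) return(empty)
  lab <- cpp_label_components(m, as.integer(connectivity))
  pos <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[pos]
  r0 <- pos[, 1] - 1L; c0 <- pos[, 2] - 1L       # 0-based coordinates
  cnt <- tabulate(lv)
  df <- data.frame(
    pixel_count = cnt,
    area_um2 = cnt * mpp^2,
    centroid_row = as.numeric(tapply(r0 + 0.5, lv, mean)),
    centroid_col = as.numeric(tapply(c0 + 0.5, lv, mean)),
    bbox_rmin = as.integer(tapply(r0, lv, min)),
    bbox_cmin = as.integer(tapply(c0, lv, min)),
    bbox_rmax = as.integer(tapply(r0, lv, max)),
    bbox_cmax = as.integer(tapply(c0, lv, max)))
  df <- df[order(df$bbox_rmin, df$bbox_cmin), , drop = FALSE]
  rownames(df) <- NULL
  cbind(component_id = seq_len(nrow(df)), slide_id = slideId, df)
}

#' Positive-pixel density and percent-positive signal of one section
#'
#' Positive pixels outside the ROI are excluded. The percent-positive
#' denominator is the ROI pixel count (the only delineated reference
#' object); the density denominator is the ROI area in mm^2.
#'
#' @param mask a \code{\linkS4class{BinaryMask}} or logical matrix
#' @param roi an \code{\linkS4class{ROIMask}} or logical matrix, same shape
#' @param mpp microns per pixel
#' @param organLabel organ label recorded in the row
#' @param slideId slide identifier
#' @return one-row data.frame: slide_id, organ, positive_px, roi_px,
#'   roi_area_mm2, positive_px_per_mm2, percent_positive
#' @export
quantifyDensity <- function(mask, roi, mpp, organLabel = "unknown",
                            slideId = "slide") {
  if (mpp <= 0) stop("mpp must be positive")
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  r <- if (is(roi, "ROIMask")) roi@mask else roi
  if (!all(dim(m) == dim(r))) stop("mask and ROI shapes differ")
  roiPx <- sum(r)
  if (roiPx == 0L) stop("ROI is empty")
  pos <- sum(m & r)
  roiMm2 <- roiPx * mpp^2 / 1e6
  data.frame(slide_id = slideId, organ = organLabel,
             positive_px = pos, roi_px = roiPx, roi_area_mm2 = roiMm2,
             positive_px_per_mm2 = pos / roiMm2,
             percent_positive = 100 * pos / roiPx)
}

#' Default deposit-size histogram bin edges (um^2)
#'
#' Brackets the ~1 um^2 and ~25 um^2 deposit classes emphasized in
#' targeted-AuNP histology while covering macrophage-scale aggregates.
#'
#' @return ascending numeric vector of bin edges ending in Inf
#' @export
defaultBinEdges <- function() c(0.25, 0.5, 2, 10, 50, 200, Inf)

#' Deposit-size histogram from a component table
#'
#' Bins are left-closed, right-open on area in um^2. Components smaller
#' than the first edge are counted into the first bin, so that counts
#' always sum to the component count and summed areas to the total
#' positive area.
#'
#' @param table a component table from \code{\link{findComponents}}
#' @param binEdges ascending bin edges (last may be Inf)
#' @return data.frame with bin_lo, bin_hi, label, count, summed_area_um2
#' @export
sizeHistogram <- function(table, binEdges = defaultBinEdges()) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("bin edges must be strictly ascending")
  nb <- length(binEdges) - 1L
  lab <- sprintf("[%g,%g)", binEdges[-length(binEdges)], binEdges[-1])
  idx <- findInterval(table$area_um2, binEdges)
  idx[idx == 0L] <- 1L                     # sub-first-edge areas: first bin
  idx[idx > nb] <- nb                      # area == last finite edge guard
  data.frame(
    bin_lo = binEdges[-length(binEdges)], bin_hi = binEdges[-1],
    label = lab,
    count = vapply(seq_len(nb), function(b) sum(idx == b), integer(1)),
    summed_area_um2 = vapply(seq_len(nb),
                             function(b) sum(table$area_um2[idx == b]),
                             numeric(1)))
}

# dominant bin: arg-max count; ties resolved toward the larger-area bin
# (large dominant spots are the object of interest); NA when empty
.dominant_bin <- function(hist) {
  if (sum(hist$count) == 0L) return(NA_character_)
  best <- max(which(hist$count == max(hist$count)))
  hist$label[best]
}

#' Build the per-organ biodistribution report
#'
#' Aggregates per-slide density statistics into per-organ mean and sd
#' (sd = 0 for single slides) and pools component tables into per-organ
#' size histograms with a dominant-bin call. Organs present in the input
#' with zero usable slides are excluded with a warning.
#'
#' @param stats data.frame of rows from \code{\link{quantifyDensity}}
#' @param tables list of component tables (concatenated and matched to
#'   organs via slide_id)
#' @param binEdges histogram bin edges
#' @return a \code{\linkS4class{BiodistributionReport}}
#' @export
buildReport <- function(stats, tables, binEdges = defaultBinEdges()) {
  if (nrow(stats) == 0L) stop("no slide statistics supplied")
  comp <- if (length(tables)) do.call(rbind, tables) else
    findComponents(matrix(FALSE, 1, 1), 1)
  organs <- unique(stats$organ)
  keep <- organs[vapply(organs,
                        function(o) sum(stats$organ == o) >= 1L, logical(1))]
  dropped <- setdiff(organs, keep)
  if (length(dropped))
    warning("organs with zero slides excluded: ",
            paste(dropped, collapse = ", "))
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  organStats <- do.call(rbind, lapply(keep, function(o) {
    s <- stats[stats$organ == o, ]
    data.frame(organ = o, n_slides = nrow(s),
               mean_px_per_mm2 = mean(s$positive_px_per_mm2),
               sd_px_per_mm2 = sd0(s$positive_px_per_mm2),
               mean_percent_positive = mean(s$percent_positive),
               sd_percent_positive = sd0(s$percent_positive))
  }))
  hists <- lapply(keep, function(o) {
    sids <- stats$slide_id[stats$organ == o]
    sizeHistogram(comp[comp$slide_id %in% sids, , drop = FALSE], binEdges)
  })
  names(hists) <- keep
  dom <- vapply(hists, .dominant_bin, character(1))
  new("BiodistributionReport", organStats = organStats, histograms = hists,
      dominantBin = dom, slideStats = stats)
}
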