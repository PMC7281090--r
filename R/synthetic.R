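# Synthetic pseudo-histology with exact ground truth.
#
# The generator emulates the appearance that drives the real analysis --
# dark, high-optical-density silver-enhanced deposits on pale tissue
# scattered with red-pink nuclear counterstain -- while keeping the planted
# geometry exact: deposits are non-overlapping rasterized ellipses, the
# ground-truth mask is their union before any noise, and channel noise
# perturbs colour only, never geometry.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Construct a log-normal mixture over deposit areas
#'
#' @param weights component weights (positive, sum to 1)
#' @param medianArea per-component median area in um^2
#' @param sdLog per-component log-scale sd
#' @return a \code{\linkS4class{DepositMixture}}
#' @export
DepositMixture <- function(weights, medianArea, sdLog) {
  new("DepositMixture", weights = as.numeric(weights),
      medianArea = as.numeric(medianArea), sdLog = as.numeric(sdLog))
}

#' Default stain palette
#'
#' Rows: tissue background (pale pink), nuclear counterstain (red-pink,
#' red-dominant so the weak-label colour veto has something to veto), and
#' deposit (dark achromatic gray, luminance well below both backgrounds,
#' as silver enhancement renders gold deposits).
#'
#' @return 3 x 3 integer matrix with rownames background/counterstain/deposit
#' @export
defaultPalette <- function() {
  p <- rbind(background   = c(235L, 200L, 210L),
             counterstain = c(200L, 120L, 145L),
             deposit      = c(40L, 42L, 45L))
  colnames(p) <- c("R", "G", "B")
  p
}

#' Construct a SyntheticSpec
#'
#' @param dims H, W in pixels
#' @param mpp microns per pixel
#' @param depositDensity expected deposits per mm^2
#' @param mixture a \code{DepositMixture}
#' @param palette 3 x 3 RGB matrix (background, counterstain, deposit)
#' @param noiseSd additive Gaussian channel noise sd (8-bit units)
#' @param nucleiDensity expected counterstained nuclei per mm^2
#' @param seed RNG seed
#' @param fixedCount exact deposit count override (NA for a Poisson draw)
#' @return a \code{\linkS4class{SyntheticSpec}}
#' @export
syntheticSpec <- function(dims = c(512L, 512L), mpp = 0.25,
                          depositDensity = 100,
                          mixture = DepositMixture(c(0.6, 0.4), c(25, 1),
                                                   c(0.35, 0.4)),
                          palette = defaultPalette(), noiseSd = 8,
                          nucleiDensity = 1500, seed = 1L,
                          fixedCount = NA_integer_) {
  new("SyntheticSpec", dims = as.integer(dims), mpp = as.numeric(mpp),
      depositDensity = as.numeric(depositDensity), mixture = mixture,
      palette = palette, noiseSd = as.numeric(noiseSd),
      nucleiDensity = as.numeric(nucleiDensity), seed = as.integer(seed),
      fixedCount = as.integer(fixedCount))
}

# pixel set of a filled ellipse: centers (r + 0.5, c + 0.5) inside the
# ellipse of pixel area areaPx, eccentricity ecc, orientation theta
.ellipse_pixels <- function(r0, c0, areaPx, ecc, theta) {
  q <- sqrt(1 - ecc^2)
  a <- sqrt(areaPx / (pi * q))
  b <- a * q
  ext <- ceiling(a) + 1L
  rr <- seq(floor(r0 - ext), ceiling(r0 + ext))
  cc <- seq(floor(c0 - ext), ceiling(c0 + ext))
  g <- expand.grid(r = rr, c = cc)
  dy <- g$r + 0.5 - r0; dx <- g$c + 0.5 - c0
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  if (!any(inside))  # sub-pixel ellipse: occupy the pixel under the center
    return(cbind(r = floor(r0), c = floor(c0)))
  cbind(r = g$r[inside], c = g$c[inside])
}

.draw_area_um2 <- function(mixture) {
  comp <- sample.int(length(mixture@weights), 1L, prob = mixture@weights)
  area <- rlnorm(1L, meanlog = log(mixture@medianArea[comp]),
                 sdlog = mixture@sdLog[comp])
  list(comp = comp, area = area)
}

#' Render one synthetic section with exact ground truth
#'
#' Deposits are filled ellipses with areas drawn from the spec's mixture,
#' placed by rejection sampling so that no two deposits overlap or touch
#' (8-neighborhood separation of at least 1 px); the planted count is
#' Poisson(depositDensity x section area in mm^2) under the spec's seed,
#' or \code{fixedCount} when set. The ground-truth mask is exactly the
#' union of rendered deposit pixels before noise; identical seeds give
#' bit-identical output.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}
#' @param organLabel organ label attached to the image
#' @param slideId slide identifier
#' @param maxAttempts rejection-sampling retry budget per deposit
#' @return list with elements \code{image} (\code{CalibratedImage}) and
#'   \code{truth} (\code{\linkS4class{GroundTruth}})
#' @export
renderSection <- function(spec, organLabel = "unknown", slideId = "slide",
                          maxAttempts = 200L) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  .with_seed(spec@seed, {
    H <- spec@dims[1]; W <- spec@dims[2]
    areaMm2 <- H * W * spec@mpp^2 / 1e6
    ch <- array(0, c(H, W, 3L))
    for (k in 1:3) ch[, , k] <- spec@palette[1, k]

    # counterstained nuclei: red-pink ellipses, ~30 um^2 median
    nNuc <- rpois(1L, spec@nucleiDensity * areaMm2)
    if (nNuc > 0) for (i in seq_len(nNuc)) {
      r0 <- runif(1, 0, H); c0 <- runif(1, 0, W)
      aPx <- rlnorm(1, log(30), 0.3) / spec@mpp^2
      px <- .ellipse_pixels(r0, c0, aPx, runif(1, 0, 0.6), runif(1, 0, pi))
      keep <- px[, 1] >= 0 & px[, 1] < H & px[, 2] >= 0 & px[, 2] < W
      px <- px[keep, , drop = FALSE]
      jit <- runif(1, -12, 12)
      for (k in 1:3)
        ch[cbind(px[, 1] + 1L, px[, 2] + 1L, k)] <-
          min(max(spec@palette[2, k] + jit, 0), 255)
    }

    # deposits
    nDep <- if (!is.na(spec@fixedCount)) spec@fixedCount
            else rpois(1L, spec@depositDensity * areaMm2)
    occ <- matrix(FALSE, H, W)
    log_rows <- vector("list", nDep)
    if (nDep > 0) for (i in seq_len(nDep)) {
      d <- .draw_area_um2(spec@mixture)
      areaPx <- d$area / spec@mpp^2
      ecc <- runif(1, 0, 0.8); theta <- runif(1, 0, pi)
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        r0 <- runif(1, 0, H); c0 <- runif(1, 0, W)
        px <- .ellipse_pixels(r0, c0, areaPx, ecc, theta)
        if (any(px[, 1] < 0 | px[, 1] >= H | px[, 2] < 0 | px[, 2] >= W))
          next
        # 8-neighborhood separation: the pixel set dilated by 1 must be free
        rs <- rep(px[, 1], each = 9L) + rep(c(-1L, 0L, 1L), times = 3L)
        cs <- rep(px[, 2], each = 9L) + rep(rep(c(-1L, 0L, 1L), each = 3L),
                                            times = nrow(px))
        ok <- rs >= 0 & rs < H & cs >= 0 & cs < W
        if (any(occ[cbind(rs[ok] + 1L, cs[ok] + 1L)])) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop("rejection sampling failed after ", maxAttempts,
             " attempts; lower depositDensity")
      occ[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- TRUE
      shade <- runif(1, -15, 30)
      for (k in 1:3)
        ch[cbind(px[, 1] + 1L, px[, 2] + 1L, k)] <-
          min(max(spec@palette[3, k] + shade, 0), 255)
      log_rows[[i]] <- data.frame(
        slide_id = slideId, mixture_component = d$comp,
        pixel_count = nrow(px),
        area_um2 = nrow(px) * spec@mpp^2,
        centroid_row = mean(px[, 1] + 0.5), centroid_col = mean(px[, 2] + 0.5),
        bbox_rmin = min(px[, 1]), bbox_cmin = min(px[, 2]),
        bbox_rmax = max(px[, 1]), bbox_cmax = max(px[, 2]))
    }
    comp <- if (nDep > 0) do.call(rbind, log_rows) else
      data.frame(slide_id = character(), mixture_component = integer(),
                 pixel_count = integer(), area_um2 = numeric(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 bbox_rmin = integer(), bbox_cmin = integer(),
                 bbox_rmax = integer(), bbox_cmax = integer())
    # deterministic component ids ordered by bounding-box top-left, matching
    # the ordering contract of findComponents()
    if (nrow(comp) > 0) {
      comp <- comp[order(comp$bbox_rmin, comp$bbox_cmin), , drop = FALSE]
      rownames(comp) <- NULL
    }
    comp <- cbind(component_id = seq_len(nrow(comp)), comp)

    if (spec@noiseSd > 0)
      ch <- ch + rnorm(length(ch), 0, spec@noiseSd)
    ch <- round(pmin(pmax(ch, 0), 255))

    img <- CalibratedImage(ch, mpp = spec@mpp, organLabel = organLabel,
                           slideId = slideId)
    truth <- new("GroundTruth",
                 mask = BinaryMask(occ, provenance = "ground_truth"),
                 components = comp)
    list(image = img, truth = truth)
  })
}

#' Ranked organ presets for the synthetic cohort
#'
#' Densities follow the organ ranking of silver-positive signal reported
#' for antibody-targeted AuNPs -- tumor highest, then spleen, liver,
#' intestine, lung, kidney, and heart (muscle) at the detection floor --
#' with adjacent ratios spaced so the ranking is identifiable at
#' simulation scale. Size mixtures follow the reported pattern: large
#' (~25 um^2) spots dominant in tumor with a secondary ~1 um^2 class;
#' mid-size macrophage-scale deposits in liver/spleen; small ~1 um^2
#' deposits dominant in intestine, lung, kidney, heart.
#'
#' @param dims per-slide H, W in pixels
#' @param mpp microns per pixel (default 0.25, a 40x scan scale that
#'   resolves ~1 um^2 deposits)
#' @param noiseSd channel noise sd
#' @param nucleiDensity nuclei per mm^2
#' @return list of \code{\linkS4class{OrganPreset}} in ranked order
#' @export
organPresets <- function(dims = c(512L, 512L), mpp = 0.25, noiseSd = 8,
                         nucleiDensity = 1500) {
  mix_tumor <- DepositMixture(c(0.6, 0.4), c(25, 1), c(0.35, 0.4))
  mix_macro <- DepositMixture(c(0.45, 0.35, 0.2), c(8, 25, 1),
                              c(0.4, 0.35, 0.4))
  mix_small <- function(w1) DepositMixture(c(w1, 1 - w1), c(1, 8),
                                           c(0.4, 0.4))
  dens <- c(tumor = 1300, spleen = 260, liver = 180, intestine = 120,
            lung = 75, kidney = 35, heart = 10)
  mixes <- list(tumor = mix_tumor, spleen = mix_macro, liver = mix_macro,
                intestine = mix_small(0.65), lung = mix_small(0.65),
                kidney = mix_small(0.7), heart = mix_small(0.75))
  lapply(names(dens), function(org) {
    new("OrganPreset", name = org,
        spec = syntheticSpec(dims = dims, mpp = mpp,
                             depositDensity = dens[[org]],
                             mixture = mixes[[org]], noiseSd = noiseSd,
                             nucleiDensity = nucleiDensity, seed = 1L))
  })
}

#' Generate a synthetic slide cohort
#'
#' Renders \code{slidesPerOrgan} replicate sections per organ preset.
#' Each slide gets a distinct child seed derived deterministically from
#' the master seed, and a slide id encoding organ and replicate index;
#' the same master seed reproduces the cohort bit-exactly.
#'
#' @param presets list of \code{\linkS4class{OrganPreset}}
#' @param slidesPerOrgan replicate slides per organ (>= 1)
#' @param seed master seed
#' @return list of per-slide lists with elements \code{image} and
#'   \code{truth}
#' @export
makeCohort <- function(presets, slidesPerOrgan = 6L, seed = 1L) {
  if (length(presets) == 0L) stop("preset list must be non-empty")
  if (slidesPerOrgan < 1L) stop("slidesPerOrgan must be >= 1")
  n <- length(presets) * slidesPerOrgan
  childSeeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  out <- vector("list", n)
  i <- 0L
  for (p in presets) {
    stopifnot(is(p, "OrganPreset"))
    for (rep in seq_len(slidesPerOrgan)) {
      i <- i + 1L
      sp <- p@spec
      sp@seed <- childSeeds[i]
      sid <- sprintf("%s_%02d", p@name, rep)
      out[[i]] <- renderSection(sp, organLabel = p@name, slideId = sid)
    }
  }
  out
}
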