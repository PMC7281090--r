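test_that("makeFolds reproduces the 28/14 rotation arithmetic", {
  ids <- sprintf("s%02d", 1:42)
  fa <- makeFolds(ids, k = 3, seed = 1)
  for (r in 1:3) {
    rot <- rotationSlides(fa, r)
    expect_length(rot$train, 28)
    expect_length(rot$test, 14)
    expect_length(intersect(rot$train, rot$test), 0)
  }
})

test_that("folds partition the slide set for arbitrary (n, k, seed)", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:40, 1); k <- sample(2:min(n, 8), 1)
    ids <- sprintf("sl%03d", sample.int(500, n))
    fa <- makeFolds(ids, k, seed = sample.int(1e6, 1))
    tests <- lapply(seq_len(k), function(r) rotationSlides(fa, r)$test)
    # disjoint and exhaustive
    expect_setequal(unlist(tests), ids)
    expect_equal(sum(lengths(tests)), n)
    # near-equal sizes
    expect_lte(diff(range(lengths(tests))), 1)
    # no slide in its own rotation's training set
    for (r in seq_len(k))
      expect_length(intersect(tests[[r]], rotationSlides(fa, r)$train), 0)
  }
  # leave-one-slide-out limit
  fa4 <- makeFolds(c("a", "b", "c", "d"), k = 4, seed = 2)
  expect_equal(sort(lengths(lapply(1:4, function(r)
    rotationSlides(fa4, r)$test))), rep(1L, 4))
  # determinism
  expect_identical(foldOf(makeFolds(letters[1:9], 3, 5)),
                   foldOf(makeFolds(letters[1:9], 3, 5)))
  expect_error(makeFolds(letters[1:3], k = 4), "exceeds")
})

test_that("channel doubling rule gives the documented sequence", {
  expect_equal(channelSequence(modelSpec(4, 16)), c(16, 32, 64, 128, 256))
  expect_equal(channelSequence(modelSpec(2, 4)), c(4, 8, 16))
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("AuNPquant")
  ms <- modelSpec(2, 2)
  set.seed(5)
  wts <- ns$.unet_init(ms)
  x <- array(runif(16 * 16 * 3, -0.5, 0.5), c(16, 16, 3))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fw <- ns$.unet_forward(x, wts, ms)
  l0 <- ns$.bce_loss(fw$p, y)
  g <- ns$.unet_backward((fw$p - y) / 256, wts, ms, fw$cache)
  eps <- 1e-6
  probe <- function(get, set, gv) {
    w2 <- set(wts, get(wts) + eps)
    lp <- ns$.bce_loss(ns$.unet_forward(x, w2, ms, want_cache = FALSE)$p, y)
    fd <- (lp - l0) / eps
    expect_lt(abs(fd - gv) / max(1e-8, abs(fd) + abs(gv)), 1e-3)
  }
  for (l in 1:2) for (i in c(1L, 5L)) {
    probe(function(w) w$enc[[l]]$W[i],
          function(w, v) { w$enc[[l]]$W[i] <- v; w }, g$enc[[l]]$W[i])
    probe(function(w) w$dec[[l]]$W[i],
          function(w, v) { w$dec[[l]]$W[i] <- v; w }, g$dec[[l]]$W[i])
  }
  probe(function(w) w$bot$W[3], function(w, v) { w$bot$W[3] <- v; w },
        g$bot$W[3])
  probe(function(w) w$head$W[1], function(w, v) { w$head$W[1] <- v; w },
        g$head$W[1])
  probe(function(w) w$enc[[1]]$b[1],
        function(w, v) { w$enc[[1]]$b[1] <- v; w }, g$enc[[1]]$b[1])
})

test_that("training reduces loss on trivially separable patches", {
  set.seed(8)
  mkp <- function() {
    p <- array(0L, c(64, 64, 3))
    p[, , 1] <- 235L; p[, , 2] <- 200L; p[, , 3] <- 210L
    m <- matrix(FALSE, 64, 64)
    r <- sample(5:50, 1); c <- sample(5:50, 1)
    m[r:(r + 8), c:(c + 8)] <- TRUE
    for (k in 1:3) { ch <- p[, , k]; ch[m] <- 40L; p[, , k] <- ch }
    list(p = p, m = m)
  }
  tp <- replicate(50, mkp(), simplify = FALSE)
  seg <- trainSegmenter(lapply(tp, `[[`, "p"), lapply(tp, `[[`, "m"),
                        modelSpec(2, 4),
                        trainingSpec(epochs = 10, batchSize = 2,
                                     learningRate = 1e-2,
                                     targetTrainPatches = 50,
                                     trainPatchEdge = 64, seed = 3),
                        trainSlides = "trainslide")
  ll <- lossLog(seg)
  expect_length(ll, 10)
  expect_lt(tail(ll, 1), ll[1])
  # training is reproducible under the seed
  seg2 <- trainSegmenter(lapply(tp, `[[`, "p"), lapply(tp, `[[`, "m"),
                         modelSpec(2, 4),
                         trainingSpec(epochs = 2, batchSize = 2,
                                      learningRate = 1e-2,
                                      targetTrainPatches = 50,
                                      trainPatchEdge = 64, seed = 3))
  seg3 <- trainSegmenter(lapply(tp, `[[`, "p"), lapply(tp, `[[`, "m"),
                         modelSpec(2, 4),
                         trainingSpec(epochs = 2, batchSize = 2,
                                      learningRate = 1e-2,
                                      targetTrainPatches = 50,
                                      trainPatchEdge = 64, seed = 3))
  expect_equal(lossLog(seg2), lossLog(seg3))

  # inference determinism and the fold-leak guard
  te <- mkp()
  p1 <- segmentPatch(te$p, seg, slideId = "other")
  p2 <- segmentPatch(te$p, seg, slideId = "other")
  expect_identical(probs(p1), probs(p2))
  expect_true(all(probs(p1) >= 0 & probs(p1) <= 1))
  expect_error(segmentPatch(te$p, seg, slideId = "trainslide"), "fold leak")
  expect_s4_class(segmentPatch(te$p, seg, slideId = "trainslide",
                               allowTrainSlide = TRUE), "ProbabilityMask")

  expect_error(trainSegmenter(list(), list(), modelSpec(2, 4),
                              trainingSpec()), "empty")
  expect_error(trainSegmenter(list(tp[[1]]$p), list(matrix(FALSE, 3, 3)),
                              modelSpec(2, 4), trainingSpec()),
               "shape mismatch")
})

test_that("stitching is a left inverse of tiling on random masks", {
  set.seed(13)
  for (i in 1:50) {
    H <- sample(60:260, 1); W <- sample(60:260, 1)
    P <- sample(c(32, 48, 64), 1); ov <- sample(4:(P / 2), 1)
    M <- matrix(runif(H * W) < 0.2, H, W)
    roi <- rasterROI(matrix(TRUE, H, W))
    g <- planTiles(c(H, W), roi, tilingSpec(P, ov))
    crops <- lapply(seq_len(nrow(anchors(g))), function(j)
      extractMaskPatch(M, g, j, pad = FALSE))
    st <- stitchMasks(g, crops)
    expect_identical(maskMatrix(st), M)
  }
})

test_that("single-patch stitching binarizes and crops to image dims", {
  roi <- rasterROI(matrix(TRUE, 40, 40))
  g <- planTiles(c(40, 40), roi, tilingSpec(64, 8))
  pr <- matrix(runif(64 * 64), 64, 64)
  st <- stitchMasks(g, list(new("ProbabilityMask", probs = pr,
                                threshold = 0.5)), threshold = 0.5)
  expect_identical(maskMatrix(st), pr[1:40, 1:40] >= 0.5)
  expect_identical(provenance(st), "predicted")
  expect_error(stitchMasks(g, list()), "missing patch masks")
})

test_that("overlap-zone deposits are counted exactly once after stitching", {
  # deposits placed inside overlap margins; component counts from stitched
  # crops equal those from the unsplit mask
  set.seed(19)
  for (i in 1:10) {
    M <- matrix(FALSE, 120, 120)
    g <- planTiles(c(120, 120), rasterROI(matrix(TRUE, 120, 120)),
                   tilingSpec(64, 16))
    # a blob centred on each internal patch boundary region
    M[44:52, 44:52] <- TRUE
    M[sample(5:110, 1) + 0:3, sample(5:110, 1) + 0:3] <- TRUE
    crops <- lapply(seq_len(nrow(anchors(g))), function(j)
      extractMaskPatch(M, g, j))
    st <- stitchMasks(g, crops)
    expect_identical(maskMatrix(st), M)
    expect_equal(nrow(findComponents(maskMatrix(st), 1)),
                 nrow(findComponents(M, 1)))
  }
})
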