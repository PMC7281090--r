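full_roi <- function(H, W) rasterROI(matrix(TRUE, H, W))

test_that("an image equal to one patch yields a single anchor", {
  g <- planTiles(c(1000, 1000), full_roi(1000, 1000), tilingSpec())
  expect_equal(nrow(anchors(g)), 1)
  expect_equal(unname(anchors(g)[1, ]), c(0, 0))
})

test_that("stride and end-clamp produce the expected anchor lattice", {
  g <- planTiles(c(2500, 2500), full_roi(2500, 2500), tilingSpec(1000, 100))
  expect_equal(sort(unique(anchors(g)[, 1])), c(0, 900, 1500))
  expect_equal(sort(unique(anchors(g)[, 2])), c(0, 900, 1500))
  expect_equal(nrow(anchors(g)), 9)
  # brute-force coverage oracle: every pixel covered at least once
  cov <- matrix(0L, 2500, 2500)
  for (i in seq_len(nrow(anchors(g)))) {
    a <- anchors(g)[i, ]
    cov[a[1] + 1:1000, a[2] + 1:1000] <- cov[a[1] + 1:1000, a[2] + 1:1000] + 1L
  }
  expect_true(all(cov >= 1L))
})

test_that("small images are padded to one patch and the pad is discarded on stitch", {
  spec <- tilingSpec(1000, 100, padValue = c(250L, 250L, 250L))
  g <- planTiles(c(500, 800), full_roi(500, 800), spec)
  expect_equal(nrow(anchors(g)), 1)
  expect_equal(g@paddedDims, c(1000L, 1000L))
  set.seed(2)
  px <- array(sample(0:200, 500 * 800 * 3, TRUE), c(500, 800, 3))
  img <- CalibratedImage(px, 1, slideId = "s")
  patch <- extractPatch(img, g, 1)
  expect_equal(dim(patch), c(1000L, 1000L, 3L))
  expect_identical(patch[1:500, 1:800, ], px)
  expect_true(all(patch[501:1000, , ] == 250L))
  # stitching a mask patch crops all pad pixels away
  m <- matrix(TRUE, 1000, 1000)
  st <- stitchMasks(g, list(m))
  expect_equal(dim(maskMatrix(st)), c(500L, 800L))
  expect_true(all(maskMatrix(st)))
})

test_that("extractPatch slices exactly and duplicates clamped overlap", {
  set.seed(3)
  px <- array(sample(0:255, 1200 * 1200 * 3, TRUE), c(1200, 1200, 3))
  img <- CalibratedImage(px, 1, slideId = "s")
  g <- planTiles(c(1200, 1200), full_roi(1200, 1200), tilingSpec(1000, 100))
  expect_identical(extractPatch(img, g, 1)[1:1000, 1:1000, ],
                   px[1:1000, 1:1000, ])
  # clamped final anchor: its leading columns duplicate the neighbour patch
  ac <- sort(unique(anchors(g)[, 2]))
  expect_equal(ac, c(0, 200))
  p1 <- extractPatch(img, g, 1); p2 <- extractPatch(img, g, 2)
  expect_identical(p1[, 201:1000, ], p2[, 1:800, ])
  expect_error(extractPatch(img, g, 99), "out of range")
})

test_that("every ROI pixel is covered by at least one patch (random draws)", {
  set.seed(7)
  for (i in 1:200) {
    H <- sample(40:200, 1); W <- sample(40:200, 1)
    P <- sample(16:80, 1); ov <- sample(seq_len(P - 1), 1)
    roi <- matrix(FALSE, H, W)
    r0 <- sample.int(H, 1); c0 <- sample.int(W, 1)
    r1 <- sample(r0:H, 1); c1 <- sample(c0:W, 1)
    roi[r0:r1, c0:c1] <- TRUE
    g <- planTiles(c(H, W), rasterROI(roi), tilingSpec(P, ov))
    cov <- matrix(FALSE, max(H, P), max(W, P))
    for (j in seq_len(nrow(anchors(g)))) {
      a <- anchors(g)[j, ]
      cov[a[1] + seq_len(P), a[2] + seq_len(P)] <- TRUE
    }
    expect_true(all(cov[1:H, 1:W][roi]))
  }
})

test_that("tiling rejects invalid input", {
  expect_error(planTiles(c(100, 100), rasterROI(matrix(FALSE, 100, 100)),
                         tilingSpec(50, 10)), "empty")
  expect_error(tilingSpec(100, 0), "overlap")
  expect_error(tilingSpec(100, 100), "overlap")
})
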