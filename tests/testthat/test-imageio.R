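test_that("loadImage reads 8-bit images and attaches calibration", {
  d <- withr::local_tempdir()
  # white 2x2 PNG
  p <- file.path(d, "w.png")
  png::writePNG(array(1, c(2, 2, 3)), p)
  img <- loadImage(p, mpp = 1.0, organLabel = "tumor")
  expect_s4_class(img, "CalibratedImage")
  expect_true(all(pixels(img) == 255L))
  expect_identical(imageDims(img), c(2L, 2L))
  expect_equal(mpp(img), 1.0)

  # grayscale is replicated to three channels
  g <- file.path(d, "g.png")
  png::writePNG(matrix(0.5, 3, 4), g)
  gi <- loadImage(g, mpp = 0.5)
  expect_equal(dim(pixels(gi)), c(3L, 4L, 3L))
  expect_true(all(pixels(gi)[, , 1] == pixels(gi)[, , 3]))

  # 8-bit TIFF reads identically to its source values
  tf <- file.path(d, "t.tif")
  arr <- array(round(runif(2 * 3 * 3) * 255) / 255, c(2, 3, 3))
  tiff::writeTIFF(arr, tf, bits.per.sample = 8L)
  ti <- loadImage(tf, mpp = 2)
  expect_equal(dim(pixels(ti)), c(2L, 3L, 3L))
})

test_that("loadImage rejects invalid inputs with informative errors", {
  d <- withr::local_tempdir()
  expect_error(loadImage(file.path(d, "nope.png"), 1), "cannot read")
  p <- file.path(d, "w.png"); png::writePNG(array(1, c(2, 2, 3)), p)
  expect_error(loadImage(p, mpp = 0), "mpp")
  expect_error(loadImage(p, mpp = -1), "mpp")
  # 16-bit TIFF: unsupported bit depth
  t16 <- file.path(d, "t16.tif")
  tiff::writeTIFF(array(0.5, c(2, 2, 3)), t16, bits.per.sample = 16L)
  expect_error(loadImage(t16, 1), "bit depth")
  # RGBA PNG: channel count named in the error
  r4 <- file.path(d, "r4.png")
  png::writePNG(array(0.5, c(2, 2, 4)), r4)
  expect_error(loadImage(r4, 1), "4 channels")
})

test_that("mask save/load round trips are bit-exact", {
  d <- withr::local_tempdir()
  set.seed(11)
  for (i in 1:3) {
    m <- matrix(runif(64 * 64) < 0.3, 64, 64)
    path <- file.path(d, sprintf("m%d.png", i))
    saveMask(BinaryMask(m, "ground_truth"), path)
    back <- loadMask(path, "ground_truth")
    expect_identical(maskMatrix(back), m)
  }
  # all-false and all-true encode as 0 and 255
  saveMask(BinaryMask(matrix(FALSE, 4, 4)), file.path(d, "f.png"))
  expect_true(all(png::readPNG(file.path(d, "f.png")) == 0))
  saveMask(BinaryMask(matrix(TRUE, 4, 4)), file.path(d, "t.png"))
  expect_true(all(png::readPNG(file.path(d, "t.png")) == 1))
  expect_error(saveMask(BinaryMask(matrix(TRUE, 2, 2)),
                        file.path(d, "no/such/dir/x.png")), "directory")
})

test_that("image save/load round trips are bit-exact", {
  d <- withr::local_tempdir()
  set.seed(4)
  px <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  img <- CalibratedImage(px, mpp = 0.25, slideId = "s1")
  p <- file.path(d, "img.png")
  saveImage(img, p)
  back <- loadImage(p, mpp = 0.25, slideId = "s1")
  expect_identical(pixels(back), pixels(img))
})

test_that("rasterizeROI fills polygons by the pixel-center even-odd rule", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  roi <- rasterizeROI(sq, c(20, 20))
  expect_equal(sum(maskMatrix(roi)), 100)
  expect_true(all(which(maskMatrix(roi), arr.ind = TRUE) <= 10))

  # polygon covering the full image bounds
  full <- rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20))
  expect_true(all(maskMatrix(rasterizeROI(full, c(20, 20)))))

  expect_error(rasterizeROI(rbind(c(0, 0), c(5, 5)), c(10, 10)), "3 vertices")
  expect_error(rasterizeROI(rbind(c(-1, 0), c(5, 0), c(5, 5)), c(10, 10)),
               "within")
})

test_that("rasterizeROI agrees with the point-in-polygon oracle", {
  set.seed(21)
  for (i in 1:100) {
    poly <- random_convex_polygon(64, 64)
    got <- maskMatrix(rasterizeROI(poly, c(64, 64)))
    want <- oracle_rasterize(poly, 64, 64)
    expect_identical(got, want)
  }
})

test_that("ROI JSON round trip preserves the rasterization", {
  d <- withr::local_tempdir()
  poly <- rbind(c(2, 3), c(40, 5), c(50, 50), c(5, 45))
  p <- file.path(d, "roi.json")
  writeROI(poly, "s1", p)
  roi <- readROI(p, c(64, 64))
  expect_identical(maskMatrix(roi), maskMatrix(rasterizeROI(poly, c(64, 64))))
})
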