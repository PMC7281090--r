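test_that("weakLabel handles the canonical constructed cases", {
  # uniform white: nothing below the cut
  white <- array(255L, c(32, 32, 3))
  expect_equal(sum(maskMatrix(weakLabel(white))), 0)

  # pink background with one 11x11 achromatic dark square: the mask is
  # exactly the square (3x3 opening/closing leave an 11x11 square intact)
  p <- array(0L, c(64, 64, 3))
  p[, , 1] <- 230L; p[, , 2] <- 150L; p[, , 3] <- 160L
  p[20:30, 40:50, ] <- 30L
  got <- maskMatrix(weakLabel(p))
  want <- matrix(FALSE, 64, 64); want[20:30, 40:50] <- TRUE
  expect_identical(got, want)
  expect_identical(got, oracle_weak_label(p))

  # a single isolated dark pixel is removed by the 3x3 opening
  q <- array(0L, c(32, 32, 3))
  q[, , 1] <- 230L; q[, , 2] <- 150L; q[, , 3] <- 160L
  q[16, 16, ] <- 20L
  expect_equal(sum(maskMatrix(weakLabel(q))), 0)

  # dark but red-dominant pixels are vetoed as counterstain
  r <- array(0L, c(32, 32, 3))
  r[, , 1] <- 230L; r[, , 2] <- 150L; r[, , 3] <- 160L
  r[10:20, 10:20, 1] <- 120L; r[10:20, 10:20, 2] <- 60L
  r[10:20, 10:20, 3] <- 80L                       # luminance ~87, R/G = 2
  expect_equal(sum(maskMatrix(weakLabel(r))), 0)

  expect_error(weakLabel(array(0.5, c(8, 8, 3))), "8-bit")
  expect_error(weakLabel(matrix(0L, 8, 8)), "H x W x 3")
})

test_that("weakLabel equals the per-pixel + morphology oracle on random patches", {
  set.seed(33)
  for (i in 1:50) {
    p <- random_test_patch(64, 64, nblobs = sample(1:4, 1))
    expect_identical(maskMatrix(weakLabel(p)), oracle_weak_label(p))
  }
})

test_that("maskIoU follows its definition", {
  a <- matrix(FALSE, 10, 10); b <- matrix(FALSE, 10, 10)
  expect_equal(maskIoU(a, b), 1)           # both empty
  a[1:5, ] <- TRUE
  expect_equal(maskIoU(a, a), 1)
  full <- matrix(TRUE, 10, 10)
  expect_equal(maskIoU(a, full), 0.5)      # left half vs full
  c <- matrix(FALSE, 10, 10); c[6:10, ] <- TRUE
  expect_equal(maskIoU(a, c), 0)           # disjoint non-empty
  expect_error(maskIoU(a, matrix(TRUE, 5, 5)), "shapes differ")
})

test_that("consensus selection picks the majority-agreeing mask", {
  A <- matrix(FALSE, 16, 16); A[1:4, 1:4] <- TRUE
  B <- matrix(FALSE, 16, 16); B[10:14, 10:14] <- TRUE   # disjoint from A
  C <- A                                                 # agrees with A
  sel <- selectMask(list(B, A, C))
  expect_identical(maskMatrix(sel$mask), A)
  expect_true(sel$index %in% c(2L, 3L))

  # identical candidates: any one, output equals them all
  sel2 <- selectMask(list(A, A, A))
  expect_identical(maskMatrix(sel2$mask), A)
  expect_equal(sel2$score, 1)

  # explicit correction overrides verbatim
  corr <- matrix(TRUE, 16, 16)
  sel3 <- selectMask(list(A, B), correction = corr)
  expect_identical(maskMatrix(sel3$mask), corr)
  expect_true(is.na(sel3$index))

  expect_error(selectMask(list()), "non-empty")
})

test_that("weak labels recover synthetic ground truth reasonably (IoU >= 0.7)", {
  # regression floor for the bootstrap's usefulness at default palette and
  # moderate noise
  for (sd in c(41, 42)) {
    sp <- syntheticSpec(dims = c(512, 512), depositDensity = 1300,
                        noiseSd = 8, seed = sd)
    s <- renderSection(sp)
    wl <- weakLabel(pixels(s$image))
    expect_gte(maskIoU(maskMatrix(wl), maskMatrix(s$truth@mask)), 0.7)
  }
})
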