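# Calibrated containers, TIFF round trips, and preprocessing operators.

test_that("TIFF round trips preserve pixels and calibration handling", {
  img <- image2d(matrix(runif(64 * 64), 64, 64), pixelSizeUm = 0.16)
  p <- withr::local_tempfile(fileext = ".tif")
  writeMicrograph(img, p)
  back <- readMicrograph(p, pixelSizeUm = 0.16)
  expect_s4_class(back, "Image2D")
  expect_equal(pixels(back), pixels(img), tolerance = 1e-4)
  expect_equal(pixelSizeUm(back), 0.16)

  v <- videoStack(array(runif(32 * 32 * 50), c(32, 32, 50)), 1.5, 0.16)
  pv <- withr::local_tempfile(fileext = ".tif")
  writeMicrograph(v, pv)
  vb <- readMicrograph(pv, pixelSizeUm = 0.16, frameIntervalMs = 1.5)
  expect_s4_class(vb, "VideoStack")
  expect_equal(nFrames(vb), 50L)
  expect_equal(frameIntervalMs(vb), 1.5)
  expect_equal(pixels(vb), pixels(v), tolerance = 1e-4)

  expect_error(readMicrograph("no-such-file.tif"), "exist")
  expect_error(readMicrograph(pv, pixelSizeUm = -1), "pixelSizeUm")
  expect_error(readMicrograph(pv, pixelSizeUm = 0.16), "frameIntervalMs")
})

test_that("container validity enforces the documented invariants", {
  expect_error(image2d(matrix(1, 8, 8), 0.1), "16")
  expect_error(image2d(matrix(-1, 32, 32), 0.1), ">= 0")
  expect_error(image2d(matrix(1, 32, 32), -0.1), "positive")
  expect_error(videoStack(array(1, c(32, 32, 2)), 1, 0.1), "3 frames")
})

test_that("Otsu threshold equals the exhaustive brute-force search", {
  set.seed(11)
  for (i in 1:50) {
    v <- sample.int(256, 400, replace = TRUE) - 1L
    if (length(unique(v)) < 2L) next
    ours <- otsuThreshold(matrix(v, 20, 20))
    oracle <- bruteForceOtsuMask(as.numeric(v))
    expect_identical(as.vector(ours$mask), oracle$mask)
  }
  # forced split: two-value image
  m <- matrix(c(rep(50, 60), rep(200, 40)), 10, 10)
  ot <- otsuThreshold(m)
  expect_true(ot$threshold >= 50 && ot$threshold < 200)
  expect_identical(sum(ot$mask), 40L)
  expect_error(otsuThreshold(image2d(matrix(7, 20, 20), 1)), "single")
})

test_that("Otsu mask is monotone in the threshold", {
  set.seed(2)
  img <- matrix(runif(400, 0, 100), 20, 20)
  ot <- otsuThreshold(img)
  higher <- img > (ot$threshold + 10)
  expect_true(all(ot$mask[higher]))
})

test_that("background subtraction removes flat background, keeps peaks", {
  flat <- image2d(matrix(100, 64, 64), 0.2)
  expect_equal(max(pixels(subtractBackground(flat, 15))), 0)

  # single bright dot on a pedestal survives nearly intact
  px <- matrix(50, 64, 64)
  px[30:34, 30:34] <- 150
  out <- subtractBackground(image2d(px, 0.2), 15)
  expect_gt(pixels(out)[32, 32], 0.95 * 100)
  expect_lt(max(abs(pixels(out)[1:10, 1:10])), 1e-8)

  # never increases any pixel
  set.seed(5)
  rnd <- image2d(matrix(runif(4096, 0, 200), 64, 64), 0.2)
  expect_true(all(pixels(subtractBackground(rnd, 10)) <= pixels(rnd) + 1e-9))

  expect_error(subtractBackground(rnd, 64), "smaller")
  expect_error(subtractBackground(rnd, 0), ">= 1")
})

test_that("background subtraction is near-idempotent", {
  set.seed(6)
  px <- matrix(runif(4096, 0, 50), 64, 64) +
    outer(seq(0, 40, length.out = 64), rep(1, 64))
  once <- subtractBackground(image2d(px, 0.2), 15)
  twice <- subtractBackground(once, 15)
  expect_lt(mean(abs(pixels(twice) - pixels(once))), 0.05 * mean(pixels(once)))
})

test_that("contrast enhancement clips the stated pixel fraction", {
  ramp <- image2d(matrix(1:1000, 20, 50), 1)
  out <- pixels(enhanceContrast(ramp, 0.8))
  expect_identical(sum(out == 0), 4L)        # lowest 4 pixels clipped
  expect_identical(sum(out == max(out)), 4L) # highest 4 pixels clipped

  # saturated 0: pure min-max stretch
  img <- image2d(matrix(seq(40, 240, length.out = 400), 20, 20), 1)
  st <- pixels(enhanceContrast(img, 0))
  expect_equal(min(st), 0)
  expect_equal(max(st), 240)

  # monotone: pixel ranks preserved
  set.seed(7)
  r <- image2d(matrix(runif(400, 5, 50), 20, 20), 1)
  o <- pixels(enhanceContrast(r, 2))
  ord <- order(pixels(r))
  expect_true(all(diff(o[ord]) >= -1e-12))

  # constant image unchanged
  const <- image2d(matrix(3, 20, 20), 1)
  expect_equal(pixels(enhanceContrast(const, 0.8)), pixels(const))
  expect_error(enhanceContrast(r, 100), "100")
})

test_that("Mexican hat responds to ridges and kills constants", {
  const <- image2d(matrix(42, 32, 32), 1)
  expect_lt(max(pixels(mexicanHat(const, 3))), 1e-8)

  # horizontal ridge: response maximal on the centreline
  px <- matrix(0, 33, 33)
  px[16:17, ] <- 100
  out <- pixels(mexicanHat(image2d(px, 1), 3))
  inner <- 5:29
  expect_true(all(apply(out[, inner], 2, which.max) %in% 16:17))
})

test_that("median filter over a disk rejects impulses", {
  px <- matrix(10, 32, 32)
  px[16, 16] <- 200
  out <- pixels(medianDisk(image2d(px, 1), 1))
  expect_equal(out[16, 16], 10)
  const <- matrix(9, 32, 32)
  expect_equal(pixels(medianDisk(image2d(const, 1), 1)), const)
  # radius 2 generic path
  px2 <- matrix(5, 20, 20); px2[10, 10] <- 100
  expect_equal(pixels(medianDisk(image2d(px2, 1), 2))[10, 10], 5)
})

test_that("rotation finds and levels the cell long axis", {
  tilted <- ellipseImage(angleDeg = 30)
  rt <- rotateToHorizontal(tilted)
  expect_equal(principalAxisDeg(rt$geometry), 30, tolerance = 1)
  # post-rotation footprint is horizontal
  postAngle <- dyadscape:::maskOrientationDeg(footprint(rt$geometry))
  expect_lt(abs(postAngle), 1)

  flat <- ellipseImage(angleDeg = 0)
  rt0 <- rotateToHorizontal(flat)
  expect_lt(abs(principalAxisDeg(rt0$geometry)), 0.5)
  expect_equal(dim(pixels(rt0$image)), dim(pixels(flat)))

  expect_error(rotateToHorizontal(image2d(matrix(5, 32, 32), 1)), "single")
})

test_that("footprint is recovered after rotating back (IoU > 0.95)", {
  ref <- rotateToHorizontal(ellipseImage(angleDeg = 0))
  tilted <- rotateToHorizontal(ellipseImage(angleDeg = 25))
  a <- footprint(ref$geometry); b <- footprint(tilted$geometry)
  # compare centroid-centred pixel sets (canvas sizes differ after rotation)
  centred <- function(m) {
    p <- which(m, arr.ind = TRUE)
    p <- sweep(p, 2, round(colMeans(p)))
    paste(p[, 1], p[, 2])
  }
  ka <- centred(a); kb <- centred(b)
  iou <- length(intersect(ka, kb)) / length(union(ka, kb))
  expect_gt(iou, 0.95)
})

test_that("interior ROI sits strictly inside the footprint", {
  rt <- rotateToHorizontal(ellipseImage(angleDeg = 12), roiMarginUm = 1)
  expect_true(all(footprint(rt$geometry)[interiorRoi(rt$geometry)]))
  expect_lt(sum(interiorRoi(rt$geometry)), sum(footprint(rt$geometry)))
})
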