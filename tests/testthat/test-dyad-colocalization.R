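# Manders overlap, orientation territories, densities and distance maps.

# small helper: puncta image with discs of radius r at given centres
discImage <- function(h, w, centres, r = 2, amp = 100, bg = 0, ps = 0.1) {
  px <- matrix(bg, h, w)
  for (k in seq_len(nrow(centres))) {
    for (dy in -r:r) for (dx in -r:r) {
      if (dy * dy + dx * dx <= r * r) {
        i <- centres[k, 1] + dy; j <- centres[k, 2] + dx
        if (i >= 1 && i <= h && j >= 1 && j <= w) px[i, j] <- amp
      }
    }
  }
  image2d(px, ps)
}

test_that("Manders coefficients match the direct-summation oracle", {
  set.seed(31)
  r <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  l <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  # embed the fixed 8x8 block in a minimal valid image
  R <- matrix(0, 16, 16); L <- matrix(0, 16, 16)
  R[1:8, 1:8] <- r; L[1:8, 1:8] <- l
  roi <- matrix(FALSE, 16, 16); roi[1:8, 1:8] <- TRUE
  pair <- channelPair(image2d(R, 0.1), image2d(L, 0.1), roi)
  tR <- 97; tL <- 123                         # hand-set thresholds
  res <- mandersMCC(pair, thresholds = c(tR, tL))
  mR <- r > tR; mL <- l > tL
  expect_equal(m1(res), sum(l[mL & mR]) / sum(l[mL]), tolerance = 1e-12)
  expect_equal(m2(res), sum(r[mR & mL]) / sum(r[mR]), tolerance = 1e-12)
  expect_identical(res@method, "manual")
})

test_that("identical channels give perfect overlap, disjoint give none", {
  set.seed(32)
  centres <- cbind(sample(10:50, 8), sample(10:50, 8))
  img <- discImage(64, 64, centres)
  roi <- matrix(TRUE, 64, 64)
  same <- channelPair(img, img, roi)
  res <- mandersMCC(same)
  expect_equal(m1(res), 1)
  expect_equal(m2(res), 1)

  a <- discImage(64, 64, cbind(c(15, 20), c(15, 40)))
  b <- discImage(64, 64, cbind(c(45, 50), c(20, 45)))
  res2 <- mandersMCC(channelPair(a, b, roi))
  expect_equal(m1(res2), 0)
  expect_equal(m2(res2), 0)

  blank <- image2d(matrix(0, 64, 64), 0.1)
  expect_error(mandersMCC(channelPair(blank, img, roi)), "zero")
})

test_that("Manders result is invariant to channel scaling", {
  g <- generateDyadPair(dyadSpec(seed = 33))
  prep <- preprocessPair(g$pair)
  base <- mandersMCC(prep)
  scaled <- channelPair(prep@ryr,
                        image2d(pixels(prep@ltcc) * 4.2, pixelSizeUm(prep@ltcc)),
                        prep@cellRoi)
  res <- mandersMCC(scaled)
  expect_equal(m1(res), m1(base), tolerance = 1e-9)
  expect_equal(m2(res), m2(base), tolerance = 1e-9)
})

test_that("preprocessing clears extracellular signal and is idempotent", {
  g <- generateDyadPair(dyadSpec(seed = 34))
  prep <- preprocessPair(g$pair)
  expect_true(all(pixels(prep@ryr)[!prep@cellRoi] == 0))
  expect_true(all(pixels(prep@ltcc)[!prep@cellRoi] == 0))
  twice <- preprocessPair(prep)
  expect_lt(mean(abs(pixels(twice@ryr) - pixels(prep@ryr))),
            0.05 * mean(pixels(prep@ryr)))
})

test_that("orientation masks follow the stripe direction", {
  # vertical stripes: everything transverse
  px <- matrix(5, 120, 120)
  for (cc in seq(20, 100, by = 24)) px[15:105, cc + (-1:0)] <- 150
  roi <- matrix(TRUE, 120, 120)
  img <- image2d(px, 0.05)
  masks <- orientationMasks(img, roi)
  stripePx <- px > 100
  expect_gt(sum(masks$transverse & stripePx) / sum(stripePx), 0.9)
  # transposed image: stripes become longitudinal structures, so the
  # transverse territory collapses and the complement takes over
  masksT <- orientationMasks(image2d(t(px), 0.05), roi)
  expect_lt(sum(masksT$transverse), 0.1 * sum(masks$transverse))
  expect_gt(sum(masksT$longitudinal), 0.8 * sum(roi))
})

test_that("orientation masks cover the true Z-lines of generated pairs", {
  g <- generateDyadPair(dyadSpec(seed = 35))
  prep <- preprocessPair(g$pair)
  masks <- orientationMasks(prep@ryr, prep@cellRoi)
  cover <- sum(masks$transverse & g$truth$zlineMask) / sum(g$truth$zlineMask)
  expect_gt(cover, 0.8)
})

test_that("orientation MCC with a full-ROI mask reduces to the whole-cell MCC", {
  g <- generateDyadPair(dyadSpec(seed = 36))
  prep <- preprocessPair(g$pair)
  whole <- mandersMCC(prep)
  full <- list(transverse = prep@cellRoi, longitudinal = prep@cellRoi)
  red <- orientationMCC(prep, full, "transverse",
                        thresholds = c(whole@tRyr, whole@tLtcc))
  expect_equal(m1(red), m1(whole), tolerance = 1e-12)
  empty <- list(transverse = prep@cellRoi & FALSE,
                longitudinal = prep@cellRoi & FALSE)
  expect_warning(res <- orientationMCC(prep, empty, "transverse",
                                       thresholds = c(1, 1)), "empty")
  expect_null(res)
})

test_that("per-orientation colocalized fractions are recovered", {
  seeds <- 41:44
  m1t <- m1l <- numeric(0)
  for (s in seeds) {
    g <- generateDyadPair(dyadSpec(colocFractionTransverse = 0.9,
                                   colocFractionLongitudinal = 0.3, seed = s))
    dm <- dyadMetrics(g$pair)
    expect_gt(dm@m1Transverse, dm@m1Longitudinal)
    m1t <- c(m1t, dm@m1Transverse); m1l <- c(m1l, dm@m1Longitudinal)
  }
  expect_lt(abs(mean(m1t) - 0.9), 0.1)
  expect_lt(abs(mean(m1l) - 0.3), 0.1)
})

test_that("protein density counts above-threshold area, nuclei excluded", {
  roi <- matrix(TRUE, 64, 64)
  blank <- image2d(matrix(0, 64, 64), 0.1)
  expect_equal(proteinDensity(blank, roi), 0)
  fullImg <- image2d(matrix(7, 64, 64), 0.1)
  expect_equal(proteinDensity(fullImg, roi), 100)
  # nucleus exclusion: signal only in the nucleus -> zero density outside
  px <- matrix(0, 64, 64); px[20:30, 20:30] <- 50
  nuc <- matrix(FALSE, 64, 64); nuc[20:30, 20:30] <- TRUE
  expect_equal(proteinDensity(image2d(px, 0.1), roi, nuc, threshold = 10), 0)
  expect_error(proteinDensity(blank, nuc & FALSE), "empty")
})

test_that("puncta covering a known ROI fraction read out within 2 points", {
  set.seed(37)
  h <- w <- 200
  centres <- cbind(sample(10:190, 22), sample(10:190, 22))
  img <- discImage(h, w, centres, r = 4, amp = 120, bg = 0, ps = 0.05)
  # add mild noise so the threshold is not degenerate
  noisy <- image2d(pmax(pixels(img) + rnorm(h * w, 4, 2), 0), 0.05)
  roi <- matrix(TRUE, h, w)
  truthMask <- pixels(img) > 50
  truthPct <- 100 * sum(truthMask) / sum(roi)
  est <- proteinDensity(noisy, roi)
  expect_lt(abs(est - truthPct), 2)
})

test_that("dyadic density is the exact product of density and M1", {
  expect_equal(dyadicDensity(10, 0), 0)
  expect_equal(dyadicDensity(10, 1), 10)
  expect_equal(dyadicDensity(12, 0.75), 9)
  expect_error(dyadicDensity(120, 0.5))
  g <- generateDyadPair(dyadSpec(seed = 38))
  dm <- dyadMetrics(g$pair)
  expect_identical(dm@dyadicDensityPercent, dm@ltccDensityPercent * dm@m1)
  expect_lte(dm@dyadicDensityPercent, dm@ltccDensityPercent)
})

test_that("nearest-LTCC distances equal the brute-force all-pairs minimum", {
  set.seed(39)
  h <- w <- 48
  ryrMask <- matrix(FALSE, h, w); ryrMask[sample(h * w, 150)] <- TRUE
  ltccMask <- matrix(FALSE, h, w); ltccMask[sample(h * w, 120)] <- TRUE
  ps <- 0.1
  pair <- channelPair(image2d(ryrMask * 1, ps), image2d(ltccMask * 1, ps),
                      matrix(TRUE, h, w))
  res <- nearestLtccDistances(pair, thresholds = c(0.5, 0.5))
  rp <- which(ryrMask, arr.ind = TRUE)
  lp <- which(ltccMask, arr.ind = TRUE)
  oracle <- apply(rp, 1, function(p)
    ps * sqrt(min((lp[, 1] - p[1])^2 + (lp[, 2] - p[2])^2)))
  expect_equal(sort(res$distancesUm), sort(oracle), tolerance = 1e-9)
  expect_identical(sum(res$counts), length(res$distancesUm))
})

test_that("distance map handles the textbook cases", {
  h <- w <- 32; ps <- 0.1
  ltcc <- matrix(0, h, w); ltcc[1, 1] <- 1
  ryr <- matrix(0, h, w); ryr[4, 5] <- 1    # offset (3, 4) -> 5 px
  pair <- channelPair(image2d(ryr, ps), image2d(ltcc, ps), matrix(TRUE, h, w))
  res <- nearestLtccDistances(pair, thresholds = c(0.5, 0.5))
  expect_equal(res$distancesUm, 0.5, tolerance = 1e-9)

  # RyR inside LTCC support: all distances zero
  both <- matrix(0, h, w); both[10:20, 10:20] <- 1
  pair2 <- channelPair(image2d(both, ps), image2d(both, ps),
                       matrix(TRUE, h, w))
  res2 <- nearestLtccDistances(pair2, thresholds = c(0.5, 0.5))
  expect_true(all(res2$distancesUm == 0))

  # empty LTCC mask: flagged, all infinite
  none <- image2d(matrix(0, h, w), ps)
  res3 <- nearestLtccDistances(channelPair(image2d(ryr, ps), none,
                                           matrix(TRUE, h, w)),
                               thresholds = c(0.5, 0.5))
  expect_identical(res3$flag, "all-infinite")
  expect_true(all(is.infinite(res3$distancesUm)))
})

test_that("orphan gaps right-shift the nearest-LTCC distance distribution", {
  for (s in 51:53) {
    g0 <- generateDyadPair(dyadSpec(orphanGapCount = 0, seed = s))
    g5 <- generateDyadPair(dyadSpec(orphanGapCount = 5, seed = s))
    d0 <- nearestLtccDistances(preprocessPair(g0$pair))
    d5 <- nearestLtccDistances(preprocessPair(g5$pair))
    # at realistic orphan shares (~10-15% of RyR pixels) the median is
    # pinned to the colocalized mass; the mean and the orphaned fraction
    # are the sensitive location statistics
    expect_gt(mean(d5$distancesUm), mean(d0$distancesUm))
    expect_gt(d5$orphanedFraction, d0$orphanedFraction)
  }
})
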