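# Global transients, dyssynchrony maps, site classification, local timing.

test_that("global kinetics are exact on an analytic ramp", {
  # baseline 100 for 9 frames, linear rise to 300 over 150 ms (dt = 1.5)
  f <- c(rep(100, 9), 100 + seq(0, 200, length.out = 101), rep(300, 20))
  v <- uniformVideo(f, dt = 1.5)
  roi <- matrix(TRUE, 24, 24)
  res <- globalTransient(v, roi, stimulusFrame = 10)
  expect_equal(res$kinetics@f50Level, 200)
  expect_equal(res$kinetics@tf50Ms, 75, tolerance = 1e-9)
  expect_equal(res$kinetics@timeToPeakMs, 150, tolerance = 1e-9)
  expect_identical(res$kinetics@flag, "")
})

test_that("a step at the stimulus peaks within one frame interval", {
  f <- c(rep(100, 9), rep(300, 30))
  v <- uniformVideo(f, dt = 1.5)
  res <- globalTransient(v, matrix(TRUE, 24, 24), 10)
  expect_lte(res$kinetics@timeToPeakMs, 1.5)
})

test_that("flat traces are flagged rather than fabricated", {
  v <- uniformVideo(rep(100, 30))
  res <- globalTransient(v, matrix(TRUE, 24, 24), 10)
  expect_identical(res$kinetics@flag, "flat-trace")
  expect_true(is.na(res$kinetics@tf50Ms))
  expect_error(globalTransient(v, matrix(TRUE, 24, 24), 2), "pre-stimulus")
  expect_error(globalTransient(v, matrix(FALSE, 24, 24), 10), "empty")
})

test_that("dyssynchrony is zero for synchrony, exact for two half-cells", {
  f <- c(rep(100, 9), 100 + seq(0, 200, length.out = 41))
  v <- uniformVideo(f, dt = 1.5)
  roi <- matrix(TRUE, 24, 24)
  di <- dyssynchronyMap(v, roi, 10)
  expect_equal(diMs(di), 0, tolerance = 1e-9)

  # two halves stepping at +10 ms and +30 ms (dt = 1 ms)
  onset <- matrix(15L, 20, 20); onset[11:20, ] <- 35L
  v2 <- stepVideo(onset, nframes = 60, dt = 1)
  di2 <- dyssynchronyMap(v2, matrix(TRUE, 20, 20), 5, smooth = FALSE)
  expect_equal(diMs(di2), 10, tolerance = 1e-9)
})

test_that("dyssynchrony index is invariant to offset and gain", {
  g <- generateCalciumVideo(calciumSpec(seed = 61))
  roi <- g$truth$footprint
  base <- diMs(dyssynchronyMap(g$video, roi, 20))
  shifted <- videoStack(pixels(g$video) + 37, 1.5, pixelSizeUm(g$video))
  scaled <- videoStack(pixels(g$video) * 2.4, 1.5, pixelSizeUm(g$video))
  expect_equal(diMs(dyssynchronyMap(shifted, roi, 20)), base, tolerance = 1e-9)
  expect_equal(diMs(dyssynchronyMap(scaled, roi, 20)), base, tolerance = 1e-9)
})

test_that("the programmed delay-field dispersion is recovered", {
  sp <- calciumSpec(siteDelayMeanMs = 30, siteDelaySdMs = 12,
                    orphanPropagationSpeedUmPerMs = Inf, seed = 62)
  g <- generateCalciumVideo(sp)
  di <- dyssynchronyMap(g$video, g$truth$footprint, sp$stimulusFrame)
  truthSd <- sd(g$truth$delayFieldMs[g$truth$footprint])
  expect_lt(abs(diMs(di) - truthSd), 2)
})

test_that("interpolated crossings converge on analytic values across rates", {
  tau <- 20
  analytic <- -tau * log(0.5)                 # time to half of (1 - exp(-t/tau))
  errs <- sapply(c(3, 1.5, 0.75), function(dt) {
    tt <- seq(0, 200, by = dt)
    f <- c(rep(100, 9), 100 + 200 * (1 - exp(-tt / tau)))
    res <- globalTransient(uniformVideo(f, dt = dt), matrix(TRUE, 24, 24), 10)
    abs(res$kinetics@tf50Ms - analytic)
  })
  expect_true(all(errs < c(3, 1.5, 0.75) + 1e-9))
  expect_lte(errs[3], errs[1] + 1e-9)
})

test_that("site classification respects the network geometry", {
  # intact grid: no orphaned sites
  g <- generateCalciumVideo(calciumSpec(
    network = tubuleNetworkSpec(cellLengthUm = 18, cellWidthUm = 9,
                                marginUm = 1.5, transverseOccupancy = 1,
                                longitudinalDensityPerUm2 = 0.05),
    seed = 63))
  sites <- classifyReleaseSites(g$membrane, nSites = 10)
  expect_identical(sum(sites$category == "orphaned"), 0L)
  # boxes fully inside the ROI
  half <- attr(sites, "halfPx")
  seg <- segmentTubules(g$membrane, rotate = FALSE)
  roi <- interiorRoi(seg)
  for (i in seq_len(nrow(sites))) {
    box <- roi[(sites$y[i] - half):(sites$y[i] + half),
               (sites$x[i] - half):(sites$x[i] + half)]
    expect_true(all(box))
  }
})

test_that("a deliberate tubule gap produces a centred orphaned site", {
  cols <- setdiff(seq(15, 125, by = 11), c(59, 70))   # 3.5 um hole
  img <- lineCellImage(cols = cols)
  sites <- classifyReleaseSites(img, nSites = 5, categories = "orphaned",
                                orphanCutoffUm = 1.2)
  expect_gte(nrow(sites), 1L)
  # the strongest orphan site sits in the carved-out gap, near column 64
  expect_lt(abs(sites$x[1] - 64) * 0.16, 1)
})

test_that("local TTF50 reproduces programmed release delays", {
  # uniform rise everywhere except one delayed block
  onset <- matrix(20L, 40, 40)
  onset[5:15, 5:15] <- 40L                   # +20 ms delay (dt = 1)
  v <- stepVideo(onset, nframes = 80, dt = 1, ps = 0.2)
  roi <- matrix(TRUE, 40, 40)
  gk <- globalTransient(v, roi, 10)$kinetics
  half <- 2L
  onTime <- localTtf50(v, list(x = 30, y = 30), gk, half)
  delayed <- localTtf50(v, list(x = 10, y = 10), gk, half)
  expect_identical(onTime$flag, "")
  expect_equal(delayed$ttf50Ms - onTime$ttf50Ms, 20, tolerance = 1)
})

test_that("a site identical to the whole cell matches global timing", {
  f <- c(rep(100, 9), 100 + seq(0, 200, length.out = 41), rep(300, 10))
  v <- uniformVideo(f, dt = 1.5)
  gk <- globalTransient(v, matrix(TRUE, 24, 24), 10)$kinetics
  site <- localTtf50(v, list(x = 12, y = 12), gk, 3L)
  expect_equal(site$ttf50Ms, gk@tf50Ms - gk@riseOnsetMs, tolerance = 1e-6)
})

test_that("orphaned sites report later release than transverse sites", {
  net <- tubuleNetworkSpec(cellLengthUm = 18, cellWidthUm = 9, marginUm = 1.5,
                          transverseOccupancy = 0.55,
                          longitudinalDensityPerUm2 = 0.02)
  for (s in c(71, 72)) {
    sp <- calciumSpec(network = net, siteDelayMeanMs = 3, siteDelaySdMs = 0,
                      orphanPropagationSpeedUmPerMs = 0.1, seed = s)
    g <- generateCalciumVideo(sp)
    sites <- classifyReleaseSites(g$membrane, nSites = 8)
    if (!any(sites$category == "orphaned")) next
    gk <- globalTransient(g$video, g$truth$footprint, sp$stimulusFrame)$kinetics
    half <- attr(sites, "halfPx")
    tt <- vapply(seq_len(nrow(sites)), function(i)
      localTtf50(g$video, sites[i, ], gk, half)$ttf50Ms, numeric(1))
    expect_gt(median(tt[sites$category == "orphaned"], na.rm = TRUE),
              median(tt[sites$category == "transverse"], na.rm = TRUE))
  }
})
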