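# Generator determinism and ground-truth sidecar consistency.

test_that("generators are bit-reproducible for a fixed spec and seed", {
  a <- generateTubuleImage(tubuleNetworkSpec(seed = 5))
  b <- generateTubuleImage(tubuleNetworkSpec(seed = 5))
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth$branchMap, b$truth$branchMap)
  c2 <- generateTubuleImage(tubuleNetworkSpec(seed = 6))
  expect_false(identical(pixels(a$image), pixels(c2$image)))

  d1 <- generateDyadPair(dyadSpec(seed = 5))
  d2 <- generateDyadPair(dyadSpec(seed = 5))
  expect_identical(pixels(d1$pair@ryr), pixels(d2$pair@ryr))
  expect_identical(d1$truth$puncta, d2$truth$puncta)

  v1 <- generateCalciumVideo(calciumSpec(seed = 5))
  v2 <- generateCalciumVideo(calciumSpec(seed = 5))
  expect_identical(pixels(v1$video), pixels(v2$video))

  w1 <- generateVoltageVideo(voltageSpec(seed = 5))
  w2 <- generateVoltageVideo(voltageSpec(seed = 5))
  expect_identical(pixels(w1$video), pixels(w2$video))
  expect_identical(w1$truth$depolarizedSkeletonMask,
                   w2$truth$depolarizedSkeletonMask)
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generateTubuleImage(tubuleNetworkSpec(seed = 9)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("tubule ground truth is internally consistent", {
  g <- generateTubuleImage(tubuleNetworkSpec(seed = 10))
  tr <- g$truth
  expect_identical(dim(tr$tubuleMask), dim(pixels(g$image)))
  expect_true(all(tr$skeletonMask[tr$branchMap > 0]))
  b <- tr$branches
  expect_equal(tr$transverseFraction,
               sum(b$lengthUm[b$label == "transverse"]) / sum(b$lengthUm))
  expect_true(all(tr$tubuleMask | !tr$skeletonMask | !tr$footprint))
  # fully transverse construction
  g2 <- generateTubuleImage(tubuleNetworkSpec(longitudinalDensityPerUm2 = 0,
                                              seed = 11))
  expect_equal(g2$truth$transverseFraction, 1)
  expect_error(generateTubuleImage(tubuleNetworkSpec(cellLengthUm = 1,
                                                     seed = 1)), "sarcomere")
})

test_that("dyad ground truth reports realized colocalized fractions", {
  g <- generateDyadPair(dyadSpec(colocFractionTransverse = 1,
                                 colocFractionLongitudinal = 1, seed = 12))
  expect_equal(g$truth$colocFractionTransverse, 1)
  p <- g$truth$puncta
  expect_true(all(p$hasLtcc == !p$orphan))
  g5 <- generateDyadPair(dyadSpec(orphanGapCount = 5, seed = 12))
  expect_gt(sum(g5$truth$puncta$orphan), 0)
  expect_true(all(!g5$truth$puncta$colocalized[g5$truth$puncta$orphan]))
})

test_that("calcium truth delay field matches the propagation model", {
  sp <- calciumSpec(siteDelayMeanMs = 5, siteDelaySdMs = 0,
                    orphanPropagationSpeedUmPerMs = 0.1, seed = 13)
  g <- generateCalciumVideo(sp)
  D <- g$truth$delayFieldMs
  # on the skeleton: pure site delay (distance term vanishes)
  expect_equal(unname(quantile(D[g$truth$skeletonMask], 0.5)), 5,
               tolerance = 0.5)
  # off-tubule delay grows with distance at 1/speed
  dmap <- dyadscape:::distanceToMask(g$truth$skeletonMask) * 0.16
  inside <- g$truth$footprint
  expect_equal(D[inside], 5 + dmap[inside] / 0.1, tolerance = 1e-9)
})

test_that("voltage truth matches the requested depolarized fraction", {
  for (f in c(0.25, 1)) {
    g <- generateVoltageVideo(voltageSpec(depolarizedFraction = f, seed = 14))
    expect_lt(abs(g$truth$realizedFraction - f), 0.02)
    expect_true(all(g$truth$skeletonMask[g$truth$depolarizedSkeletonMask]))
  }
  g0 <- generateVoltageVideo(voltageSpec(depolarizedFraction = 0, seed = 14))
  expect_identical(sum(g0$truth$depolarizedSkeletonMask), 0L)
})

test_that("phenotype presets produce valid specs for every modality", {
  for (ph in c("developing", "adult", "hf")) {
    expect_s3_class(phenotypePreset(ph, "tubules", 1), "TubuleNetworkSpec")
    expect_s3_class(phenotypePreset(ph, "dyads", 1), "DyadSpec")
    expect_s3_class(phenotypePreset(ph, "calcium", 1), "CalciumSpec")
    expect_s3_class(phenotypePreset(ph, "voltage", 1), "VoltageSpec")
  }
})
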