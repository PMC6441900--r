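# Seeded synthetic-data generators with ground-truth sidecars. The
# generators emulate the striated tubule network of cardiomyocytes at
# sarcomere spacing, paired punctate immunolabel channels, Ca2+ release
# videos with site-wise delays, and voltage-dye videos with a controllable
# depolarized skeleton fraction. Same spec + same seed => bit-identical
# output.

#' Tubule-network simulation parameters
#'
#' Defaults emulate a healthy adult ventricular myocyte imaged by confocal
#' microscopy of a membrane dye: a superelliptical cell footprint with a
#' bright surface sarcolemma, transverse tubules at Z-lines (sarcomere
#' pitch 1.8 um, jittered by <= 5%), sparse longitudinal connectors,
#' Gaussian PSF blur and Poisson-like photon noise.
#'
#' @param cellLengthUm,cellWidthUm cell dimensions (um)
#' @param sarcomereSpacingUm Z-line pitch (default 1.8 um)
#' @param transverseOccupancy probability that a Z-line position bears a
#'   transverse tubule
#' @param longitudinalDensityPerUm2 longitudinal connectors per um^2
#' @param tubuleWidthUm rendered tubule diameter (default 0.4 um)
#' @param psfSigmaUm Gaussian PSF sigma (default 0.18 um)
#' @param photonScale photons per intensity unit; noise variance is
#'   intensity / photonScale (Inf = noise-free)
#' @param backgroundLevel additive background intensity
#' @param amplitude tubule signal amplitude above background
#' @param pixelSizeUm sampling (default 0.16 um, confocal range)
#' @param marginUm empty border around the cell
#' @param seed RNG seed for this specification
#' @return a validated spec list of class "TubuleNetworkSpec"
#' @export
tubuleNetworkSpec <- function(cellLengthUm = 28, cellWidthUm = 13,
                              sarcomereSpacingUm = 1.8,
                              transverseOccupancy = 0.9,
                              longitudinalDensityPerUm2 = 0.03,
                              tubuleWidthUm = 0.4, psfSigmaUm = 0.18,
                              photonScale = 2, backgroundLevel = 10,
                              amplitude = 150, pixelSizeUm = 0.16,
                              marginUm = 2, seed = 1L) {
  spec <- list(cellLengthUm = cellLengthUm, cellWidthUm = cellWidthUm,
               sarcomereSpacingUm = sarcomereSpacingUm,
               transverseOccupancy = transverseOccupancy,
               longitudinalDensityPerUm2 = longitudinalDensityPerUm2,
               tubuleWidthUm = tubuleWidthUm, psfSigmaUm = psfSigmaUm,
               photonScale = photonScale, backgroundLevel = backgroundLevel,
               amplitude = amplitude, pixelSizeUm = pixelSizeUm,
               marginUm = marginUm, seed = as.integer(seed))
  stopifnot(cellLengthUm > 0, cellWidthUm > 0, sarcomereSpacingUm > 0,
            transverseOccupancy >= 0, transverseOccupancy <= 1,
            longitudinalDensityPerUm2 >= 0, tubuleWidthUm > 0,
            psfSigmaUm > 0, photonScale > 0, backgroundLevel >= 0,
            amplitude > 0, pixelSizeUm > 0, marginUm >= 0)
  if (cellLengthUm < sarcomereSpacingUm)
    stop("cell is smaller than one sarcomere")
  structure(spec, class = "TubuleNetworkSpec")
}

# Superellipse (exponent 4) cell footprint; x along the image width.
cellFootprint <- function(H, W, ps, lenUm, widUm) {
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  x <- (seq_len(W) - cx) * ps
  y <- (seq_len(H) - cy) * ps
  fx <- abs(x / (lenUm / 2))^4
  fy <- abs(y / (widUm / 2))^4
  outer(fy, fx, "+") <= 1
}

# chord half-height (um) of the footprint at longitudinal position x (um)
chordHalf <- function(xUm, lenUm, widUm) {
  f <- 1 - abs(xUm / (lenUm / 2))^4
  ifelse(f <= 0, 0, (widUm / 2) * f^0.25)
}

# Jittered Z-line x positions (um from cell centre).
zlinePositions <- function(lenUm, pitchUm) {
  n <- floor((lenUm - pitchUm) / pitchUm) + 1L
  x0 <- -((n - 1) / 2) * pitchUm
  x0 + (seq_len(n) - 1L) * pitchUm + stats::runif(n, -0.05, 0.05) * pitchUm
}

# Lay the true 1-px skeleton with branch labels. Returns branchMap (integer
# matrix), branch table, and helpers. Consumes RNG.
layNetwork <- function(spec) {
  ps <- spec$pixelSizeUm
  W <- round((spec$cellLengthUm + 2 * spec$marginUm) / ps)
  H <- round((spec$cellWidthUm + 2 * spec$marginUm) / ps)
  fp <- cellFootprint(H, W, ps, spec$cellLengthUm, spec$cellWidthUm)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  zx <- zlinePositions(spec$cellLengthUm, spec$sarcomereSpacingUm)
  occupied <- stats::runif(length(zx)) < spec$transverseOccupancy
  bmap <- matrix(0L, H, W)
  lab <- character(0); len <- numeric(0)
  id <- 0L
  for (i in seq_along(zx)) {
    if (!occupied[i]) next
    col <- round(cx + zx[i] / ps)
    if (col < 1L || col > W) next
    b <- 0.88 * chordHalf(zx[i], spec$cellLengthUm, spec$cellWidthUm)
    if (b <= 0) next
    rows <- max(1L, round(cy - b / ps)):min(H, round(cy + b / ps))
    id <- id + 1L
    bmap[rows, col] <- id
    lab <- c(lab, "transverse"); len <- c(len, length(rows) * ps)
  }
  areaUm2 <- sum(fp) * ps^2
  nLong <- round(spec$longitudinalDensityPerUm2 * areaUm2)
  gaps <- length(zx) - 1L
  for (j in seq_len(nLong)) {
    if (gaps < 1L) break
    g <- sample.int(gaps, 1L)
    span <- if (stats::runif(1) < 0.3 && g < gaps) 2L else 1L
    x0 <- zx[g]; x1 <- zx[min(g + span, length(zx))]
    xm <- (x0 + x1) / 2
    b <- 0.8 * chordHalf(xm, spec$cellLengthUm, spec$cellWidthUm)
    if (b <= 0) next
    yUm <- stats::runif(1, -b, b)
    row <- round(cy + yUm / ps)
    if (row < 1L || row > H) next
    cols <- max(1L, round(cx + x0 / ps)):min(W, round(cx + x1 / ps))
    if (length(cols) < 2L) next
    free <- bmap[row, cols] == 0L
    id <- id + 1L
    bmap[row, cols[free]] <- id
    lab <- c(lab, "longitudinal"); len <- c(len, length(cols) * ps)
  }
  branchTable <- data.frame(branch = seq_len(id), label = lab,
                            lengthUm = len)
  outline <- fp & !binErode(fp, 1L)
  list(branchMap = bmap, branches = branchTable, footprint = fp,
       outline = outline, zxUm = zx, occupied = occupied,
       H = H, W = W, cx = cx, cy = cy, ps = ps)
}

# Gaussian blur that tolerates sigma in pixels.
blurPx <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  r <- max(5L, 2L * ceiling(3 * sigmaPx) + 1L)   # gblur wants an odd size
  as.matrix(EBImage::gblur(m, sigma = sigmaPx, radius = r))
}

# Poisson-like photon noise plus read noise.
addNoise <- function(I, photonScale, readNoiseSd = 1) {
  if (is.finite(photonScale))
    I <- I + stats::rnorm(length(I), 0, sqrt(pmax(I, 0) / photonScale))
  I <- I + stats::rnorm(length(I), 0, readNoiseSd)
  I[I < 0] <- 0
  I
}

#' Simulate a membrane-dye tubule micrograph with ground truth
#'
#' Lays transverse tubule segments at jittered Z-line positions (each
#' occupied with probability \code{transverseOccupancy}) and longitudinal
#' connectors at the stated areal density, dilates the 1-px skeleton to the
#' tubule width, adds the surface sarcolemma outline, convolves with a
#' Gaussian PSF, and adds background plus Poisson-like noise. The ground
#' truth carries the labelled skeleton, the tubule object mask (without the
#' sarcolemma), the footprint, and the length-weighted transverse fraction.
#'
#' @param spec a \code{\link{tubuleNetworkSpec}}
#' @return list with \code{image} (\linkS4class{Image2D}) and \code{truth}
#' @export
generateTubuleImage <- function(spec) {
  stopifnot(inherits(spec, "TubuleNetworkSpec"))
  withr::with_seed(spec$seed, {
    net <- layNetwork(spec)
    wpx <- oddPixels(spec$tubuleWidthUm, net$ps)
    brush <- EBImage::makeBrush(wpx, shape = "disc")
    tubuleMask <- as.matrix(EBImage::dilate((net$branchMap > 0L) * 1,
                                            brush)) > 0.5
    tubuleMask <- tubuleMask & net$footprint
    outlineMask <- as.matrix(EBImage::dilate(net$outline * 1, brush)) > 0.5
    obj <- (tubuleMask | outlineMask) * 1
    I <- spec$backgroundLevel +
      spec$amplitude * blurPx(obj, spec$psfSigmaUm / net$ps)
    I <- matrix(addNoise(I, spec$photonScale), net$H, net$W)
    tl <- net$branches$lengthUm[net$branches$label == "transverse"]
    total <- sum(net$branches$lengthUm)
    interior <- binErode(net$footprint,
                         as.integer(ceiling(1 / net$ps)))
    truth <- list(
      skeletonMask = net$branchMap > 0L,
      branchMap = net$branchMap,
      branches = net$branches,
      tubuleMask = tubuleMask,
      footprint = net$footprint,
      interiorRoi = interior,
      zlineXUm = net$zxUm,
      occupied = net$occupied,
      transverseFraction = if (total > 0) sum(tl) / total else NA_real_,
      densityPercent = if (any(interior))
        100 * sum(tubuleMask & interior) / sum(interior) else NA_real_,
      spec = spec, seed = spec$seed)
    list(image = image2d(I, net$ps, "membrane"), truth = truth)
  })
}

#' Dyad-pair simulation parameters
#'
#' Geometry comes from an embedded \code{\link{tubuleNetworkSpec}} sampled
#' at Airyscan-like resolution (default 0.05 um/px, so the default
#' 17 x 17 / 13 x 13 orientation kernels apply unscaled). RyR clusters are
#' laid as beaded rows along Z-lines (and along longitudinal elements);
#' for each orientation a fraction of LTCC puncta is placed coincident with
#' its RyR partner and the remainder displaced by an isotropic Gaussian
#' offset. Orphan gaps are Z-line stretches that keep RyR but lose their
#' LTCC partner.
#'
#' @param network a \code{\link{tubuleNetworkSpec}} (geometry source)
#' @param ryrClusterPitchUm RyR cluster pitch along lines (default 0.6 um)
#' @param ryrOccupancy probability a lattice position carries a cluster
#' @param colocFractionTransverse,colocFractionLongitudinal per-orientation
#'   colocalized fractions in [0, 1]
#' @param displacementSigmaUm Gaussian offset SD of non-colocalized LTCC
#'   (default 0.5 um)
#' @param orphanGapCount number of Z-line stretches with RyR but no LTCC
#' @param orphanGapLengthUm length of each such stretch (default 3 um)
#' @param extraLtccRate LTCC-only puncta per RyR punctum (default 0.05)
#' @param noiseSd Gaussian read noise (default 4)
#' @param seed RNG seed
#' @return spec list of class "DyadSpec"
#' @export
dyadSpec <- function(network = tubuleNetworkSpec(cellLengthUm = 16,
                                                 cellWidthUm = 8,
                                                 pixelSizeUm = 0.05,
                                                 marginUm = 1.2,
                                                 psfSigmaUm = 0.07,
                                                 longitudinalDensityPerUm2 = 0.1),
                     ryrClusterPitchUm = 0.6, ryrOccupancy = 0.85,
                     colocFractionTransverse = 0.9,
                     colocFractionLongitudinal = 0.3,
                     displacementSigmaUm = 0.5, orphanGapCount = 0L,
                     orphanGapLengthUm = 3, extraLtccRate = 0.05,
                     nonspecificAmplitude = 8, noiseSd = 4, seed = 1L) {
  stopifnot(inherits(network, "TubuleNetworkSpec"),
            ryrClusterPitchUm > 0, ryrOccupancy >= 0, ryrOccupancy <= 1,
            colocFractionTransverse >= 0, colocFractionTransverse <= 1,
            colocFractionLongitudinal >= 0, colocFractionLongitudinal <= 1,
            displacementSigmaUm >= 0, orphanGapCount >= 0, noiseSd >= 0)
  structure(list(network = network, ryrClusterPitchUm = ryrClusterPitchUm,
                 ryrOccupancy = ryrOccupancy,
                 colocFractionTransverse = colocFractionTransverse,
                 colocFractionLongitudinal = colocFractionLongitudinal,
                 displacementSigmaUm = displacementSigmaUm,
                 orphanGapCount = as.integer(orphanGapCount),
                 orphanGapLengthUm = orphanGapLengthUm,
                 extraLtccRate = extraLtccRate,
                 nonspecificAmplitude = nonspecificAmplitude,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "DyadSpec")
}

# render point spots (um coordinates relative to cell centre) into a matrix
renderSpots <- function(H, W, cx, cy, ps, xUm, yUm, amp, sigmaPx) {
  m <- matrix(0, H, W)
  col <- round(cx + xUm / ps); row <- round(cy + yUm / ps)
  ok <- row >= 1L & row <= H & col >= 1L & col <= W
  for (i in which(ok)) m[row[i], col[i]] <- m[row[i], col[i]] + amp[i]
  blurPx(m, sigmaPx) * (2 * pi * sigmaPx^2)   # unit peak per unit amplitude
}

#' Simulate an RyR/LTCC immunolabel pair with ground truth
#'
#' @param spec a \code{\link{dyadSpec}}
#' @return list with \code{pair} (\linkS4class{ChannelPair}) and
#'   \code{truth} (puncta table, realized per-orientation colocalized
#'   fractions, Z-line mask, footprint)
#' @export
generateDyadPair <- function(spec) {
  stopifnot(inherits(spec, "DyadSpec"))
  ns <- spec$network
  withr::with_seed(spec$seed, {
    ps <- ns$pixelSizeUm
    W <- round((ns$cellLengthUm + 2 * ns$marginUm) / ps)
    H <- round((ns$cellWidthUm + 2 * ns$marginUm) / ps)
    fp <- cellFootprint(H, W, ps, ns$cellLengthUm, ns$cellWidthUm)
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    zx <- zlinePositions(ns$cellLengthUm, ns$sarcomereSpacingUm)
    pitch <- spec$ryrClusterPitchUm
    # orphan stretches: z-line index -> y interval
    orphan <- list()
    if (spec$orphanGapCount > 0L) {
      lines <- sample(seq_along(zx),
                      min(spec$orphanGapCount, length(zx)))
      for (li in lines) {
        b <- 0.85 * chordHalf(zx[li], ns$cellLengthUm, ns$cellWidthUm)
        c0 <- stats::runif(1, -b + spec$orphanGapLengthUm / 2,
                           b - spec$orphanGapLengthUm / 2)
        orphan[[as.character(li)]] <-
          c(c0 - spec$orphanGapLengthUm / 2, c0 + spec$orphanGapLengthUm / 2)
      }
    }
    puncta <- NULL
    addRow <- function(x, y, orientation, zline = NA_integer_) {
      rbind(puncta, data.frame(xUm = x, yUm = y, orientation = orientation,
                               zline = zline))
    }
    for (i in seq_along(zx)) {
      b <- 0.85 * chordHalf(zx[i], ns$cellLengthUm, ns$cellWidthUm)
      if (b <= pitch) next
      ys <- seq(-b, b, by = pitch) + stats::runif(1, -0.1, 0.1) * pitch
      ys <- ys + stats::rnorm(length(ys), 0, 0.05 * pitch)
      keep <- stats::runif(length(ys)) < spec$ryrOccupancy
      puncta <- addRow(rep(zx[i], sum(keep)), ys[keep], "transverse", i)
    }
    areaUm2 <- sum(fp) * ps^2
    nLong <- round(ns$longitudinalDensityPerUm2 * areaUm2)
    for (j in seq_len(nLong)) {
      if (length(zx) < 2L) break
      g <- sample.int(length(zx) - 1L, 1L)
      span <- if (stats::runif(1) < 0.3 && g < length(zx) - 1L) 2L else 1L
      xm <- (zx[g] + zx[g + span]) / 2
      b <- 0.8 * chordHalf(xm, ns$cellLengthUm, ns$cellWidthUm)
      if (b <= 0) next
      yr <- stats::runif(1, -b, b)
      xs <- seq(zx[g], zx[g + span], by = pitch)
      # longitudinal dyads sit between Z-lines; junctional clusters at the
      # crossings are already counted as transverse
      nearZ <- vapply(xs, function(x) min(abs(x - zx)) < 0.35, logical(1))
      xs <- xs[!nearZ]
      if (length(xs) == 0L) next
      puncta <- addRow(xs, rep(yr, length(xs)), "longitudinal")
    }
    # orphan flag
    puncta$orphan <- FALSE
    for (li in names(orphan)) {
      iv <- orphan[[li]]
      hit <- puncta$orientation == "transverse" &
        !is.na(puncta$zline) & puncta$zline == as.integer(li) &
        puncta$yUm >= iv[1L] & puncta$yUm <= iv[2L]
      puncta$orphan[hit] <- TRUE
    }
    n <- nrow(puncta)
    pColoc <- ifelse(puncta$orientation == "transverse",
                     spec$colocFractionTransverse,
                     spec$colocFractionLongitudinal)
    puncta$colocalized <- stats::runif(n) < pColoc & !puncta$orphan
    puncta$hasLtcc <- !puncta$orphan
    # Non-dyadic LTCC sit in RyR-free stretches of their own tubule
    # membrane: displaced along the structure (Gaussian magnitude, at least
    # minSepUm away) and rejected while they fall on any RyR cluster -
    # otherwise the "non-colocalized" truth label would contradict the
    # rendered geometry.
    minSepUm <- 0.45
    displacedPos <- function(i) {
      trans <- puncta$orientation[i] == "transverse"
      along <- if (trans) c(0, 1) else c(1, 0)
      best <- NULL; bestD <- -Inf
      for (try in 1:30) {
        d <- stats::rnorm(1, 0, spec$displacementSigmaUm)
        if (abs(d) < minSepUm) d <- sign(d + 1e-12) * (minSepUm + abs(d))
        x <- puncta$xUm[i] + along[1L] * d + stats::rnorm(1, 0, 0.05)
        y <- puncta$yUm[i] + along[2L] * d + stats::rnorm(1, 0, 0.05)
        sep <- sqrt(min((puncta$xUm - x)^2 + (puncta$yUm - y)^2))
        # keep longitudinal free membrane between Z-lines: near the Z-line
        # a longitudinal segment merges into the junctional (transverse)
        # compartment
        if (!trans && min(abs(zx - x)) < minSepUm) sep <- -1
        if (sep >= minSepUm * 0.93) return(c(x, y))
        if (sep > bestD) { bestD <- sep; best <- c(x, y) }
      }
      best
    }
    puncta$ltccXUm <- NA_real_; puncta$ltccYUm <- NA_real_
    for (i in seq_len(n)) {
      if (!puncta$hasLtcc[i]) next
      if (puncta$colocalized[i]) {
        # dyadic partners face each other across a ~15 nm cleft: in-plane
        # offsets are far below the optical resolution
        puncta$ltccXUm[i] <- puncta$xUm[i] + stats::rnorm(1, 0, 0.015)
        puncta$ltccYUm[i] <- puncta$yUm[i] + stats::rnorm(1, 0, 0.015)
      } else {
        p2 <- displacedPos(i)
        puncta$ltccXUm[i] <- p2[1L]; puncta$ltccYUm[i] <- p2[2L]
      }
    }
    nExtra <- stats::rpois(1, spec$extraLtccRate * n)
    exX <- exY <- numeric(nExtra)
    for (k in seq_len(nExtra)) {
      for (try in 1:30) {
        exX[k] <- stats::runif(1, -ns$cellLengthUm / 2, ns$cellLengthUm / 2)
        exY[k] <- stats::runif(1, -ns$cellWidthUm / 2, ns$cellWidthUm / 2)
        if (sqrt(min((puncta$xUm - exX[k])^2 +
                     (puncta$yUm - exY[k])^2)) >= minSepUm) break
      }
    }
    sigmaPx <- ns$psfSigmaUm / ps
    ampR <- stats::runif(n, 0.7, 1.3) * ns$amplitude
    ryrImg <- ns$backgroundLevel +
      renderSpots(H, W, cx, cy, ps, puncta$xUm, puncta$yUm, ampR, sigmaPx)
    sel <- puncta$hasLtcc
    # intact dyads pack the two proteins together, so their channel
    # brightnesses correlate; displaced and extra LTCC are independent
    ampL <- ifelse(puncta$colocalized[sel],
                   ampR[sel] * stats::runif(sum(sel), 0.9, 1.1),
                   stats::runif(sum(sel), 0.7, 1.3) * ns$amplitude)
    ampL <- c(ampL, stats::runif(nExtra, 0.7, 1.3) * ns$amplitude)
    ltccImg <- ns$backgroundLevel +
      renderSpots(H, W, cx, cy, ps,
                  c(puncta$ltccXUm[sel], exX), c(puncta$ltccYUm[sel], exY),
                  ampL, sigmaPx)
    # channel-independent nonspecific labelling (blurred positive texture)
    nonspec <- function() {
      tex <- matrix(pmax(stats::rnorm(H * W), 0), H, W)
      tex <- blurPx(tex, 0.3 / ps)
      spec$nonspecificAmplitude * tex / max(mean(tex), 1e-9) * fp
    }
    ryrImg <- ryrImg + nonspec()
    ltccImg <- ltccImg + nonspec()
    ryrImg <- matrix(ryrImg + stats::rnorm(length(ryrImg), 0, spec$noiseSd),
                     H, W)
    ltccImg <- matrix(ltccImg + stats::rnorm(length(ltccImg), 0,
                                             spec$noiseSd), H, W)
    ryrImg[ryrImg < 0] <- 0; ltccImg[ltccImg < 0] <- 0
    # Z-line pixel mask spanned by the RyR rows (for orientation-mask checks)
    zmask <- matrix(FALSE, H, W)
    for (i in seq_along(zx)) {
      pts <- puncta$yUm[puncta$orientation == "transverse" &
                          !is.na(puncta$zline) & puncta$zline == i]
      if (length(pts) < 2L) next
      col <- round(cx + zx[i] / ps)
      if (col < 1L || col > W) next
      rows <- max(1L, round(cy + min(pts) / ps)):
        min(H, round(cy + max(pts) / ps))
      zmask[rows, col] <- TRUE
    }
    realized <- function(o) {
      s <- puncta$orientation == o
      if (!any(s)) return(NA_real_)
      sum(puncta$colocalized[s]) / sum(s)
    }
    pair <- channelPair(image2d(ryrImg, ps, "RyR"),
                        image2d(ltccImg, ps, "LTCC"), fp)
    truth <- list(puncta = puncta,
                  colocFractionTransverse = realized("transverse"),
                  colocFractionLongitudinal = realized("longitudinal"),
                  zlineMask = zmask, footprint = fp, zlineXUm = zx,
                  orphanStretches = orphan, spec = spec, seed = spec$seed)
    list(pair = pair, truth = truth)
  })
}

#' Calcium-video simulation parameters
#'
#' Fluorescence at each cell pixel follows
#' baseline + amplitude * (1 - exp(-(t - t0)/riseTau)) * exp(-(t - t0)/decayTau)
#' for t > t0. The onset t0 is the stimulus time plus the release delay of
#' the nearest tubule site (drawn per ~1 um skeleton segment from
#' N(siteDelayMean, siteDelaySd), truncated at 0) plus a propagation term,
#' distance-to-nearest-tubule / orphanPropagationSpeed, so pixels in tubule
#' gaps ("orphaned" sites) rise late.
#'
#' @param network a \code{\link{tubuleNetworkSpec}} (geometry source)
#' @param baseline,amplitude trace baseline and amplitude
#' @param riseTauMs,decayTauMs kinetic time constants (ms)
#' @param siteDelayMeanMs,siteDelaySdMs per-site release delay distribution
#' @param orphanPropagationSpeedUmPerMs Ca2+ wave speed into tubule-free
#'   regions (Inf = instantaneous)
#' @param frameIntervalMs sampling interval (default 1.5 ms)
#' @param nFrames number of frames
#' @param stimulusFrame stimulus frame index
#' @param noiseSd Gaussian noise SD
#' @param seed RNG seed
#' @return spec list of class "CalciumSpec"
#' @export
calciumSpec <- function(network = tubuleNetworkSpec(cellLengthUm = 18,
                                                    cellWidthUm = 9,
                                                    marginUm = 1.5),
                        baseline = 50, amplitude = 120, riseTauMs = 8,
                        decayTauMs = 80, siteDelayMeanMs = 5,
                        siteDelaySdMs = 3,
                        orphanPropagationSpeedUmPerMs = 0.3,
                        frameIntervalMs = 1.5, nFrames = 160,
                        stimulusFrame = 20L, noiseSd = 3, seed = 1L) {
  stopifnot(inherits(network, "TubuleNetworkSpec"), baseline > 0,
            amplitude > 0, riseTauMs > 0, decayTauMs > 0,
            siteDelaySdMs >= 0, orphanPropagationSpeedUmPerMs > 0,
            frameIntervalMs > 0, nFrames >= 10, stimulusFrame >= 4,
            noiseSd >= 0)
  maxDelay <- siteDelayMeanMs + 4 * siteDelaySdMs
  if ((nFrames - stimulusFrame) * frameIntervalMs < maxDelay + 3 * riseTauMs)
    stop("frame budget too short for the programmed delays")
  structure(list(network = network, baseline = baseline,
                 amplitude = amplitude, riseTauMs = riseTauMs,
                 decayTauMs = decayTauMs, siteDelayMeanMs = siteDelayMeanMs,
                 siteDelaySdMs = siteDelaySdMs,
                 orphanPropagationSpeedUmPerMs = orphanPropagationSpeedUmPerMs,
                 frameIntervalMs = frameIntervalMs,
                 nFrames = as.integer(nFrames),
                 stimulusFrame = as.integer(stimulusFrame),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "CalciumSpec")
}

#' Simulate a Ca2+ release video with ground truth
#'
#' Returns the video, a co-registered membrane-dye frame of the same
#' network (for site classification), and ground truth holding the
#' per-pixel release-delay field.
#'
#' @param spec a \code{\link{calciumSpec}}
#' @return list with \code{video} (\linkS4class{VideoStack}),
#'   \code{membrane} (\linkS4class{Image2D}) and \code{truth}
#' @export
generateCalciumVideo <- function(spec) {
  stopifnot(inherits(spec, "CalciumSpec"))
  ns <- spec$network
  withr::with_seed(spec$seed, {
    net <- layNetwork(ns)
    H <- net$H; W <- net$W; ps <- net$ps
    skel <- net$branchMap > 0L
    if (!any(skel)) stop("network has no tubules")
    skIdx <- which(skel)
    skPos <- arrayInd(skIdx, dim(skel))
    # ~1 um release sites along the skeleton
    siteKey <- paste(net$branchMap[skIdx],
                     floor(skPos[, 1L] * ps), floor(skPos[, 2L] * ps))
    siteId <- as.integer(factor(siteKey))
    nSites <- max(siteId)
    siteDelay <- pmax(stats::rnorm(nSites, spec$siteDelayMeanMs,
                                   spec$siteDelaySdMs), 0)
    fpIdx <- which(net$footprint)
    fpPos <- arrayInd(fpIdx, dim(skel))
    nn <- as.integer(as.character(class::knn1(
      skPos, fpPos, factor(seq_along(skIdx)))))
    nnDelay <- siteDelay[siteId[nn]]
    dmapUm <- distanceToMask(skel) * ps
    prop <- if (is.finite(spec$orphanPropagationSpeedUmPerMs))
      dmapUm[fpIdx] / spec$orphanPropagationSpeedUmPerMs else 0
    delay <- nnDelay + prop
    stimMs <- (spec$stimulusFrame - 1L) * spec$frameIntervalMs
    t0 <- stimMs + delay
    frames <- array(0, c(H, W, spec$nFrames))
    background <- 5
    base <- matrix(background, H, W)
    base[fpIdx] <- spec$baseline
    shape <- function(u) ifelse(u > 0,
                                (1 - exp(-u / spec$riseTauMs)) *
                                  exp(-u / spec$decayTauMs), 0)
    for (t in seq_len(spec$nFrames)) {
      tm <- (t - 1L) * spec$frameIntervalMs
      f <- base
      f[fpIdx] <- spec$baseline + spec$amplitude * shape(tm - t0)
      frames[, , t] <- f
    }
    frames <- frames + stats::rnorm(length(frames), 0, spec$noiseSd)
    frames[frames < 0] <- 0
    # co-registered membrane frame (light noise, same geometry)
    wpx <- oddPixels(ns$tubuleWidthUm, ps)
    brush <- EBImage::makeBrush(wpx, shape = "disc")
    obj <- ((as.matrix(EBImage::dilate(skel * 1, brush)) > 0.5 &
               net$footprint) |
              (as.matrix(EBImage::dilate(net$outline * 1, brush)) > 0.5)) * 1
    mem <- ns$backgroundLevel + ns$amplitude * blurPx(obj, ns$psfSigmaUm / ps)
    mem <- matrix(addNoise(mem, ns$photonScale), H, W)
    delayField <- matrix(NA_real_, H, W)
    delayField[fpIdx] <- delay
    truth <- list(delayFieldMs = delayField, skeletonMask = skel,
                  branchMap = net$branchMap, branches = net$branches,
                  footprint = net$footprint,
                  interiorRoi = binErode(net$footprint,
                                         as.integer(ceiling(1 / ps))),
                  siteDelaysMs = siteDelay, stimulusMs = stimMs,
                  spec = spec, seed = spec$seed)
    list(video = videoStack(frames, spec$frameIntervalMs, ps),
         membrane = image2d(mem, ps, "membrane"),
         truth = truth)
  })
}

#' Voltage-video simulation parameters
#'
#' @param network a \code{\link{tubuleNetworkSpec}} (geometry source)
#' @param depolarizedFraction target fraction of skeleton length that
#'   depolarizes, in [0, 1]
#' @param stepAmplitudePercent fluorescence step of depolarized tubules
#'   (percent of the local structure signal, default 12)
#' @param onsetFrame frame at which the step begins
#' @param contractionFrame frame of contraction motion
#'   (> onsetFrame + 3)
#' @param motionAmplitudePx rigid translation applied from
#'   \code{contractionFrame}
#' @param frameIntervalMs sampling interval (default 10 ms)
#' @param nFrames number of frames
#' @param noiseSd Gaussian noise SD (default 2)
#' @param seed RNG seed
#' @return spec list of class "VoltageSpec"
#' @export
voltageSpec <- function(network = tubuleNetworkSpec(cellLengthUm = 20,
                                                    cellWidthUm = 10,
                                                    marginUm = 1.5),
                        depolarizedFraction = 1, stepAmplitudePercent = 12,
                        onsetFrame = 8L, contractionFrame = 14L,
                        motionAmplitudePx = 2L, frameIntervalMs = 10,
                        nFrames = 24L, noiseSd = 2, seed = 1L) {
  stopifnot(inherits(network, "TubuleNetworkSpec"),
            depolarizedFraction >= 0, depolarizedFraction <= 1,
            stepAmplitudePercent >= 0, onsetFrame >= 2,
            contractionFrame > onsetFrame + 3, nFrames >= contractionFrame,
            motionAmplitudePx >= 0, frameIntervalMs > 0, noiseSd >= 0)
  structure(list(network = network,
                 depolarizedFraction = depolarizedFraction,
                 stepAmplitudePercent = stepAmplitudePercent,
                 onsetFrame = as.integer(onsetFrame),
                 contractionFrame = as.integer(contractionFrame),
                 motionAmplitudePx = as.integer(motionAmplitudePx),
                 frameIntervalMs = frameIntervalMs,
                 nFrames = as.integer(nFrames), noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "VoltageSpec")
}

#' Simulate a voltage-dye (FluoVolt) video with ground truth
#'
#' Selects a random subset of skeleton branches (topped up pixel-wise on
#' the last branch) totalling \code{depolarizedFraction} of the skeleton;
#' their territory steps up by \code{stepAmplitudePercent} from
#' \code{onsetFrame}, and a rigid translation is applied from
#' \code{contractionFrame}.
#'
#' @param spec a \code{\link{voltageSpec}}
#' @return list with \code{video}, \code{skeleton}
#'   (\linkS4class{TubuleSkeleton} of the true network) and \code{truth}
#' @export
generateVoltageVideo <- function(spec) {
  stopifnot(inherits(spec, "VoltageSpec"))
  ns <- spec$network
  withr::with_seed(spec$seed, {
    net <- layNetwork(ns)
    H <- net$H; W <- net$W; ps <- net$ps
    skel <- net$branchMap > 0L
    if (!any(skel)) stop("network has no tubules")
    skIdx <- which(skel)
    nTarget <- round(spec$depolarizedFraction * length(skIdx))
    depIdx <- integer(0)
    if (nTarget > 0L) {
      ord <- sample(seq_len(nrow(net$branches)))
      for (b in ord) {
        bi <- which(net$branchMap == b)
        if (length(depIdx) + length(bi) <= nTarget) {
          depIdx <- c(depIdx, bi)
        } else {
          need <- nTarget - length(depIdx)
          if (need > 0L) depIdx <- c(depIdx, bi[seq_len(need)])
          break
        }
      }
    }
    depMask <- matrix(FALSE, H, W)
    depMask[depIdx] <- TRUE
    wpx <- oddPixels(ns$tubuleWidthUm, ps)
    brush <- EBImage::makeBrush(wpx, shape = "disc")
    tubMask <- as.matrix(EBImage::dilate(skel * 1, brush)) > 0.5 &
      net$footprint
    depTerr <- as.matrix(EBImage::dilate(depMask * 1, brush)) > 0.5 &
      tubMask
    sigmaPx <- ns$psfSigmaUm / ps
    blurAll <- blurPx(tubMask * 1, sigmaPx)
    blurDep <- blurPx(depTerr * 1, sigmaPx)
    baseFrame <- ns$backgroundLevel + ns$amplitude * blurAll
    stepFrame <- baseFrame +
      ns$amplitude * (spec$stepAmplitudePercent / 100) * blurDep
    frames <- array(0, c(H, W, spec$nFrames))
    for (t in seq_len(spec$nFrames)) {
      f <- if (t >= spec$onsetFrame) stepFrame else baseFrame
      if (t >= spec$contractionFrame && spec$motionAmplitudePx > 0L)
        f <- shiftMatrix(f, spec$motionAmplitudePx, 0L,
                         fill = ns$backgroundLevel)
      frames[, , t] <- f
    }
    frames <- frames + stats::rnorm(length(frames), 0, spec$noiseSd)
    frames[frames < 0] <- 0
    skeleton <- skeletonFromMask(skel, ps)
    truth <- list(depolarizedSkeletonMask = depMask,
                  realizedFraction = length(depIdx) / length(skIdx),
                  skeletonMask = skel, branchMap = net$branchMap,
                  footprint = net$footprint, tubuleMask = tubMask,
                  spec = spec, seed = spec$seed)
    list(video = videoStack(frames, spec$frameIntervalMs, ps),
         skeleton = skeleton, truth = truth)
  })
}
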