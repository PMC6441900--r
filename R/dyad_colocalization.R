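# Two-channel dyadic protein analysis: Manders fractional overlap with
# automatic (Costes) thresholds, orientation-resolved colocalization,
# protein and dyadic densities, and nearest-neighbour distance maps.

#' Construct an aligned two-channel pair
#'
#' @param ryr RyR-channel \linkS4class{Image2D}
#' @param ltcc partner-channel \linkS4class{Image2D} (same shape/calibration)
#' @param cellRoi logical matrix marking the cell interior
#' @param nucleusMask optional logical matrix of nuclei to exclude
#' @return a \linkS4class{ChannelPair}
#' @export
channelPair <- function(ryr, ltcc, cellRoi, nucleusMask = NULL) {
  if (is.null(nucleusMask))
    nucleusMask <- matrix(FALSE, nrow(cellRoi), ncol(cellRoi))
  new("ChannelPair", ryr = ryr, ltcc = ltcc,
      cellRoi = unname(cellRoi), nucleusMask = unname(nucleusMask))
}

#' Background-subtract both channels and clear extracellular signal
#'
#' Rolling-ball background subtraction (default radius 20 px) per channel,
#' then zeroing of everything outside the cell ROI.
#'
#' @param pair a \linkS4class{ChannelPair}
#' @param backgroundRadiusPx rolling-ball radius (default 20)
#' @return the preprocessed \linkS4class{ChannelPair}
#' @export
preprocessPair <- function(pair, backgroundRadiusPx = 20) {
  stopifnot(is(pair, "ChannelPair"))
  clean <- function(img) {
    out <- subtractBackground(img, backgroundRadiusPx)
    px <- out@pixels
    px[!pair@cellRoi] <- 0
    image2d(px, img@pixelSizeUm, img@channelName)
  }
  channelPair(clean(pair@ryr), clean(pair@ltcc), pair@cellRoi,
              pair@nucleusMask)
}

# Costes automatic threshold pair. Reduced-major-axis regression of ltcc
# on ryr over the ROI (symmetric in the two channels up to inversion, and
# scale-equivariant, so the thresholds - and hence M1/M2 - are invariant to
# rescaling either channel), then the threshold is lowered from the maximum
# until the correlation of the below-threshold pixels is statistically
# indistinguishable from zero (rho <= z/sqrt(n); a strict rho <= 0 test
# walks far into the noise floor because sampling wobble keeps rho barely
# positive across the flat tail of the curve). When no such point exists
# the threshold with minimal below-set correlation is used. Returns NULL
# when the regression itself is inapplicable (non-positive association).
costesThresholds <- function(r, l, nLevels = 256L, minPixels = 20L,
                             z = 2.5) {
  if (stats::sd(r) == 0 || stats::sd(l) == 0) return(NULL)
  cv <- stats::cov(r, l)
  if (cv <= 0) return(NULL)
  slope <- stats::sd(l) / stats::sd(r)
  if (!is.finite(slope) || slope <= 0) return(NULL)
  inter <- mean(l) - slope * mean(r)
  bestRho <- Inf; bestT <- NA_real_
  for (Tr in seq(max(r), min(r), length.out = nLevels)) {
    Tl <- inter + slope * Tr
    sel <- r < Tr & l < Tl
    n <- sum(sel)
    if (n < minPixels) next
    if (stats::sd(r[sel]) == 0 || stats::sd(l[sel]) == 0) next
    rho <- stats::cor(r[sel], l[sel])
    if (!is.finite(rho)) next
    if (rho <= z / sqrt(n))
      return(list(tRyr = Tr, tLtcc = inter + slope * Tr, method = "costes"))
    if (rho < bestRho) { bestRho <- rho; bestT <- Tr }
  }
  if (!is.na(bestT))
    return(list(tRyr = bestT, tLtcc = inter + slope * bestT,
                method = "costes"))
  NULL
}

#' Manders fractional-overlap coefficients with automatic thresholds
#'
#' Thresholds are generated by the Costes regression procedure (per-channel
#' Otsu is used as fallback when the regression is inapplicable). M1 is the
#' fraction of above-threshold LTCC intensity found at pixels that are also
#' above the RyR threshold; M2 is the symmetric quantity for RyR.
#'
#' On densely labelled, low-background images the regression decorrelates
#' only near background level, giving permissive thresholds; this is the
#' documented behaviour of the procedure, and \code{maxAboveFraction} can
#' optionally force the Otsu fallback when the solution classifies more
#' than that fraction of the ROI as signal.
#'
#' @param pair a \linkS4class{ChannelPair} (typically preprocessed)
#' @param thresholds optional numeric c(tRyr, tLtcc) overriding the
#'   automatic procedure
#' @param maxAboveFraction optional degeneracy guard for the Costes
#'   solution (default Inf: never reject)
#' @return a \linkS4class{MandersResult}
#' @export
mandersMCC <- function(pair, thresholds = NULL, maxAboveFraction = Inf) {
  stopifnot(is(pair, "ChannelPair"))
  roi <- pair@cellRoi
  r <- pair@ryr@pixels[roi]
  l <- pair@ltcc@pixels[roi]
  if (all(r == 0)) stop("RyR channel is all zero inside the ROI")
  if (all(l == 0)) stop("LTCC channel is all zero inside the ROI")
  if (is.null(thresholds)) {
    th <- costesThresholds(r, l)
    # a regression solution that calls most of the ROI "signal" only
    # decorrelated at background level (dense labelling); treat as failed
    if (!is.null(th) &&
        (mean(r > th$tRyr) > maxAboveFraction ||
         mean(l > th$tLtcc) > maxAboveFraction))
      th <- NULL
    if (is.null(th)) {
      th <- list(tRyr = otsuVector(r), tLtcc = otsuVector(l),
                 method = "otsu")
    }
  } else {
    th <- list(tRyr = thresholds[1L], tLtcc = thresholds[2L],
               method = "manual")
  }
  mr <- r > th$tRyr
  ml <- l > th$tLtcc
  denL <- sum(l[ml]); denR <- sum(r[mr])
  m1 <- if (denL > 0) sum(l[ml & mr]) / denL else NA_real_
  m2 <- if (denR > 0) sum(r[mr & ml]) / denR else NA_real_
  new("MandersResult", m1 = m1, m2 = m2, tRyr = th$tRyr, tLtcc = th$tLtcc,
      method = th$method)
}

#' Transverse and longitudinal territory masks from the RyR channel
#'
#' The RyR channel is background-subtracted, contrast-enhanced,
#' ridge-filtered, binarized (Otsu), closed (to merge beaded cluster rows
#' into lines) and skeletonized; branches are labelled with the 45-degree
#' rule. The transverse skeleton is then convolved with a vertical line
#' kernel (17 x 1) and a horizontal line kernel (1 x 13) and binarized at
#' > 0 - a controlled dilation fusing skeleton pixels into the transverse
#' territory. The single transverse mask isolates the fluorescence in
#' either direction: inside it the signal is transverse, and the
#' longitudinal compartment is its complement within the cell ROI (with
#' \code{longitudinal = "skeleton"} a per-skeleton longitudinal band with
#' the kernel roles swapped is returned instead). Kernel sizes are in
#' pixels at Airyscan sampling (34-71 nm) and should be rescaled for other
#' pixel sizes.
#'
#' @param ryr RyR \linkS4class{Image2D}
#' @param cellRoi logical matrix; masks are restricted to it
#' @param kernel1Px,kernel2Px line-kernel lengths (defaults 17 and 13)
#' @param closingUm radius of the pre-skeletonization closing (default
#'   0.5 um: bridges single missing clusters at typical 0.6 um pitch
#'   without merging neighbouring Z-lines at 1.8 um)
#' @param backgroundRadiusPx rolling-ball radius (default 20)
#' @param longitudinal "complement" (default): everything in the ROI
#'   outside the transverse territory; "skeleton": a band around the
#'   longitudinal skeleton
#' @return list with logical matrices \code{transverse} and
#'   \code{longitudinal}, plus the labelled \code{skeleton}
#' @export
orientationMasks <- function(ryr, cellRoi, kernel1Px = 17L, kernel2Px = 13L,
                             closingUm = 0.5, backgroundRadiusPx = 20,
                             longitudinal = c("complement", "skeleton")) {
  longitudinal <- match.arg(longitudinal)
  stopifnot(is(ryr, "Image2D"))
  proc <- subtractBackground(ryr, backgroundRadiusPx)
  px <- proc@pixels; px[!cellRoi] <- 0
  proc <- enhanceContrast(image2d(px, ryr@pixelSizeUm), 0.8)
  proc <- mexicanHat(proc, 3)
  proc <- medianDisk(proc, 1)
  if (min(proc@pixels) == max(proc@pixels))
    return(list(transverse = cellRoi & FALSE, longitudinal = cellRoi & FALSE,
                skeleton = NULL))
  mask <- otsuThreshold(proc)$mask & cellRoi
  mask <- binClose(mask, max(1L, round(closingUm / ryr@pixelSizeUm)))
  if (!any(mask))
    return(list(transverse = mask, longitudinal = mask, skeleton = NULL))
  sk <- skeletonizeNetwork(mask, pixelSizeUm = ryr@pixelSizeUm)
  dilateLines <- function(m, vLen, hLen) {
    if (!any(m)) return(m)
    m <- as.matrix(EBImage::dilate(m * 1, matrix(1, as.integer(vLen), 1L)))
    m <- as.matrix(EBImage::dilate(m, matrix(1, 1L, as.integer(hLen))))
    (m > 0.5) & cellRoi
  }
  skelOf <- function(lbl) {
    ids <- sk@branches$branch[sk@branches$label == lbl]
    m <- matrix(sk@branchMap %in% ids, nrow(sk@branchMap))
    m & sk@branchMap > 0
  }
  trans <- dilateLines(skelOf("transverse"), kernel1Px, kernel2Px)
  long <- if (longitudinal == "complement") {
    cellRoi & !trans
  } else {
    dilateLines(skelOf("longitudinal"), kernel2Px, kernel1Px) & !trans
  }
  list(transverse = trans, longitudinal = long, skeleton = sk)
}

#' Orientation-specific Manders coefficients
#'
#' Multiplies both channels by the orientation territory mask and reruns
#' \code{\link{mandersMCC}} on the masked pair.
#'
#' By default the cell-wide automatic thresholds of the unmasked pair are
#' reused, so that "signal" means the same thing in both compartments and
#' the per-orientation fractions are comparable; thresholding a single
#' signal-poor compartment would drift towards its background.
#'
#' @param pair a preprocessed \linkS4class{ChannelPair}
#' @param masks output of \code{\link{orientationMasks}}
#' @param orientation "transverse" or "longitudinal"
#' @param thresholds numeric c(tRyr, tLtcc); NULL recomputes them from the
#'   whole (unmasked) pair
#' @return a \linkS4class{MandersResult}, or NULL (with a warning) when the
#'   requested mask is empty
#' @export
orientationMCC <- function(pair, masks,
                           orientation = c("transverse", "longitudinal"),
                           thresholds = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(thresholds)) {
    whole <- mandersMCC(pair)
    thresholds <- c(whole@tRyr, whole@tLtcc)
  }
  m <- masks[[orientation]]
  if (is.null(m) || !any(m)) {
    warning("empty ", orientation, " mask: orientation skipped")
    return(NULL)
  }
  maskImg <- function(img) {
    px <- img@pixels
    px[!m] <- 0
    image2d(px, img@pixelSizeUm, img@channelName)
  }
  sub <- channelPair(maskImg(pair@ryr), maskImg(pair@ltcc),
                     pair@cellRoi & m, pair@nucleusMask & m)
  mandersMCC(sub, thresholds = thresholds)
}

#' Nucleus-excluded protein density
#'
#' Percentage of the (cell ROI minus nucleus) area above threshold. The
#' threshold defaults to Otsu over the ROI pixels; pass the automatically
#' generated Manders threshold to reproduce a matched density/overlap
#' analysis.
#'
#' @param img single-channel \linkS4class{Image2D}
#' @param cellRoi logical matrix
#' @param nucleusMask optional logical matrix of excluded nuclei
#' @param threshold optional fixed threshold; pixels strictly above count
#' @return density in percent
#' @export
proteinDensity <- function(img, cellRoi, nucleusMask = NULL,
                           threshold = NULL) {
  stopifnot(is(img, "Image2D"))
  if (is.null(nucleusMask))
    nucleusMask <- matrix(FALSE, nrow(cellRoi), ncol(cellRoi))
  denom <- cellRoi & !nucleusMask
  if (!any(denom)) stop("cell ROI minus nucleus is empty")
  v <- img@pixels[denom]
  if (is.null(threshold)) {
    if (min(v) == max(v)) return(if (max(v) > 0) 100 else 0)
    threshold <- otsuVector(v)
  }
  100 * sum(v > threshold) / length(v)
}

#' Dyadic density
#'
#' The density of intact dyads: LTCC %-area density multiplied by the
#' Manders fraction of LTCC containing RyR (M1). Units: percent cell area.
#'
#' @param ltccDensityPercent LTCC density in percent
#' @param m1 fraction of LTCC colocalized with RyR, in [0, 1]
#' @return dyadic density in percent
#' @export
dyadicDensity <- function(ltccDensityPercent, m1) {
  stopifnot(ltccDensityPercent >= 0, ltccDensityPercent <= 100,
            m1 >= 0, m1 <= 1)
  ltccDensityPercent * m1
}

#' Whole-cell dyadic metrics
#'
#' Convenience wrapper: preprocesses the pair, computes Manders
#' coefficients, nucleus-excluded densities at the automatic thresholds,
#' the dyadic density, and per-orientation M1 values.
#'
#' @param pair a raw \linkS4class{ChannelPair}
#' @param ... passed to \code{\link{orientationMasks}}
#' @return a \linkS4class{DyadMetrics}
#' @export
dyadMetrics <- function(pair, ...) {
  prep <- preprocessPair(pair)
  mcc <- mandersMCC(prep)
  ltccD <- proteinDensity(prep@ltcc, prep@cellRoi, prep@nucleusMask,
                          threshold = mcc@tLtcc)
  ryrD <- proteinDensity(prep@ryr, prep@cellRoi, prep@nucleusMask,
                         threshold = mcc@tRyr)
  masks <- orientationMasks(prep@ryr, prep@cellRoi, ...)
  thr <- c(mcc@tRyr, mcc@tLtcc)
  m1t <- m1l <- NA_real_
  mt <- tryCatch(orientationMCC(prep, masks, "transverse", thresholds = thr),
                 warning = function(w) NULL)
  if (!is.null(mt)) m1t <- mt@m1
  ml <- tryCatch(orientationMCC(prep, masks, "longitudinal",
                                thresholds = thr),
                 warning = function(w) NULL)
  if (!is.null(ml)) m1l <- ml@m1
  new("DyadMetrics", ltccDensityPercent = ltccD, ryrDensityPercent = ryrD,
      dyadicDensityPercent = dyadicDensity(ltccD, mcc@m1), m1 = mcc@m1,
      m1Transverse = m1t, m1Longitudinal = m1l)
}

#' Distances from RyR pixels to the nearest LTCC pixel
#'
#' Euclidean distance transform of the above-threshold LTCC mask evaluated
#' at every above-threshold RyR pixel, scaled to micrometres. Also reports
#' the "orphaned fraction": the share of RyR pixels farther than
#' \code{orphanCutoffUm} from any LTCC. Positional analysis needs
#' object-level masks, so the default thresholds are per-channel Otsu over
#' the ROI (the permissive Costes overlap thresholds admit scattered
#' background pixels that erase the distance structure).
#'
#' @param pair a preprocessed \linkS4class{ChannelPair}
#' @param thresholds optional c(tRyr, tLtcc); default: per-channel Otsu
#'   over the ROI pixels
#' @param binWidthUm histogram bin width (default 0.1 um)
#' @param orphanCutoffUm orphaned-RyR cutoff (default 0.5 um)
#' @return list with \code{distancesUm}, \code{coords} (x, y pixel
#'   positions), \code{binEdgesUm}, \code{counts}, \code{orphanedFraction},
#'   and \code{flag} ("all-infinite" when the LTCC mask is empty)
#' @export
nearestLtccDistances <- function(pair, thresholds = NULL, binWidthUm = 0.1,
                                 orphanCutoffUm = 0.5) {
  stopifnot(is(pair, "ChannelPair"))
  roi <- pair@cellRoi
  if (is.null(thresholds)) {
    thresholds <- c(otsuVector(pair@ryr@pixels[roi]),
                    otsuVector(pair@ltcc@pixels[roi]))
  }
  ryrMask <- pair@ryr@pixels > thresholds[1L] & roi
  ltccMask <- pair@ltcc@pixels > thresholds[2L] & roi
  if (!any(ryrMask)) stop("no above-threshold RyR pixels")
  ps <- pair@ryr@pixelSizeUm
  pos <- which(ryrMask, arr.ind = TRUE)
  if (!any(ltccMask)) {
    d <- rep(Inf, nrow(pos))
    return(list(distancesUm = d,
                coords = data.frame(x = pos[, 2L], y = pos[, 1L]),
                binEdgesUm = numeric(0), counts = integer(0),
                orphanedFraction = 1, flag = "all-infinite"))
  }
  dmap <- distanceToMask(ltccMask) * ps
  d <- dmap[ryrMask]
  edges <- seq(0, max(d) + binWidthUm, by = binWidthUm)
  counts <- graphicsFreeHist(d, edges)
  list(distancesUm = d,
       coords = data.frame(x = pos[, 2L], y = pos[, 1L]),
       binEdgesUm = edges, counts = counts,
       orphanedFraction = mean(d > orphanCutoffUm), flag = "")
}

# histogram counts over [edges[i], edges[i+1]) without plotting machinery
graphicsFreeHist <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[b < 1L] <- 1L
  nb <- length(edges) - 1L
  b[b > nb] <- nb
  tabulate(b, nb)
}
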