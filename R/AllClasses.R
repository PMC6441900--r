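#' @import methods
NULL

#' Calibrated 2D fluorescence micrograph
#'
#' Container for a single-channel raster image with physical pixel
#' calibration. Pixel values are stored as a numeric matrix whose rows run
#' top to bottom (y) and whose columns run left to right (x).
#'
#' @slot pixels numeric matrix of non-negative intensities (H x W, H, W >= 16)
#' @slot pixelSizeUm physical pixel size in micrometres (> 0)
#' @slot channelName free-text channel label
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSizeUm = "numeric",
                 channelName = "character"),
  prototype(pixelSizeUm = 1, channelName = ""))

setValidity("Image2D", function(object) {
  px <- object@pixels
  if (nrow(px) < 16L || ncol(px) < 16L)
    return("image must be at least 16 x 16 pixels")
  if (!all(is.finite(px)))
    return("all intensities must be finite")
  if (any(px < 0))
    return("all intensities must be >= 0")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' Calibrated time-lapse stack
#'
#' @slot frames numeric array H x W x T (T >= 3) of non-negative intensities
#' @slot frameIntervalMs frame interval in milliseconds (> 0)
#' @slot pixelSizeUm physical pixel size in micrometres (> 0)
#' @export
setClass("VideoStack",
  representation(frames = "array", frameIntervalMs = "numeric",
                 pixelSizeUm = "numeric"),
  prototype(frameIntervalMs = 1, pixelSizeUm = 1))

setValidity("VideoStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (d[3L] < 3L) return("a video needs at least 3 frames")
  if (!all(is.finite(object@frames))) return("all intensities must be finite")
  if (any(object@frames < 0)) return("all intensities must be >= 0")
  if (object@frameIntervalMs <= 0) return("frameIntervalMs must be > 0")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  TRUE
})

#' Cell footprint geometry after long-axis alignment
#'
#' @slot footprint logical matrix marking the whole-cell footprint
#' @slot principalAxisDeg orientation of the cell long axis in the original
#'   image, degrees counterclockwise from horizontal, in (-90, 90]
#' @slot interiorRoi logical matrix, the footprint eroded inward from the
#'   sarcolemma (analysis region "just inside the surface membrane")
#' @slot roiMarginUm inward erosion margin in micrometres
#' @slot pixelSizeUm micrometres per pixel
#' @export
setClass("CellGeometry",
  representation(footprint = "matrix", principalAxisDeg = "numeric",
                 interiorRoi = "matrix", roiMarginUm = "numeric",
                 pixelSizeUm = "numeric"))

setValidity("CellGeometry", function(object) {
  if (!identical(dim(object@footprint), dim(object@interiorRoi)))
    return("footprint and interiorRoi must have identical shape")
  if (any(object@interiorRoi & !object@footprint))
    return("interiorRoi must be contained in the footprint")
  a <- object@principalAxisDeg
  if (!(a > -90 && a <= 90)) return("principalAxisDeg must lie in (-90, 90]")
  TRUE
})

#' Segmented t-tubule network
#'
#' @slot mask logical matrix of tubule pixels (restricted to the footprint)
#' @slot geometry a \linkS4class{CellGeometry} in the same (rotated) frame
#' @slot pixelSizeUm micrometres per pixel
#' @export
setClass("SegmentedTubules",
  representation(mask = "matrix", geometry = "CellGeometry",
                 pixelSizeUm = "numeric"))

setValidity("SegmentedTubules", function(object) {
  if (!identical(dim(object@mask), dim(object@geometry@footprint)))
    return("mask shape must match the geometry footprint")
  TRUE
})

#' One-pixel-wide tubule skeleton with labelled branches
#'
#' Junction pixels (>= 3 skeleton neighbours) belong to no branch and are
#' counted separately; every other skeleton pixel belongs to exactly one
#' branch. Branch orientation is the principal direction of the pixel path
#' in degrees from horizontal (y up), in (-90, 90]. A branch is labelled
#' \code{"transverse"} when its absolute angle to the image vertical is
#' <= 45 degrees (it runs across the horizontally aligned cell), else
#' \code{"longitudinal"}.
#'
#' @slot mask logical matrix of all skeleton pixels
#' @slot branchMap integer matrix: 0 background, -1 junction, else branch id
#' @slot branches data.frame with columns branch, label, orientationDeg,
#'   lengthUm, nPixels
#' @slot junctionCount number of junction pixels
#' @slot pixelSizeUm micrometres per pixel
#' @export
setClass("TubuleSkeleton",
  representation(mask = "matrix", branchMap = "matrix",
                 branches = "data.frame", junctionCount = "integer",
                 pixelSizeUm = "numeric"))

#' T-tubule morphometry summary
#'
#' @slot densityPercent percentage of the interior ROI covered by tubules
#' @slot transverseFraction fraction of skeleton length in transverse branches
#' @slot longitudinalFraction complement of \code{transverseFraction}
#' @slot skeletonLengthUm total branch path length in micrometres
#' @slot junctionCount number of junction pixels (not in any branch)
#' @export
setClass("TubuleMetrics",
  representation(densityPercent = "numeric", transverseFraction = "numeric",
                 longitudinalFraction = "numeric", skeletonLengthUm = "numeric",
                 junctionCount = "integer"))

#' Aligned two-channel immunolabel pair
#'
#' @slot ryr RyR channel \linkS4class{Image2D}
#' @slot ltcc LTCC (or other partner) channel, same shape and calibration
#' @slot cellRoi logical matrix marking the cell interior
#' @slot nucleusMask logical matrix of excluded nuclei (subset of cellRoi;
#'   all-FALSE when absent)
#' @export
setClass("ChannelPair",
  representation(ryr = "Image2D", ltcc = "Image2D",
                 cellRoi = "matrix", nucleusMask = "matrix"))

setValidity("ChannelPair", function(object) {
  if (!identical(dim(object@ryr@pixels), dim(object@ltcc@pixels)))
    return("channels must have identical shapes")
  if (object@ryr@pixelSizeUm != object@ltcc@pixelSizeUm)
    return("channels must share the same pixel size")
  if (!identical(dim(object@cellRoi), dim(object@ryr@pixels)))
    return("cellRoi shape must match the channels")
  if (!identical(dim(object@nucleusMask), dim(object@cellRoi)))
    return("nucleusMask shape must match cellRoi")
  if (any(object@nucleusMask & !object@cellRoi))
    return("nucleusMask must be contained in cellRoi")
  TRUE
})

#' Manders fractional-overlap result
#'
#' @slot m1 fraction of LTCC signal overlapping above-threshold RyR
#' @slot m2 fraction of RyR signal overlapping above-threshold LTCC
#' @slot tRyr,tLtcc automatic per-channel thresholds
#' @slot method "costes" or "otsu" (fallback)
#' @export
setClass("MandersResult",
  representation(m1 = "numeric", m2 = "numeric", tRyr = "numeric",
                 tLtcc = "numeric", method = "character"))

setValidity("MandersResult", function(object) {
  if (is.finite(object@m1) && (object@m1 < 0 || object@m1 > 1))
    return("m1 must lie in [0, 1]")
  if (is.finite(object@m2) && (object@m2 < 0 || object@m2 > 1))
    return("m2 must lie in [0, 1]")
  TRUE
})

#' Dyadic organization metrics
#'
#' \code{dyadicDensityPercent} is exactly
#' \code{ltccDensityPercent * m1} (the fraction of LTCC colocalized with
#' RyR), in units of percent cell area.
#'
#' @slot ltccDensityPercent,ryrDensityPercent nucleus-excluded %-area densities
#' @slot dyadicDensityPercent LTCC density x M1
#' @slot m1 whole-cell fraction of LTCC containing RyR
#' @slot m1Transverse,m1Longitudinal per-orientation M1 (NA when a mask is empty)
#' @export
setClass("DyadMetrics",
  representation(ltccDensityPercent = "numeric", ryrDensityPercent = "numeric",
                 dyadicDensityPercent = "numeric", m1 = "numeric",
                 m1Transverse = "numeric", m1Longitudinal = "numeric"))

#' Global calcium-transient kinetics
#'
#' @slot stimulusFrame index of the stimulus frame
#' @slot timeToPeakMs time from stimulus to the trace maximum
#' @slot f50Level intensity halfway between baseline and peak
#' @slot tf50Ms time from stimulus to the F50 crossing (linear interpolation)
#' @slot riseOnsetMs time from stimulus to the detected start of the global
#'   rise (sustained excursion above baseline + 2 SD)
#' @slot flag "" when valid, otherwise a reason the kinetics are undefined
#' @export
setClass("GlobalKinetics",
  representation(stimulusFrame = "integer", timeToPeakMs = "numeric",
                 f50Level = "numeric", tf50Ms = "numeric",
                 riseOnsetMs = "numeric", flag = "character"))

#' Dyssynchrony map of per-pixel time to half-maximal fluorescence
#'
#' @slot tf50Map matrix of per-pixel times (ms) to the pixel's own
#'   half-maximal level; NA outside the ROI or where no crossing occurred
#' @slot diMs dyssynchrony index: dispersion (population SD by default) of
#'   the valid per-pixel times
#' @slot statistic "sd" or "iqr"
#' @slot nValid,nExcluded pixel counts with/without a valid crossing
#' @slot flag "" or "unreliable" (more than half the ROI had no crossing)
#' @export
setClass("DIMap",
  representation(tf50Map = "matrix", diMs = "numeric", statistic = "character",
                 nValid = "integer", nExcluded = "integer", flag = "character"))

#' T-tubule electrical-activation result
#'
#' @slot fractionDepolarized fraction of analysable skeleton pixels whose
#'   normalized voltage-dye signal rose above threshold
#' @slot aboveMask logical matrix (subset of the skeleton mask)
#' @slot contractionFrame frame index used as the contraction onset
#' @slot framesUsed the three pre-contraction frame indices
#' @slot nExcluded skeleton pixels excluded for zero-valued F0
#' @slot flag "" | "no-signal" | "many-excluded"
#' @export
setClass("DepolarizationResult",
  representation(fractionDepolarized = "numeric", aboveMask = "matrix",
                 contractionFrame = "integer", framesUsed = "integer",
                 nExcluded = "integer", flag = "character"))

#' Surface-topography indices from Z-spine annotations
#'
#' @slot zGrooveIndex total crest length / total Z-spine length, in [0, 1]
#' @slot tTubuleOpeningFraction share of Z-spines with a visible tubule lumen
#' @slot nSpines number of annotated Z-spines
#' @export
setClass("TopographyMetrics",
  representation(zGrooveIndex = "numeric", tTubuleOpeningFraction = "numeric",
                 nSpines = "integer"))

setValidity("TopographyMetrics", function(object) {
  if (object@zGrooveIndex < 0 || object@zGrooveIndex > 1)
    return("zGrooveIndex must lie in [0, 1]")
  if (object@tTubuleOpeningFraction < 0 || object@tTubuleOpeningFraction > 1)
    return("tTubuleOpeningFraction must lie in [0, 1]")
  if (object@nSpines < 1L) return("nSpines must be >= 1")
  TRUE
})
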