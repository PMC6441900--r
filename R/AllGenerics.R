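# Accessor generics and show methods.

#' @rdname accessors
#' @param x an object
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("frameIntervalMs", function(x) standardGeneric("frameIntervalMs"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("footprint", function(x) standardGeneric("footprint"))
#' @rdname accessors
#' @export
setGeneric("interiorRoi", function(x) standardGeneric("interiorRoi"))
#' @rdname accessors
#' @export
setGeneric("principalAxisDeg", function(x) standardGeneric("principalAxisDeg"))
#' @rdname accessors
#' @export
setGeneric("tubuleMask", function(x) standardGeneric("tubuleMask"))
#' @rdname accessors
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @rdname accessors
#' @export
setGeneric("densityPercent", function(x) standardGeneric("densityPercent"))
#' @rdname accessors
#' @export
setGeneric("transverseFraction", function(x) standardGeneric("transverseFraction"))
#' @rdname accessors
#' @export
setGeneric("longitudinalFraction", function(x) standardGeneric("longitudinalFraction"))
#' @rdname accessors
#' @export
setGeneric("skeletonLengthUm", function(x) standardGeneric("skeletonLengthUm"))
#' @rdname accessors
#' @export
setGeneric("m1", function(x) standardGeneric("m1"))
#' @rdname accessors
#' @export
setGeneric("m2", function(x) standardGeneric("m2"))
#' @rdname accessors
#' @export
setGeneric("dyadicDensityPercent", function(x) standardGeneric("dyadicDensityPercent"))
#' @rdname accessors
#' @export
setGeneric("diMs", function(x) standardGeneric("diMs"))
#' @rdname accessors
#' @export
setGeneric("tf50Map", function(x) standardGeneric("tf50Map"))
#' @rdname accessors
#' @export
setGeneric("fractionDepolarized", function(x) standardGeneric("fractionDepolarized"))
#' @rdname accessors
#' @export
setGeneric("zGrooveIndex", function(x) standardGeneric("zGrooveIndex"))
#' @rdname accessors
#' @export
setGeneric("tTubuleOpeningFraction", function(x) standardGeneric("tTubuleOpeningFraction"))

#' Accessors for dyadscape result objects
#'
#' Small typed accessors in place of direct slot access.
#'
#' @name accessors
#' @return the corresponding slot value
NULL

#' @rdname accessors
setMethod("pixels", "Image2D", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "VideoStack", function(x) x@frames)
#' @rdname accessors
setMethod("pixelSizeUm", "Image2D", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "VideoStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "CellGeometry", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "SegmentedTubules", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "TubuleSkeleton", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("frameIntervalMs", "VideoStack", function(x) x@frameIntervalMs)
#' @rdname accessors
setMethod("nFrames", "VideoStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("footprint", "CellGeometry", function(x) x@footprint)
#' @rdname accessors
setMethod("footprint", "SegmentedTubules", function(x) x@geometry@footprint)
#' @rdname accessors
setMethod("interiorRoi", "CellGeometry", function(x) x@interiorRoi)
#' @rdname accessors
setMethod("interiorRoi", "SegmentedTubules", function(x) x@geometry@interiorRoi)
#' @rdname accessors
setMethod("principalAxisDeg", "CellGeometry", function(x) x@principalAxisDeg)
#' @rdname accessors
setMethod("tubuleMask", "SegmentedTubules", function(x) x@mask)
#' @rdname accessors
setMethod("tubuleMask", "TubuleSkeleton", function(x) x@mask)
#' @rdname accessors
setMethod("branches", "TubuleSkeleton", function(x) x@branches)
#' @rdname accessors
setMethod("densityPercent", "TubuleMetrics", function(x) x@densityPercent)
#' @rdname accessors
setMethod("transverseFraction", "TubuleMetrics", function(x) x@transverseFraction)
#' @rdname accessors
setMethod("longitudinalFraction", "TubuleMetrics", function(x) x@longitudinalFraction)
#' @rdname accessors
setMethod("skeletonLengthUm", "TubuleMetrics", function(x) x@skeletonLengthUm)
#' @rdname accessors
setMethod("m1", "MandersResult", function(x) x@m1)
#' @rdname accessors
setMethod("m2", "MandersResult", function(x) x@m2)
#' @rdname accessors
setMethod("m1", "DyadMetrics", function(x) x@m1)
#' @rdname accessors
setMethod("dyadicDensityPercent", "DyadMetrics", function(x) x@dyadicDensityPercent)
#' @rdname accessors
setMethod("diMs", "DIMap", function(x) x@diMs)
#' @rdname accessors
setMethod("tf50Map", "DIMap", function(x) x@tf50Map)
#' @rdname accessors
setMethod("fractionDepolarized", "DepolarizationResult",
          function(x) x@fractionDepolarized)
#' @rdname accessors
setMethod("zGrooveIndex", "TopographyMetrics", function(x) x@zGrooveIndex)
#' @rdname accessors
setMethod("tTubuleOpeningFraction", "TopographyMetrics",
          function(x) x@tTubuleOpeningFraction)

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D %d x %d px (%.3f um/px)%s\n", d[1L], d[2L],
              object@pixelSizeUm,
              if (nzchar(object@channelName))
                paste0(", channel '", object@channelName, "'") else ""))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "VideoStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoStack %d x %d px, %d frames (%.3f um/px, %.2f ms/frame)\n",
              d[1L], d[2L], d[3L], object@pixelSizeUm, object@frameIntervalMs))
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry: footprint %d px, interior ROI %d px, long axis %.2f deg\n",
    sum(object@footprint), sum(object@interiorRoi), object@principalAxisDeg))
})

setMethod("show", "SegmentedTubules", function(object) {
  cat(sprintf("SegmentedTubules: %d tubule px in a %d px footprint\n",
              sum(object@mask), sum(object@geometry@footprint)))
})

setMethod("show", "TubuleSkeleton", function(object) {
  b <- object@branches
  cat(sprintf(
    "TubuleSkeleton: %d px, %d branches (%d transverse / %d longitudinal), %d junction px\n",
    sum(object@mask), nrow(b), sum(b$label == "transverse"),
    sum(b$label == "longitudinal"), object@junctionCount))
})

setMethod("show", "TubuleMetrics", function(object) {
  cat(sprintf(
    "TubuleMetrics: density %.1f%%, transverse %.2f / longitudinal %.2f, skeleton %.1f um\n",
    object@densityPercent, object@transverseFraction,
    object@longitudinalFraction, object@skeletonLengthUm))
})

setMethod("show", "ChannelPair", function(object) {
  cat(sprintf("ChannelPair %d x %d px (%.3f um/px), ROI %d px, nucleus %d px\n",
              nrow(object@ryr@pixels), ncol(object@ryr@pixels),
              object@ryr@pixelSizeUm, sum(object@cellRoi),
              sum(object@nucleusMask)))
})

setMethod("show", "MandersResult", function(object) {
  cat(sprintf("MandersResult (%s thresholds %.4g / %.4g): M1 = %.3f, M2 = %.3f\n",
              object@method, object@tRyr, object@tLtcc, object@m1, object@m2))
})

setMethod("show", "DyadMetrics", function(object) {
  cat(sprintf(
    paste0("DyadMetrics: LTCC %.2f%%, RyR %.2f%%, M1 %.3f -> dyadic %.2f%%",
           " (M1 transverse %.3f / longitudinal %.3f)\n"),
    object@ltccDensityPercent, object@ryrDensityPercent, object@m1,
    object@dyadicDensityPercent, object@m1Transverse, object@m1Longitudinal))
})

setMethod("show", "GlobalKinetics", function(object) {
  if (nzchar(object@flag)) {
    cat(sprintf("GlobalKinetics: flagged '%s'\n", object@flag))
  } else {
    cat(sprintf(
      "GlobalKinetics: TTP %.1f ms, TF50 %.1f ms (F50 level %.3g), rise onset %.1f ms\n",
      object@timeToPeakMs, object@tf50Ms, object@f50Level, object@riseOnsetMs))
  }
})

setMethod("show", "DIMap", function(object) {
  cat(sprintf("DIMap: DI = %.2f ms (%s over %d px, %d excluded)%s\n",
              object@diMs, object@statistic, object@nValid, object@nExcluded,
              if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})

setMethod("show", "DepolarizationResult", function(object) {
  cat(sprintf(
    "DepolarizationResult: %.1f%% of tubule skeleton depolarized (frames %s)%s\n",
    100 * object@fractionDepolarized,
    paste(object@framesUsed, collapse = ","),
    if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})

setMethod("show", "TopographyMetrics", function(object) {
  cat(sprintf(
    "TopographyMetrics (%d Z-spines): Z-groove index %.3f, t-tubule openings %.3f\n",
    object@nSpines, object@zGrooveIndex, object@tTubuleOpeningFraction))
})
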