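# Voltage-dye (FluoVolt) analysis: the fraction of the skeletonized
# t-tubule network that is electrically activated during the action
# potential.

#' Detect the cell-contraction frame from a motion metric
#'
#' The motion metric is the mean absolute frame-to-frame difference,
#' normalized by the mean intensity of the earlier frame. The contraction
#' frame is the first frame whose metric exceeds the baseline mean plus
#' 3 x the baseline SD (the first \code{baselineFrames} differences form
#' the baseline). When no frame qualifies the last frame is returned with
#' a warning (all frames usable). Note that a large fluorescence step can
#' also trigger the metric; supply the frame explicitly when the electrical
#' onset precedes contraction.
#'
#' @param video a \linkS4class{VideoStack} with >= 10 frames
#' @param baselineFrames number of initial frame-differences treated as
#'   motion-free baseline (default 5)
#' @param k threshold in baseline SDs (default 3)
#' @return frame index
#' @export
detectContractionFrame <- function(video, baselineFrames = 5L, k = 3) {
  stopifnot(is(video, "VideoStack"))
  d <- dim(video@frames)
  if (d[3L] < 10L) stop("need at least 10 frames")
  met <- vapply(2:d[3L], function(t) {
    prev <- video@frames[, , t - 1L]
    mp <- mean(prev)
    if (mp <= 0) return(0)
    mean(abs(video@frames[, , t] - prev)) / mp
  }, numeric(1))                       # met[i] is the metric at frame i + 1
  nb <- min(baselineFrames, length(met) - 1L)
  base <- met[seq_len(nb)]
  thr <- mean(base) + k * max(stats::sd(base), 1e-12)
  hit <- which(met[(nb + 1L):length(met)] > thr)
  if (length(hit) == 0L) {
    warning("no motion detected; returning the last frame")
    return(d[3L])
  }
  hit[1L] + nb + 1L
}

#' Fraction of the t-tubule skeleton depolarized during the action potential
#'
#' Restricts the three frames preceding \code{contractionFrame} to the
#' skeleton pixels, normalizes each pixel by the first frame of the
#' recording (F/F0), pools the normalized values and thresholds them with
#' the Otsu algorithm. A skeleton pixel counts as depolarized when it is
#' above threshold in at least one of the three frames (\code{rule =
#' "any"}; "all" requires all three). Pixels with non-positive F0 are
#' excluded and counted; more than 20% excluded flags the result.
#'
#' Because F/F0 of a resting pixel is 1 by construction, the Otsu split is
#' calibrated against that anchor: when even the lower class lies clearly
#' above 1 (mean > 1 + 3 SD) the distribution is a unimodal step and the
#' whole skeleton is called depolarized; when even the upper class sits at
#' baseline the result is 0 with a "no-signal" flag (a histogram split
#' would otherwise just halve the noise).
#'
#' @param video a \linkS4class{VideoStack} (voltage dye)
#' @param skeleton a \linkS4class{TubuleSkeleton} or logical skeleton mask
#' @param contractionFrame frame index of contraction onset (>= 4); see
#'   \code{\link{detectContractionFrame}}
#' @param rule "any" (default) or "all": frames above threshold required
#' @return a \linkS4class{DepolarizationResult}
#' @export
depolarizedFraction <- function(video, skeleton, contractionFrame,
                                rule = c("any", "all")) {
  stopifnot(is(video, "VideoStack"))
  rule <- match.arg(rule)
  mask <- if (is(skeleton, "TubuleSkeleton")) skeleton@mask else skeleton
  if (!any(mask)) stop("skeleton is empty")
  contractionFrame <- as.integer(contractionFrame)
  if (contractionFrame < 4L) stop("contractionFrame must be >= 4")
  d <- dim(video@frames)
  if (!identical(dim(mask), d[1:2]))
    stop("skeleton shape must match the frames")
  if (contractionFrame > d[3L]) stop("contractionFrame beyond the video")
  framesUsed <- (contractionFrame - 3L):(contractionFrame - 1L)
  idx <- which(mask)
  f0 <- video@frames[, , 1L][idx]
  ok <- f0 > 0
  nExcluded <- sum(!ok)
  flag <- if (nExcluded > 0.2 * length(idx)) "many-excluded" else ""
  idxOk <- idx[ok]
  norm <- vapply(framesUsed, function(t) video@frames[, , t][idxOk] / f0[ok],
                 numeric(length(idxOk)))       # npix x 3
  norm <- matrix(norm, ncol = 3L)
  pooled <- as.numeric(norm)
  emptyMask <- matrix(FALSE, d[1L], d[2L])
  done <- function(fraction, above, flg) {
    new("DepolarizationResult", fractionDepolarized = fraction,
        aboveMask = above, contractionFrame = contractionFrame,
        framesUsed = as.integer(framesUsed),
        nExcluded = as.integer(nExcluded), flag = flg)
  }
  allMask <- emptyMask; allMask[idxOk] <- TRUE
  if (max(pooled) == min(pooled)) {
    # a degenerate distribution is either a uniform step (all depolarized)
    # or a perfectly static recording
    if (pooled[1L] > 1.02) return(done(1, allMask, flag))
    return(done(0, emptyMask, "no-signal"))
  }
  thr <- otsuVector(pooled)
  # F/F0 of a resting pixel is 1 by construction: calibrate the Otsu split
  # against that anchor. When even the lower class sits clearly above 1 the
  # whole skeleton is depolarized (unimodal stepped distribution, which a
  # histogram split would halve); when even the upper class is at baseline
  # there is no signal to segment.
  lower <- pooled[pooled <= thr]; upper <- pooled[pooled > thr]
  sdl <- if (length(lower) > 1L) stats::sd(lower) else 0
  sdu <- if (length(upper) > 1L) stats::sd(upper) else 0
  if (mean(lower) > 1 + 3 * max(sdl, 1e-6))
    return(done(1, allMask, flag))
  if (mean(upper) <= 1 + 3 * max(sdu, 1e-6))
    return(done(0, emptyMask, "no-signal"))
  aboveCount <- rowSums(norm > thr)
  dep <- if (rule == "any") aboveCount >= 1L else aboveCount == 3L
  above <- emptyMask
  above[idxOk[dep]] <- TRUE
  done(sum(dep) / length(idxOk), above, flag)
}
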