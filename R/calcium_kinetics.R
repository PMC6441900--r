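# Global and local Ca2+ transient analysis of rapid 2D time-lapse stacks.

# start-of-rise of a trace: last frame before the trace sustainably
# (>= persist consecutive frames) exceeds baseline + k * SD(baseline).
riseOnsetFrame <- function(f, stimulusFrame, k = 2, persist = 2L) {
  base <- f[seq_len(stimulusFrame - 1L)]
  thr <- mean(base) + k * stats::sd(base)
  above <- f > thr
  n <- length(f)
  for (t in stimulusFrame:(n - persist + 1L)) {
    if (all(above[t:(t + persist - 1L)])) return(max(t - 1L, 1L))
  }
  NA_integer_
}

#' Global Ca2+ transient and its kinetics
#'
#' The trace is the spatial mean over the ROI per frame; the baseline F0 is
#' the mean of the pre-stimulus frames. The half-maximal level F50 lies
#' halfway between baseline and the post-stimulus peak; crossing times use
#' linear interpolation between frames and are measured from the stimulus
#' frame.
#'
#' @param video a \linkS4class{VideoStack}
#' @param roi logical matrix (cell ROI)
#' @param stimulusFrame index of the stimulus frame (>= 4, so that at least
#'   3 pre-stimulus frames exist)
#' @return list with \code{trace} (data.frame: timeMs, f, fNorm) and
#'   \code{kinetics} (\linkS4class{GlobalKinetics}; flagged when the trace
#'   never crosses F50)
#' @export
globalTransient <- function(video, roi, stimulusFrame) {
  stopifnot(is(video, "VideoStack"))
  stimulusFrame <- as.integer(stimulusFrame)
  if (stimulusFrame < 4L) stop("need at least 3 pre-stimulus frames")
  if (!any(roi)) stop("ROI is empty")
  d <- dim(video@frames)
  if (!identical(dim(roi), d[1:2])) stop("ROI shape must match the frames")
  dt <- video@frameIntervalMs
  mat <- matrix(video@frames, d[1L] * d[2L], d[3L])[which(roi), , drop = FALSE]
  f <- colMeans(mat)
  f0 <- mean(f[seq_len(stimulusFrame - 1L)])
  trace <- data.frame(timeMs = (seq_len(d[3L]) - 1L) * dt, f = f,
                      fNorm = if (f0 > 0) f / f0 else NA_real_)
  post <- stimulusFrame:d[3L]
  peakIdx <- post[which.max(f[post])]
  f50 <- f0 + 0.5 * (f[peakIdx] - f0)
  flag <- ""
  tf50 <- ttp <- onsetMs <- NA_real_
  if (f[peakIdx] <= f0) {
    flag <- "flat-trace"
  } else {
    cr <- firstCrossing(f, f50, from = stimulusFrame)
    if (is.na(cr)) {
      flag <- "no-crossing"
    } else {
      tf50 <- (cr - stimulusFrame) * dt
      ttp <- (peakIdx - stimulusFrame) * dt
      on <- riseOnsetFrame(f, stimulusFrame)
      onsetMs <- if (is.na(on)) 0 else (on - stimulusFrame) * dt
    }
  }
  kin <- new("GlobalKinetics", stimulusFrame = stimulusFrame,
             timeToPeakMs = ttp, f50Level = f50, tf50Ms = tf50,
             riseOnsetMs = onsetMs, flag = flag)
  list(trace = trace, kinetics = kin)
}

# 3x3 box mean of every frame (replicate edges)
smoothFrames3 <- function(frames) {
  d <- dim(frames)
  out <- array(0, d)
  for (t in seq_len(d[3L])) {
    m <- frames[, , t]
    acc <- matrix(0, d[1L], d[2L])
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + shiftMatrix(m, dy, dx, replicate = TRUE)
    out[, , t] <- acc / 9
  }
  out
}

#' Dyssynchrony map of time to half-maximal fluorescence
#'
#' Computes, per ROI pixel (after 3 x 3 spatial smoothing), the baseline,
#' peak, and the linearly interpolated time at which the pixel first
#' reaches its own half-maximal level, measured from the stimulus frame.
#' The dyssynchrony index (DI) is the dispersion of those times over
#' pixels with a valid crossing: the population standard deviation by
#' default, or the interquartile range.
#'
#' @param video a \linkS4class{VideoStack}
#' @param roi logical matrix
#' @param stimulusFrame stimulus frame index (>= 4)
#' @param smooth apply 3 x 3 spatial smoothing first (default TRUE)
#' @param statistic "sd" (population SD, default) or "iqr"
#' @return a \linkS4class{DIMap}; flagged "unreliable" when more than half
#'   of the ROI pixels have no crossing
#' @export
dyssynchronyMap <- function(video, roi, stimulusFrame, smooth = TRUE,
                            statistic = c("sd", "iqr")) {
  stopifnot(is(video, "VideoStack"))
  statistic <- match.arg(statistic)
  stimulusFrame <- as.integer(stimulusFrame)
  if (stimulusFrame < 4L) stop("need at least 3 pre-stimulus frames")
  if (!any(roi)) stop("ROI is empty")
  d <- dim(video@frames)
  dt <- video@frameIntervalMs
  fr <- if (smooth) smoothFrames3(video@frames) else video@frames
  idx <- which(roi)
  mat <- matrix(fr, d[1L] * d[2L], d[3L])[idx, , drop = FALSE]
  npix <- nrow(mat)
  base <- rowMeans(mat[, seq_len(stimulusFrame - 1L), drop = FALSE])
  post <- mat[, stimulusFrame:d[3L], drop = FALSE]
  pk <- post[, 1L]
  for (j in 2:ncol(post)) pk <- pmax(pk, post[, j])
  f50 <- base + 0.5 * (pk - base)
  rising <- pk > base
  above <- post >= f50
  hasCross <- rowSums(above) > 0L & rising
  fi <- max.col(above, ties.method = "first")  # first TRUE where any
  tf50 <- rep(NA_real_, npix)
  ok <- which(hasCross)
  if (length(ok) > 0L) {
    i <- fi[ok]
    cur <- post[cbind(ok, i)]
    prevIdx <- stimulusFrame + i - 2L          # global frame before crossing
    prev <- mat[cbind(ok, prevIdx)]
    frac <- ifelse(cur > prev, (f50[ok] - prev) / (cur - prev), 0)
    frac <- pmin(pmax(frac, 0), 1)
    tf50[ok] <- (i - 2L + frac) * dt
  }
  map <- matrix(NA_real_, d[1L], d[2L])
  map[idx] <- tf50
  nValid <- sum(!is.na(tf50))
  nExcluded <- npix - nValid
  di <- if (nValid > 0L) {
    v <- tf50[!is.na(tf50)]
    if (statistic == "sd") sdPop(v) else stats::IQR(v, type = 7)
  } else NA_real_
  new("DIMap", tf50Map = map, diMs = di, statistic = statistic,
      nValid = as.integer(nValid), nExcluded = as.integer(nExcluded),
      flag = if (nExcluded > npix / 2) "unreliable" else "")
}

#' Classify 1 x 1 um local release sites from a membrane-dye frame
#'
#' Segments and skeletonizes the co-acquired membrane image (without
#' rotation, to stay in register with the video), then centres sites on
#' skeleton pixels of the requested orientation. Orphaned sites are local
#' maxima of the distance-to-skeleton field inside the ROI whose distance
#' exceeds \code{orphanCutoffUm} (release there is fed by propagation, not
#' by a local tubule). Site boxes are squares of \code{boxUm} rounded to an
#' odd pixel count and must lie fully inside the ROI. Site selection is
#' deterministic: evenly spaced along the available candidates.
#'
#' @param tubuleFrame \linkS4class{Image2D} of the membrane dye
#' @param nSites maximum number of sites per category
#' @param categories subset of c("transverse", "longitudinal", "orphaned")
#' @param orphanCutoffUm minimum distance-to-tubule for an orphaned site
#'   (default 1.2 um; half a sarcomere must not qualify)
#' @param boxUm site box side length (default 1 um)
#' @param roi optional logical ROI; defaults to the interior ROI of the
#'   segmentation
#' @return data.frame: x, y (pixels), xUm, yUm, category, distanceUm
#'   (distance to the nearest tubule); attribute \code{halfPx} holds the
#'   half-width of the site box
#' @export
classifyReleaseSites <- function(tubuleFrame, nSites = 10L,
                                 categories = c("transverse", "longitudinal",
                                                "orphaned"),
                                 orphanCutoffUm = 1.2, boxUm = 1,
                                 roi = NULL) {
  stopifnot(is(tubuleFrame, "Image2D"))
  categories <- match.arg(categories, several.ok = TRUE)
  ps <- tubuleFrame@pixelSizeUm
  seg <- segmentTubules(tubuleFrame, rotate = FALSE)
  if (is.null(roi)) roi <- seg@geometry@interiorRoi
  sk <- skeletonizeNetwork(seg)
  boxPx <- oddPixels(boxUm, ps)
  half <- (boxPx - 1L) %/% 2L
  inRoi <- function(pos) {
    apply(pos, 1L, function(p) {
      r0 <- p[1L] - half; r1 <- p[1L] + half
      c0 <- p[2L] - half; c1 <- p[2L] + half
      r0 >= 1L && c0 >= 1L && r1 <= nrow(roi) && c1 <= ncol(roi) &&
        all(roi[r0:r1, c0:c1])
    })
  }
  dmap <- distanceToMask(sk@mask) * ps
  pick <- function(pos, category) {
    if (nrow(pos) == 0L) return(NULL)
    keep <- inRoi(pos)
    pos <- pos[keep, , drop = FALSE]
    if (nrow(pos) == 0L) return(NULL)
    sel <- unique(round(seq(1L, nrow(pos),
                            length.out = min(nSites, nrow(pos)))))
    pos <- pos[sel, , drop = FALSE]
    data.frame(x = pos[, 2L], y = pos[, 1L],
               xUm = (pos[, 2L] - 0.5) * ps, yUm = (pos[, 1L] - 0.5) * ps,
               category = category,
               distanceUm = dmap[pos])
  }
  out <- NULL
  for (cat in categories) {
    if (cat %in% c("transverse", "longitudinal")) {
      ids <- sk@branches$branch[sk@branches$label == cat]
      m <- matrix(sk@branchMap %in% ids, nrow(sk@branchMap)) &
        sk@branchMap > 0
      pos <- which(m, arr.ind = TRUE)
      out <- rbind(out, pick(pos, cat))
    } else {
      isMax <- dmap > orphanCutoffUm & roi
      for (k in seq_len(8L)) {
        isMax <- isMax &
          dmap >= shiftMatrix(dmap, NEIGH8[k, 1L], NEIGH8[k, 2L],
                              fill = -Inf)
      }
      pos <- which(isMax, arr.ind = TRUE)
      if (nrow(pos) > 0L) {
        # greedy selection by decreasing distance with 1 um separation
        ordI <- order(-dmap[pos])
        pos <- pos[ordI, , drop = FALSE]
        keep <- rep(TRUE, nrow(pos))
        minSep <- 1 / ps
        for (i in seq_len(nrow(pos))) {
          if (!keep[i]) next
          if (i < nrow(pos)) {
            j <- (i + 1L):nrow(pos)
            dd <- sqrt((pos[j, 1L] - pos[i, 1L])^2 +
                       (pos[j, 2L] - pos[i, 2L])^2)
            keep[j[dd < minSep]] <- FALSE
          }
        }
        pos <- pos[keep, , drop = FALSE]
      }
      out <- rbind(out, pick(pos, "orphaned"))
    }
  }
  if (is.null(out))
    out <- data.frame(x = integer(0), y = integer(0), xUm = numeric(0),
                      yUm = numeric(0), category = character(0),
                      distanceUm = numeric(0))
  attr(out, "halfPx") <- half
  attr(out, "skeleton") <- sk
  out
}

#' Local transient timing (TTF50) of a 1 x 1 um site
#'
#' The local trace is the mean over the site box per frame. TTF50 is the
#' time from the start of the Ca2+ rise to the frame (linearly
#' interpolated) at which the local trace reaches the half-maximal level
#' F50 of the overall (global) transient. With \code{reference = "global"}
#' (default) the start of rise is that of the global transient, so a site
#' whose release is delayed by d ms reports a TTF50 longer by d; with
#' \code{reference = "local"} the site's own rise onset is used.
#'
#' @param video a \linkS4class{VideoStack}
#' @param site one row of \code{\link{classifyReleaseSites}} output (or any
#'   list with x, y in pixels)
#' @param global \linkS4class{GlobalKinetics} from
#'   \code{\link{globalTransient}}
#' @param halfPx half-width of the site box in pixels
#' @param reference "global" or "local" rise onset
#' @return list with \code{ttf50Ms} (NA when flagged), \code{onsetMs},
#'   \code{flag} ("non-responding" when the local trace never reaches the
#'   global F50 level)
#' @export
localTtf50 <- function(video, site, global, halfPx,
                       reference = c("global", "local")) {
  stopifnot(is(video, "VideoStack"), is(global, "GlobalKinetics"))
  reference <- match.arg(reference)
  if (nzchar(global@flag)) stop("global kinetics are flagged: ", global@flag)
  d <- dim(video@frames)
  r0 <- site$y - halfPx; r1 <- site$y + halfPx
  c0 <- site$x - halfPx; c1 <- site$x + halfPx
  if (r0 < 1L || c0 < 1L || r1 > d[1L] || c1 > d[2L])
    stop("site box extends beyond the frame")
  f <- apply(video@frames[r0:r1, c0:c1, , drop = FALSE], 3L, mean)
  dt <- video@frameIntervalMs
  stim <- global@stimulusFrame
  cr <- firstCrossing(f, global@f50Level, from = stim)
  if (is.na(cr))
    return(list(ttf50Ms = NA_real_, onsetMs = NA_real_,
                flag = "non-responding"))
  crossMs <- (cr - stim) * dt
  onLocal <- riseOnsetFrame(f, stim)
  onsetMs <- if (is.na(onLocal)) 0 else (onLocal - stim) * dt
  refMs <- if (reference == "global") global@riseOnsetMs else onsetMs
  list(ttf50Ms = max(crossMs - refMs, 0), onsetMs = onsetMs, flag = "")
}
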