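# The t-tubule macro: segmentation, density, skeletonization, and
# transverse/longitudinal decomposition of the skeleton.

#' Segment the t-tubule network of a membrane-dye image
#'
#' Applies, in order: rolling-ball background subtraction (radius 15 px),
#' rotation of the cell long axis to horizontal, contrast enhancement with
#' 0.8% saturated pixels, Mexican-hat filtering (radius 3 px), median
#' filtering (radius 1 px), and Otsu thresholding. The resulting mask is
#' restricted to the cell footprint.
#'
#' @param img single-channel \linkS4class{Image2D} of a membrane stain
#' @param backgroundRadiusPx rolling-ball radius (default 15)
#' @param saturatedPercent contrast saturation (default 0.8)
#' @param hatRadiusPx Mexican-hat radius (default 3)
#' @param medianRadiusPx median-filter radius (default 1)
#' @param roiMarginUm interior-ROI margin (default 1 um)
#' @param rotate set FALSE for images already aligned with the cell long
#'   axis horizontal (e.g. co-acquired video frames that must stay in
#'   register); the footprint is still computed
#' @return a \linkS4class{SegmentedTubules}
#' @export
segmentTubules <- function(img, backgroundRadiusPx = 15,
                           saturatedPercent = 0.8, hatRadiusPx = 3,
                           medianRadiusPx = 1, roiMarginUm = 1,
                           rotate = TRUE) {
  stopifnot(is(img, "Image2D"))
  bg <- subtractBackground(img, backgroundRadiusPx)
  if (rotate) {
    rt <- rotateToHorizontal(bg, roiMarginUm = roiMarginUm)
  } else {
    ot <- otsuThreshold(bg)
    if (!any(ot$mask)) stop("no foreground after Otsu thresholding")
    fp <- fillHoles(largestComponent(ot$mask))
    marginPx <- as.integer(ceiling(roiMarginUm / img@pixelSizeUm))
    geom <- new("CellGeometry", footprint = fp,
                principalAxisDeg = maskOrientationDeg(fp),
                interiorRoi = binErode(fp, marginPx),
                roiMarginUm = roiMarginUm, pixelSizeUm = img@pixelSizeUm)
    rt <- list(image = bg, geometry = geom)
  }
  enh <- enhanceContrast(rt$image, saturatedPercent)
  hat <- mexicanHat(enh, hatRadiusPx)
  med <- medianDisk(hat, medianRadiusPx)
  px <- med@pixels
  mask <- if (min(px) == max(px)) px > 0 else otsuThreshold(med)$mask
  new("SegmentedTubules", mask = mask & rt$geometry@footprint,
      geometry = rt$geometry, pixelSizeUm = img@pixelSizeUm)
}

#' T-tubule density inside the interior ROI
#'
#' Percentage of the interior-ROI area (traced just inside the surface
#' sarcolemma) covered by the tubule mask.
#'
#' @param seg a \linkS4class{SegmentedTubules}
#' @return density in percent
#' @export
tubuleDensity <- function(seg) {
  stopifnot(is(seg, "SegmentedTubules"))
  roi <- seg@geometry@interiorRoi
  if (!any(roi)) stop("interior ROI is empty")
  100 * sum(seg@mask & roi) / sum(roi)
}

# One pass (two subiterations) of Zhang-Suen thinning; returns the matrix
# and whether anything changed.
zhangSuenPass <- function(M) {
  changed <- FALSE
  for (step in 1:2) {
    P <- lapply(seq_len(8L), function(k)
      shiftMatrix(M, NEIGH8[k, 1L], NEIGH8[k, 2L]))
    B <- Reduce(`+`, P)
    seqIdx <- c(1:8, 1)
    A <- Reduce(`+`, lapply(seq_len(8L), function(i)
      (P[[seqIdx[i]]] == 0) * (P[[seqIdx[i + 1]]] == 1)))
    if (step == 1L) {
      c1 <- P[[1]] * P[[3]] * P[[5]] == 0    # P2 * P4 * P6
      c2 <- P[[3]] * P[[5]] * P[[7]] == 0    # P4 * P6 * P8
    } else {
      c1 <- P[[1]] * P[[3]] * P[[7]] == 0    # P2 * P4 * P8
      c2 <- P[[1]] * P[[5]] * P[[7]] == 0    # P2 * P6 * P8
    }
    del <- M == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
    if (any(del)) {
      M[del] <- 0
      changed <- TRUE
    }
  }
  list(M = M, changed = changed)
}

# Topology-preserving thinning of a logical mask to (approximately)
# one-pixel width.
thinMask <- function(mask) {
  M <- mask * 1
  repeat {
    r <- zhangSuenPass(M)
    M <- r$M
    if (!r$changed) break
  }
  M == 1
}

#' Skeletonize a segmented tubule network and label its branches
#'
#' Thins the mask to one-pixel width (Zhang-Suen), splits the skeleton into
#' branches at junction pixels (>= 3 skeleton neighbours; junctions belong
#' to no branch and are counted separately), measures each branch's
#' principal orientation from a PCA of its pixel path, and labels it
#' transverse (absolute angle to the image vertical <= 45 degrees, i.e.
#' running across the horizontally aligned cell) or longitudinal. Branches
#' shorter than 3 pixels inherit the label of their longest
#' junction-neighbour branch (ties and isolated short branches default to
#' transverse). Branch path length uses the 8-connected step metric
#' (1 or sqrt(2) pixels per step).
#'
#' @param seg a \linkS4class{SegmentedTubules}, or a logical mask plus
#'   \code{pixelSizeUm}
#' @param pixelSizeUm pixel size, required when \code{seg} is a plain mask
#' @return a \linkS4class{TubuleSkeleton}
#' @export
skeletonizeNetwork <- function(seg, pixelSizeUm = NULL) {
  if (is(seg, "SegmentedTubules")) {
    mask <- seg@mask
    pixelSizeUm <- seg@pixelSizeUm
  } else {
    mask <- seg
    if (is.null(pixelSizeUm)) stop("pixelSizeUm required for a plain mask")
  }
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  sk <- thinMask(mask)
  skeletonFromMask(sk, pixelSizeUm)
}

# Branch decomposition of an already one-pixel-wide skeleton mask.
skeletonFromMask <- function(sk, pixelSizeUm) {
  ncount <- Reduce(`+`, lapply(seq_len(8L), function(k)
    shiftMatrix(sk * 1, NEIGH8[k, 1L], NEIGH8[k, 2L])))
  junction <- sk & ncount >= 3
  nonj <- sk & !junction
  lab <- label8(nonj)
  branchMap <- lab$labels
  branchMap[junction] <- -1L
  nb <- lab$n
  h <- nrow(sk)
  branchDf <- data.frame(branch = integer(0), label = character(0),
                         orientationDeg = numeric(0), lengthUm = numeric(0),
                         nPixels = integer(0))
  if (nb > 0L) {
    idx <- which(nonj)
    memb <- branchMap[idx]
    pos <- arrayInd(idx, dim(sk))
    # path length per branch: sum of unique 8-neighbour step lengths along
    # a minimum spanning tree (drops the spurious diagonal chord at turns)
    nodeOf <- integer(h * ncol(sk)); nodeOf[idx] <- seq_along(idx)
    ef <- NULL; ew <- NULL
    for (k in c(3L, 4L, 5L, 6L)) {
      nr <- pos[, 1L] + NEIGH8[k, 1L]; nc <- pos[, 2L] + NEIGH8[k, 2L]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(sk)
      nk <- (nc - 1L) * h + nr
      ok[ok] <- nonj[nk[ok]]
      if (any(ok)) {
        ef <- rbind(ef, cbind(nodeOf[idx[ok]], nodeOf[nk[ok]]))
        ew <- c(ew, rep(if (NEIGH8[k, 1L] != 0L && NEIGH8[k, 2L] != 0L)
          sqrt(2) else 1, sum(ok)))
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(ef))
      g <- igraph::add_edges(g, as.vector(t(ef)), weight = ew)
    gm <- igraph::mst(g, weights = igraph::E(g)$weight)
    lenPx <- numeric(nb)
    if (igraph::ecount(gm) > 0L) {
      el <- igraph::as_edgelist(gm, names = FALSE)
      wts <- igraph::E(gm)$weight
      bOfEdge <- memb[el[, 1L]]
      agg <- rowsum(wts, bOfEdge)
      lenPx[as.integer(rownames(agg))] <- agg
    }
    nPx <- tabulate(memb, nb)
    ori <- vapply(seq_len(nb), function(b) {
      p <- pos[memb == b, , drop = FALSE]
      branchOrientationDeg(p)
    }, numeric(1))
    label <- ifelse(abs(ori) >= 45, "transverse", "longitudinal")
    # short branches inherit the label of their longest neighbour branch
    short <- which(nPx < 3L)
    if (length(short) > 0L && nb > 1L) {
      adj <- branchAdjacency(branchMap, junction)
      for (b in short) {
        nbr <- setdiff(adj[[b]], b)
        nbr <- nbr[nPx[nbr] >= 3L]
        if (length(nbr) > 0L) {
          best <- nbr[order(-lenPx[nbr])][1L]
          if (length(nbr) > 1L &&
              sum(lenPx[nbr] == max(lenPx[nbr])) > 1L) {
            label[b] <- "transverse"          # tie -> transverse
          } else label[b] <- label[best]
        } else label[b] <- "transverse"
      }
    } else if (length(short) > 0L) {
      label[short] <- "transverse"
    }
    branchDf <- data.frame(branch = seq_len(nb), label = label,
                           orientationDeg = ori,
                           lengthUm = lenPx * pixelSizeUm, nPixels = nPx)
  }
  new("TubuleSkeleton", mask = sk, branchMap = branchMap,
      branches = branchDf, junctionCount = sum(junction),
      pixelSizeUm = pixelSizeUm)
}

# Principal orientation (degrees from horizontal, y up, (-90, 90]) of a set
# of pixel coordinates (rows of [row, col]).
branchOrientationDeg <- function(p) {
  if (nrow(p) < 2L) return(0)
  x <- p[, 2L]; y <- -p[, 1L]
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc * xc); syy <- sum(yc * yc); sxy <- sum(xc * yc)
  theta <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  theta
}

# For each branch id, the ids of branches sharing a junction pixel.
branchAdjacency <- function(branchMap, junction) {
  nb <- max(branchMap)
  adj <- rep(list(integer(0)), nb)
  jIdx <- which(junction)
  if (length(jIdx) == 0L) return(adj)
  h <- nrow(branchMap)
  pos <- arrayInd(jIdx, dim(branchMap))
  for (k in seq_len(8L)) {
    nr <- pos[, 1L] + NEIGH8[k, 1L]; nc <- pos[, 2L] + NEIGH8[k, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(branchMap)
    b <- rep(0L, length(jIdx))
    b[ok] <- branchMap[cbind(nr[ok], nc[ok])]
    pos <- cbind(pos, b)
  }
  touching <- pos[, -(1:2), drop = FALSE]
  for (i in seq_len(nrow(touching))) {
    bs <- unique(touching[i, ])
    bs <- bs[bs > 0L]
    for (b in bs) adj[[b]] <- union(adj[[b]], bs)
  }
  adj
}

#' Transverse/longitudinal composition of a skeleton
#'
#' Fractions of total branch path length (micrometres, 8-connected step
#' metric) carried by transverse and longitudinal branches.
#'
#' @param sk a \linkS4class{TubuleSkeleton}
#' @return a \linkS4class{TubuleMetrics} with density set to NA
#' @export
orientationFractions <- function(sk) {
  stopifnot(is(sk, "TubuleSkeleton"))
  b <- sk@branches
  total <- sum(b$lengthUm)
  if (nrow(b) == 0L || total <= 0)
    stop("empty skeleton: orientation fractions undefined")
  tf <- sum(b$lengthUm[b$label == "transverse"]) / total
  new("TubuleMetrics", densityPercent = NA_real_, transverseFraction = tf,
      longitudinalFraction = 1 - tf, skeletonLengthUm = total,
      junctionCount = sk@junctionCount)
}

#' Full t-tubule morphometry of a membrane-stain image
#'
#' Runs \code{\link{segmentTubules}}, \code{\link{tubuleDensity}},
#' \code{\link{skeletonizeNetwork}} and \code{\link{orientationFractions}}.
#'
#' @param img single-channel \linkS4class{Image2D}
#' @param ... passed on to \code{\link{segmentTubules}}
#' @return list with \code{segmentation}, \code{skeleton} and
#'   \code{metrics} (a complete \linkS4class{TubuleMetrics})
#' @export
tubuleMetrics <- function(img, ...) {
  seg <- segmentTubules(img, ...)
  dens <- tubuleDensity(seg)
  # organization, like density, is measured inside the interior ROI so the
  # bright surface sarcolemma does not masquerade as longitudinal tubules
  seg@mask <- seg@mask & seg@geometry@interiorRoi
  if (!any(seg@mask)) {
    metrics <- new("TubuleMetrics", densityPercent = dens,
                   transverseFraction = NA_real_,
                   longitudinalFraction = NA_real_,
                   skeletonLengthUm = 0, junctionCount = 0L)
    return(list(segmentation = seg, skeleton = NULL, metrics = metrics))
  }
  sk <- skeletonizeNetwork(seg)
  of <- orientationFractions(sk)
  metrics <- new("TubuleMetrics", densityPercent = dens,
                 transverseFraction = of@transverseFraction,
                 longitudinalFraction = of@longitudinalFraction,
                 skeletonLengthUm = of@skeletonLengthUm,
                 junctionCount = of@junctionCount)
  list(segmentation = seg, skeleton = sk, metrics = metrics)
}
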