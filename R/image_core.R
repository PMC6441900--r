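# Calibrated containers, TIFF I/O, and the shared preprocessing operators.

#' Construct a calibrated 2D image
#'
#' @param pixels numeric matrix (rows = y, columns = x), intensities >= 0
#' @param pixelSizeUm micrometres per pixel
#' @param channelName optional channel label
#' @return an \linkS4class{Image2D}
#' @export
image2d <- function(pixels, pixelSizeUm, channelName = "") {
  new("Image2D", pixels = unname(as.matrix(pixels)),
      pixelSizeUm = as.numeric(pixelSizeUm),
      channelName = as.character(channelName))
}

#' Construct a calibrated video stack
#'
#' @param frames numeric array H x W x T
#' @param frameIntervalMs milliseconds per frame
#' @param pixelSizeUm micrometres per pixel
#' @return a \linkS4class{VideoStack}
#' @export
videoStack <- function(frames, frameIntervalMs, pixelSizeUm) {
  new("VideoStack", frames = unname(frames),
      frameIntervalMs = as.numeric(frameIntervalMs),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Read a single- or multi-page TIFF as a calibrated image or video
#'
#' A one-page file becomes an \linkS4class{Image2D}; a multi-page file
#' becomes a \linkS4class{VideoStack}. TIFF resolution tags are used for
#' the pixel size when present (unit inch or cm); explicit arguments
#' override tag-derived calibration.
#'
#' @param path TIFF file path
#' @param pixelSizeUm pixel size in micrometres; overrides TIFF tags
#' @param frameIntervalMs frame interval in milliseconds (videos)
#' @param channelName optional channel label
#' @return \linkS4class{Image2D} or \linkS4class{VideoStack}
#' @export
readMicrograph <- function(path, pixelSizeUm = NULL, frameIntervalMs = NULL,
                           channelName = "") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("cannot decode TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (length(pages) == 0L) stop("TIFF contains no images: ", path)
  if (is.null(pixelSizeUm)) {
    info <- attributes(pages[[1L]])
    if (!is.null(info$x.resolution) && info$x.resolution > 0) {
      unitUm <- switch(as.character(info$resolution.unit %||% "inch"),
                       "2" = 25400, inch = 25400, "3" = 10000, cm = 10000,
                       NA_real_)
      if (is.finite(unitUm)) pixelSizeUm <- unitUm / info$x.resolution
    }
    if (is.null(pixelSizeUm))
      stop("pixel size not found in TIFF tags; supply pixelSizeUm")
  }
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  toMat <- function(p) {
    m <- unclass(p)
    bits <- attr(p, "bits.per.sample") %||% 8L
    if (length(dim(m)) == 3L) m <- m[, , 1L]   # first channel of RGB pages
    attributes(m) <- list(dim = dim(m))        # drop TIFF tag attributes
    # 32-bit (float) pages follow writeMicrograph's intensity / 2^16
    # convention; integer pages are restored to digital numbers
    if (bits == 32L) m * 65536 else m * (2^bits - 1)
  }
  if (length(pages) == 1L)
    return(image2d(toMat(pages[[1L]]), pixelSizeUm, channelName))
  if (is.null(frameIntervalMs))
    stop("multi-page TIFF: supply frameIntervalMs")
  if (frameIntervalMs <= 0) stop("frameIntervalMs must be > 0")
  mats <- lapply(pages, toMat)
  d <- dim(mats[[1L]])
  frames <- array(unlist(mats, use.names = FALSE),
                  dim = c(d[1L], d[2L], length(mats)))
  videoStack(frames, frameIntervalMs, pixelSizeUm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calibrated image or video to (multi-page) TIFF
#'
#' Intensities are stored as 32-bit samples scaled by 1/2^16, so
#' \code{\link{readMicrograph}} round-trips intensities below 2^16 with an
#' absolute quantization error of 2^-16 (~1.5e-5), far below detector
#' noise.
#'
#' @param x an \linkS4class{Image2D} or \linkS4class{VideoStack}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeMicrograph <- function(x, path) {
  if (max(pixels(x)) >= 65536)
    stop("intensities must be below 2^16 for TIFF export")
  if (is(x, "Image2D")) {
    tiff::writeTIFF(x@pixels / 65536, path, bits.per.sample = 32L)
  } else if (is(x, "VideoStack")) {
    frames <- lapply(seq_len(dim(x@frames)[3L]),
                     function(t) x@frames[, , t] / 65536)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  } else stop("x must be an Image2D or VideoStack")
  invisible(path)
}

#' Rolling-ball style background subtraction
#'
#' Estimates a smooth background by greyscale morphological opening with a
#' disc structuring element of the stated radius and subtracts it, clipping
#' at zero. A flat image therefore maps to zero everywhere and no output
#' pixel ever exceeds its input.
#'
#' @param img an \linkS4class{Image2D}
#' @param radiusPx structuring-element radius in pixels (>= 1)
#' @return background-subtracted \linkS4class{Image2D}
#' @export
subtractBackground <- function(img, radiusPx) {
  stopifnot(is(img, "Image2D"))
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("radiusPx must be >= 1")
  if (radiusPx >= min(dim(img@pixels)))
    stop("radiusPx must be smaller than the image")
  bg <- greyOpenDisc(img@pixels, radiusPx)
  image2d(pmax(img@pixels - bg, 0), img@pixelSizeUm, img@channelName)
}

#' Linear contrast stretch with saturated tails
#'
#' Rescales intensities linearly so that \code{saturatedPercent} of pixels
#' in total (split evenly between the two tails) are clipped, mapping the
#' remaining range onto [0, max(img)]. The mapping is monotone
#' non-decreasing; a constant image is returned unchanged.
#'
#' @param img an \linkS4class{Image2D}
#' @param saturatedPercent percentage of pixels to saturate (0 <= p < 100)
#' @return contrast-enhanced \linkS4class{Image2D}
#' @export
enhanceContrast <- function(img, saturatedPercent = 0.8) {
  stopifnot(is(img, "Image2D"))
  if (saturatedPercent < 0 || saturatedPercent >= 100)
    stop("saturatedPercent must lie in [0, 100)")
  v <- img@pixels
  top <- max(v)
  if (top == min(v)) return(img)            # constant image: nothing to do
  p <- saturatedPercent / 100 / 2
  lo <- stats::quantile(v, p, names = FALSE)
  hi <- stats::quantile(v, 1 - p, names = FALSE)
  if (hi <= lo) return(img)
  out <- (v - lo) / (hi - lo) * top
  out[out < 0] <- 0
  out[out > top] <- top
  image2d(out, img@pixelSizeUm, img@channelName)
}

# Second-moment orientation of a logical footprint: degrees counterclockwise
# from horizontal with y pointing up, in (-90, 90]; circular shapes give 0.
maskOrientationDeg <- function(mask) {
  pos <- which(mask, arr.ind = TRUE)
  x <- pos[, 2L]
  y <- -pos[, 1L]                            # rows grow downwards
  xc <- x - mean(x); yc <- y - mean(y)
  mu20 <- mean(xc * xc); mu02 <- mean(yc * yc); mu11 <- mean(xc * yc)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  theta
}

# Bilinear rotation of a matrix by `deg` (counterclockwise, y up) about the
# centre, output enlarged to enclose the rotated frame, zero padding.
# EBImage::rotate's angle convention was verified to match this sign.
rotateMatrix <- function(m, deg, outputDim = NULL) {
  img <- if (is.null(outputDim)) {
    EBImage::rotate(m, angle = deg, filter = "bilinear", bg.col = 0)
  } else {
    EBImage::rotate(m, angle = deg, filter = "bilinear", bg.col = 0,
                    output.dim = outputDim)
  }
  as.matrix(img)
}

#' Rotate a cell image so its long axis is horizontal
#'
#' Finds the cell footprint (Otsu threshold, largest 8-connected component,
#' hole filling), measures the long-axis orientation from the second central
#' moments of the footprint, and rotates the image by the negative of that
#' angle. The output frame is enlarged to enclose the rotated cell. The
#' returned geometry holds the post-rotation footprint and an interior ROI
#' eroded inward from the sarcolemma by \code{roiMarginUm}.
#'
#' @param img an \linkS4class{Image2D} containing one dominant cell
#' @param roiMarginUm inward erosion margin defining the interior ROI
#'   (default 1 um)
#' @return list with elements \code{image} (rotated \linkS4class{Image2D})
#'   and \code{geometry} (\linkS4class{CellGeometry})
#' @export
rotateToHorizontal <- function(img, roiMarginUm = 1) {
  stopifnot(is(img, "Image2D"))
  ot <- otsuThreshold(img)
  if (!any(ot$mask)) stop("no foreground after Otsu thresholding")
  fp <- fillHoles(largestComponent(ot$mask))
  theta <- maskOrientationDeg(fp)
  if (abs(theta) < 1e-9) {
    rimg <- img@pixels
    rfp <- fp
  } else {
    rimg <- rotateMatrix(img@pixels, -theta)
    rimg[rimg < 0] <- 0
    rfp <- rotateMatrix(fp * 1, -theta, outputDim = NULL) > 0.5
    rfp <- fillHoles(rfp)
  }
  marginPx <- as.integer(ceiling(roiMarginUm / img@pixelSizeUm))
  interior <- binErode(rfp, marginPx)
  geom <- new("CellGeometry", footprint = rfp, principalAxisDeg = theta,
              interiorRoi = interior, roiMarginUm = roiMarginUm,
              pixelSizeUm = img@pixelSizeUm)
  list(image = image2d(rimg, img@pixelSizeUm, img@channelName),
       geometry = geom)
}

#' Mexican-hat (inverted Laplacian-of-Gaussian) ridge filter
#'
#' Convolution with an inverted LoG kernel whose square support has
#' half-width \code{radiusPx}; the Gaussian sigma is \code{radiusPx / 3},
#' so the kernel is truncated at +/- 3 sigma. The kernel is normalized to
#' zero sum (a constant image maps to zero) and negative responses are
#' clipped to zero. With the standard radius of 3 the filter enhances
#' ridges at the apparent width of confocal t-tubules (2-3 px).
#'
#' @param img an \linkS4class{Image2D}
#' @param radiusPx kernel half-width in pixels (>= 1); sigma = radiusPx / 3
#' @return filtered \linkS4class{Image2D}
#' @export
mexicanHat <- function(img, radiusPx = 3) {
  stopifnot(is(img, "Image2D"))
  if (radiusPx < 1) stop("radiusPx must be >= 1")
  s <- radiusPx / 3
  hs <- ceiling(radiusPx)
  g <- seq(-hs, hs)
  d2 <- outer(g^2, g^2, "+")
  k <- -(d2 - 2 * s^2) / s^4 * exp(-d2 / (2 * s^2))
  k <- k - mean(k)                           # exact zero response to constants
  out <- as.matrix(EBImage::filter2(img@pixels, k, boundary = "replicate"))
  out[out < 0] <- 0
  image2d(out, img@pixelSizeUm, img@channelName)
}

# median of three matrices, elementwise
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

#' Median filter over a Euclidean disk
#'
#' The neighbourhood is the exact Euclidean disk \eqn{dx^2 + dy^2 \le r^2}
#' (5 pixels at radius 1); edges are handled by replication. Radius 1 uses
#' an exact 5-value sorting network; larger radii fall back to a direct
#' per-pixel median.
#'
#' @param img an \linkS4class{Image2D}
#' @param radiusPx disk radius in pixels (>= 1)
#' @return filtered \linkS4class{Image2D}
#' @export
medianDisk <- function(img, radiusPx = 1) {
  stopifnot(is(img, "Image2D"))
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("radiusPx must be >= 1")
  m <- img@pixels
  offs <- expand.grid(dy = -radiusPx:radiusPx, dx = -radiusPx:radiusPx)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radiusPx^2, ]
  if (nrow(offs) == 5L) {
    n <- shiftMatrix(m, -1L, 0L, replicate = TRUE)
    s <- shiftMatrix(m, 1L, 0L, replicate = TRUE)
    e <- shiftMatrix(m, 0L, 1L, replicate = TRUE)
    w <- shiftMatrix(m, 0L, -1L, replicate = TRUE)
    lo <- pmin(n, s); hi <- pmax(n, s)
    lo2 <- pmin(e, w); hi2 <- pmax(e, w)
    out <- med3(pmax(lo, lo2), pmin(hi, hi2), m)
  } else {
    stack <- vapply(seq_len(nrow(offs)), function(i)
      shiftMatrix(m, offs$dy[i], offs$dx[i], replicate = TRUE),
      m)
    out <- apply(stack, c(1L, 2L), stats::median.default)
  }
  image2d(out, img@pixelSizeUm, img@channelName)
}

# Otsu threshold of a numeric vector over 256 equal-width bins spanning the
# observed range. Class means use exact per-bin intensity sums, so the
# maximizing split agrees with an exhaustive search over candidate
# thresholds for quantized (e.g. 8-bit) data. Returns the threshold value
# (maximum intensity of the lower class): foreground is strictly above it.
otsuVector <- function(v) {
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("Otsu threshold undefined: image has a single intensity value")
  w <- (rng[2L] - rng[1L]) / 256
  bin <- pmin(floor((v - rng[1L]) / w), 255)   # 0 .. 255
  cnt <- tabulate(bin + 1L, 256L)
  bs <- numeric(256L)
  agg <- rowsum(v, bin)
  bs[as.integer(rownames(agg)) + 1L] <- agg
  cw <- cumsum(cnt); cs <- cumsum(bs)
  n <- cw[256L]; stot <- cs[256L]
  w0 <- cw[1:255]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cs[1:255] / w0
  mu1 <- (stot - cs[1:255]) / w1
  sigma <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(sigma)                        # split: bins [0,k-1] vs [k,255]
  max(v[bin <= k - 1L])
}

#' Otsu threshold and foreground mask
#'
#' The threshold maximizes the between-class variance over a 256-bin
#' histogram of the observed intensity range; the mask marks pixels
#' strictly above the threshold. Fails on constant images.
#'
#' @param img an \linkS4class{Image2D} (or numeric matrix/vector)
#' @return list with \code{threshold} (numeric) and \code{mask}
#'   (logical matrix, or logical vector for vector input)
#' @export
otsuThreshold <- function(img) {
  px <- if (is(img, "Image2D")) img@pixels else img
  thr <- otsuVector(as.numeric(px))
  mask <- px > thr
  list(threshold = thr, mask = mask)
}
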