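# Internal helpers shared across the measurement pipelines.

# Shift a matrix by (dy, dx); vacated cells are filled with `fill`
# or, when replicate = TRUE, with the clamped edge value.
shiftMatrix <- function(m, dy, dx, fill = 0, replicate = FALSE) {
  h <- nrow(m); w <- ncol(m)
  ri <- seq_len(h) + dy
  ci <- seq_len(w) + dx
  if (replicate) {
    ri <- pmin(pmax(ri, 1L), h)
    ci <- pmin(pmax(ci, 1L), w)
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, h, w)
  rok <- ri >= 1L & ri <= h
  cok <- ci >= 1L & ci <= w
  out[rok, cok] <- m[ri[rok], ci[cok]]
  out
}

# Offsets of the 8-neighbourhood: N, NE, E, SE, S, SW, W, NW
# (dy is down-positive in matrix row coordinates).
NEIGH8 <- cbind(
  dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

# 8-connected component labelling of a logical matrix via igraph.
# Returns an integer matrix (0 = background) and the number of components.
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = lab, n = 0L))
  h <- nrow(mask); w <- ncol(mask)
  nodeOf <- integer(h * w)       # linear pixel index -> node id
  nodeOf[idx] <- seq_along(idx)
  pos <- arrayInd(idx, dim(mask))
  edges <- vector("list", 4L)
  # forward half of the 8-neighbourhood avoids duplicate edges
  half <- c(3L, 4L, 5L, 6L)      # E, SE, S, SW
  for (j in seq_along(half)) {
    k <- half[j]
    nr <- pos[, 1L] + NEIGH8[k, 1L]
    nc <- pos[, 2L] + NEIGH8[k, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nk <- (nc - 1L) * h + nr
    ok[ok] <- mask[nk[ok]]
    if (any(ok)) edges[[j]] <- cbind(nodeOf[idx[ok]], nodeOf[nk[ok]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, n = comp$no)
}

# Largest 8-connected component of a logical matrix.
largestComponent <- function(mask) {
  l8 <- label8(mask)
  if (l8$n == 0L) return(mask & FALSE)
  sizes <- tabulate(l8$labels[l8$labels > 0L], l8$n)
  l8$labels == which.max(sizes)
}

# Greyscale morphological opening with a disc structuring element.
# EBImage morphology clips to [0, 1], so rescale around the call.
greyOpenDisc <- function(px, radiusPx) {
  mx <- max(px)
  if (mx <= 0) return(px * 0)
  brush <- EBImage::makeBrush(2L * radiusPx + 1L, shape = "disc")
  as.matrix(EBImage::opening(px / mx, brush)) * mx
}

binErode <- function(mask, radiusPx) {
  if (radiusPx < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * radiusPx + 1L, shape = "disc")
  as.matrix(EBImage::erode(mask * 1, brush)) > 0.5
}

binDilateBox <- function(mask, sizePx) {
  brush <- matrix(1, sizePx, sizePx)
  as.matrix(EBImage::dilate(mask * 1, brush)) > 0.5
}

binClose <- function(mask, radiusPx) {
  if (radiusPx < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * radiusPx + 1L, shape = "disc")
  as.matrix(EBImage::closing(mask * 1, brush)) > 0.5
}

fillHoles <- function(mask) {
  as.matrix(EBImage::fillHull(mask * 1)) > 0.5
}

# Euclidean distance (in pixels) from every pixel to the nearest TRUE pixel.
distanceToMask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap((!mask) * 1, metric = "euclidean"))
}

# Population standard deviation (denominator n).
sdPop <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Round a physical size in um to the nearest odd pixel count (>= 1).
oddPixels <- function(sizeUm, pixelSizeUm) {
  n <- max(1L, round(sizeUm / pixelSizeUm))
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

# Linear interpolation of the first upward crossing of `level` in a series
# sampled at frames 1..T; returns the fractional frame index (1-based) or NA.
firstCrossing <- function(y, level, from = 1L) {
  n <- length(y)
  if (from > n) return(NA_real_)
  above <- which(y[from:n] >= level)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L] + from - 1L
  if (i == 1L) return(1)
  y0 <- y[i - 1L]; y1 <- y[i]
  frac <- if (y1 > y0) (level - y0) / (y1 - y0) else 0
  (i - 1L) + min(max(frac, 0), 1)
}
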