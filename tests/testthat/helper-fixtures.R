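# Fixtures built in code: no binary files in the repository.

# filled ellipse (solid cell-like object) at a given orientation, degrees
# counterclockwise from horizontal (y up)
ellipseImage <- function(h = 96, w = 128, a = 45, b = 18, angleDeg = 0,
                         fg = 200, bg = 10, pixelSizeUm = 0.2) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angleDeg * pi / 180
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  x <- col - cx
  y <- -(row - cy)                  # y up
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  image2d(ifelse(inside, fg, bg), pixelSizeUm)
}

# uniform-trace video: every ROI pixel follows the same time course `f`
uniformVideo <- function(f, h = 24, w = 24, dt = 1.5, ps = 0.2) {
  frames <- array(rep(f, each = h * w), dim = c(h, w, length(f)))
  videoStack(frames, dt, ps)
}

# video in which pixel (i, j) steps from `lo` to `hi` at frame onset[i, j]
stepVideo <- function(onset, nframes, lo = 100, hi = 300, dt = 1,
                      ps = 0.2) {
  h <- nrow(onset); w <- ncol(onset)
  frames <- array(lo, dim = c(h, w, nframes))
  for (t in seq_len(nframes)) {
    frames[, , t] <- ifelse(t >= onset, hi, lo)
  }
  videoStack(frames, dt, ps)
}

# brute-force Otsu oracle: exhaustive search over all candidate thresholds
# (distinct grey values), maximizing the between-class variance with exact
# class statistics; mask = pixels strictly above the chosen value
bruteForceOtsuMask <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]       # the top value cannot be a lower class max
  best <- -Inf; bestT <- cand[1L]
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    s <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; bestT <- t }
  }
  list(threshold = bestT, mask = v > bestT)
}

# simple membrane-dye phantom: vertical tubule lines at given column
# positions inside a rectangular cell, bright border (sarcolemma)
lineCellImage <- function(h = 80, w = 140, cols = seq(15, 125, by = 11),
                          bg = 8, amp = 150, ps = 0.16) {
  px <- matrix(bg, h, w)
  cell <- matrix(FALSE, h, w); cell[8:(h - 7), 8:(w - 7)] <- TRUE
  border <- cell & !{m <- matrix(FALSE, h, w); m[10:(h - 9), 10:(w - 9)] <- TRUE; m}
  px[border] <- bg + amp
  for (cc in cols) px[10:(h - 9), cc + (-1:0)] <- bg + amp
  image2d(px, ps)
}
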