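# Independent reference implementations used as oracles, deliberately
# written in the most naive way possible.

# per-pixel Lloyd iterations, plain loops over points
naiveLloydMask <- function(rb, gb, centers = matrix(c(0, 0, 40, 40), 2, 2,
                                                    byrow = TRUE),
                           maxIter = 100) {
  pts <- cbind(as.vector(rb), as.vector(gb))
  assign <- rep(NA_integer_, nrow(pts))
  for (it in seq_len(maxIter)) {
    newA <- integer(nrow(pts))
    for (p in seq_len(nrow(pts))) {
      d1 <- sum((pts[p, ] - centers[1, ])^2)
      d2 <- sum((pts[p, ] - centers[2, ])^2)
      newA[p] <- if (d2 < d1) 2L else 1L
    }
    if (identical(newA, assign)) break
    assign <- newA
    for (k in 1:2) {
      sel <- assign == k
      if (any(sel)) centers[k, ] <- colMeans(pts[sel, , drop = FALSE])
    }
  }
  fg <- if (sum(centers[2, ]^2) >= sum(centers[1, ]^2)) 2L else 1L
  matrix(assign == fg, nrow = nrow(rb))
}

# literal double loop of the optimal-area search
exhaustiveOptimalArea <- function(s) {
  minError <- Inf
  sOpt <- NA_real_
  for (i in seq_along(s)) {
    totalError <- 0
    for (j in seq_along(s)) totalError <- totalError + abs(1 - s[j] / s[i])
    if (totalError < minError) {
      minError <- totalError
      sOpt <- s[i]
    }
  }
  sOpt
}

# brute-force valley search on a trend curve evaluated at bins 0..255:
# interior local maxima, keep the two tallest, scan every integer bin
# strictly between them for the minimum
bruteValley <- function(f) {
  peaks <- c()
  for (i in 2:(length(f) - 1)) {
    if (f[i] > f[i - 1] && f[i] > f[i + 1]) peaks <- c(peaks, i)
  }
  if (length(peaks) < 2) return(NA_real_)
  top <- peaks[order(f[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top); hi <- max(top)
  best <- NA; bestVal <- Inf
  for (i in (lo + 1):(hi - 1)) {
    if (f[i] < bestVal) {
      bestVal <- f[i]
      best <- i
    }
  }
  best - 1  # red value, 0-based
}

# independent scan of the documented two-stage point-A rule
brutePointA <- function(areas, len = 3, sigma = 0.65, minDip = 0.05) {
  sm <- numeric(length(areas))
  kern <- exp(-(-1:1)^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  n <- length(areas)
  for (i in seq_len(n)) {
    j <- (i - 1):(i + 1); ok <- j >= 1 & j <= n
    sm[i] <- sum(areas[j[ok]] * kern[ok]) / sum(kern[ok])
  }
  g <- numeric(n)
  if (n >= 3) for (i in 2:(n - 1)) g[i] <- sm[i + 1] + sm[i - 1] - 2 * sm[i]
  if (n < 3) return(1L)
  thr <- minDip * median(sm)
  if (thr > 0) {
    above <- which(g > thr)
    if (length(above)) {
      i <- above[1]
      while (i + 1 <= n && g[i + 1] > thr) i <- i + 1
      return(min(i + 1, n))
    }
  }
  for (i in 2:(n - 1)) {
    if (g[i - 1] < 0 && g[i - 1] < g[i] && g[i + 1] > 0 && g[i + 1] > g[i]) {
      j <- i - 1; runMin <- g[j]
      while (j > 1 && g[j - 1] < 0) { j <- j - 1; runMin <- min(runMin, g[j]) }
      if (runMin < -thr) return(i)
    }
  }
  1L
}

# lossless right-angle rotation of an H x W x 3 image array
rotateImage <- function(img, turns = 1) {
  for (t in seq_len(turns %% 4)) {
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

# solid-background test image with a filled disk of a given color
diskImage <- function(n = 60, r = 10, fg = c(200, 180, 100), bg = c(0, 0, 0)) {
  img <- grainGerm::solidImage(n, n, bg)
  ctr <- (n + 1) / 2
  mask <- outer(seq_len(n), seq_len(n),
                function(y, x) (y - ctr)^2 + (x - ctr)^2 <= r^2)
  for (k in 1:3) {
    ch <- img[, , k]
    ch[mask] <- as.integer(fg[k])
    img[, , k] <- ch
  }
  list(image = img, mask = mask)
}

benignSpec <- function(seed, nGrains = 40, germinationFraction = 0.7, ...) {
  grainGerm::sceneSpec(seed = seed, nGrains = nGrains,
                       germinationFraction = germinationFraction, ...)
}
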