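#' Label connected regions of a binary mask
#'
#' 8-connected component labeling. EBImage's \code{bwlabel} provides
#' 4-connected labels; components that touch only diagonally are merged
#' afterwards with a union--find pass over the diagonal adjacencies, and
#' labels are compacted to 1..k in order of first appearance.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return list with \code{labels} (integer matrix, 0 = background) and
#'   \code{table} (data.frame: \code{label}, \code{area}, bounding box
#'   \code{rowMin}, \code{rowMax}, \code{colMin}, \code{colMax}).
#' @export
labelRegions <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab > 0L && connectivity == 8L) {
    # merge labels that touch only diagonally
    nr <- nrow(lab); nc <- ncol(lab)
    p1 <- c(lab[-nr, -nc], lab[-nr, -1])   # NW and NE neighbors
    p2 <- c(lab[-1, -1], lab[-1, -nc])
    sel <- p1 > 0L & p2 > 0L & p1 != p2
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (any(sel)) {
      pairs <- unique(cbind(p1[sel], p2[sel]))
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  k <- length(ids)
  if (k == 0L) {
    return(list(labels = lab,
                table = data.frame(label = integer(0), area = integer(0),
                                   rowMin = integer(0), rowMax = integer(0),
                                   colMin = integer(0), colMax = integer(0))))
  }
  area <- tabulate(lab[lab > 0L], nbins = k)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  table <- data.frame(
    label = seq_len(k),
    area = area,
    rowMin = vapply(split(idx[, 1], l), min, 1),
    rowMax = vapply(split(idx[, 1], l), max, 1),
    colMin = vapply(split(idx[, 2], l), min, 1),
    colMax = vapply(split(idx[, 2], l), max, 1),
    row.names = NULL
  )
  list(labels = lab, table = table)
}

#' Build the sorted area-distribution curve
#'
#' Sorts the region areas ascending, smooths them with a 3-tap unit-sum
#' Gaussian (sigma 0.65; edge taps renormalized), applies the discrete
#' Laplacian \code{g(x) = f(x+1) + f(x-1) - 2 f(x)} on interior points
#' (endpoints 0), and locates the turning points A and B.
#'
#' @param table region table from [labelRegions()] (or a bare numeric
#'   vector of areas).
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return an [AreaCurve-class] object.
#' @export
buildAreaCurve <- function(table, config = pipelineConfig()) {
  a <- if (is.data.frame(table)) table$area
       else if (is.list(table)) table$table$area
       else as.numeric(table)
  stopifnot(length(a) >= 1L)
  ord <- order(a)
  sorted <- as.numeric(a[ord])
  smoothed <- smoothSeries(sorted, config$curveLen, config$curveSigma)
  m <- length(sorted)
  g <- numeric(m)
  if (m >= 3L) {
    i <- 2:(m - 1)
    g[i] <- smoothed[i + 1] + smoothed[i - 1] - 2 * smoothed[i]
  }
  curve <- new("AreaCurve", areas = sorted, smoothed = smoothed,
               laplacian = g, indexA = 1L, indexB = m,
               ordering = as.integer(ord))
  curve@indexA <- findPointA(curve, config$pointAMinDip)
  curve@indexB <- findPointB(curve, curve@indexA, config)
  validObject(curve)
  curve
}

# truncated-renormalized Gaussian smoothing of a short series
smoothSeries <- function(v, len = 3, sigma = 0.65) {
  half <- floor(len / 2)
  x <- seq(-half, half)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    k <- kern[ok]
    out[i] <- sum(v[j[ok]] * k) / sum(k)
  }
  out
}

#' Locate turning point A (end of the noise regions)
#'
#' The jump from near-zero noise areas up to the single-grain plateau
#' shows up in the Laplacian g of the smoothed area curve as a sharp
#' positive spike (convex corner at the last noise region) followed by a
#' negative dip (concave landing on the plateau) and a rise of g back
#' through zero. A is located from this structure in two stages, both
#' scaled by \code{minDipFraction * median(f)} so that the few-pixel
#' wiggles of a jittered single-grain plateau (or of near-equal noise
#' specks) never qualify:
#'
#' \enumerate{
#'   \item the first contiguous run of Laplacian values above the
#'     threshold marks the jump; A is the first index after that run --
#'     the first plateau region;
#'   \item failing that (a gradual noise ramp with no sharp spike), the
#'     first index i with \code{g(i-1) < 0}, \code{g(i-1) < g(i)},
#'     \code{g(i+1) > 0} and \code{g(i+1) > g(i)} -- g rising through
#'     zero -- whose preceding contiguous negative run dips below the
#'     threshold.
#' }
#'
#' Without any qualifying structure (no noise regions, or fewer than
#' three regions) A falls back to the first index. With
#' \code{minDipFraction = 0} stage 1 is disabled and stage 2 reduces to
#' the bare sign-pattern scan.
#'
#' @param curve an [AreaCurve-class] object.
#' @param minDipFraction scale-free spike/dip threshold (default 0.05).
#' @return integer index (1-based) into \code{areas(curve)}.
#' @export
findPointA <- function(curve, minDipFraction = 0.05) {
  g <- curve@laplacian
  m <- length(g)
  if (m < 3L) return(1L)
  thr <- minDipFraction * stats::median(curve@smoothed)
  if (thr > 0) {
    spike <- which(g > thr)
    if (length(spike)) {
      i <- spike[1]
      while (i + 1L <= m && g[i + 1L] > thr) i <- i + 1L
      return(as.integer(min(i + 1L, m)))
    }
  }
  for (i in 2:(m - 1)) {
    if (g[i - 1] < 0 && g[i - 1] < g[i] && g[i + 1] > 0 &&
        g[i + 1] > g[i]) {
      # depth of the contiguous negative run the crossing climbs out of
      j <- i - 1L
      runMin <- g[j]
      while (j > 1L && g[j - 1L] < 0) {
        j <- j - 1L
        if (g[j] < runMin) runMin <- g[j]
      }
      if (runMin < -thr) return(as.integer(i))
    }
  }
  1L
}

#' Locate turning point B (end of the single-grain plateau)
#'
#' Scanning the raw sorted areas upward from A, the first index i with
#' \code{s[i + 3] / s[i] > 1.2} marks the start of the jump to
#' multi-grain cluster areas; B is that index i, the last stable point
#' (with \code{config$pointBConvention = "post-jump"}, B is i + 3
#' instead). If the condition never fires every region holds a single
#' grain and B falls back to the last index.
#'
#' @param curve an [AreaCurve-class] object.
#' @param A index of point A.
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return integer index (1-based).
#' @export
findPointB <- function(curve, A = curve@indexA,
                       config = pipelineConfig()) {
  s <- if (isTRUE(config$smoothedAreasForB)) curve@smoothed else curve@areas
  m <- length(s)
  for (i in A:m) {
    if (i + 3L <= m && s[i + 3L] / s[i] > config$ratioThreshold) {
      return(if (identical(config$pointBConvention, "post-jump"))
               as.integer(i + 3L) else as.integer(i))
    }
  }
  as.integer(m)
}

#' Optimal single-grain area
#'
#' Exhaustively evaluates every candidate area s_i between the turning
#' points: the cost of s_i is \code{sum_j |1 - s_j / s_i|}, and the
#' optimum is the candidate with minimal cost (first minimizer on ties).
#' Dividing a region area by this optimum gives the number of grains the
#' region holds.
#'
#' @param candidates numeric vector of candidate areas (the sorted areas
#'   between A and B inclusive).
#' @return the optimal single-grain area.
#' @examples
#' optimalGrainArea(c(100, 110, 120))  # 110
#' @export
optimalGrainArea <- function(candidates) {
  if (length(candidates) == 0L)
    stop("no candidate areas between A and B; cannot estimate grain size")
  cost <- vapply(candidates,
                 function(si) sum(abs(1 - candidates / si)), numeric(1))
  candidates[which.min(cost)]
}

#' Grains in one connected region
#'
#' \code{s / sOpt} rounded down, plus one when the fractional part
#' exceeds 0.4 (so a region 2.5 times the single-grain area counts 3
#' grains). Vectorized over \code{s}.
#'
#' @param s region area(s), pixels.
#' @param sOpt optimal single-grain area, pixels.
#' @param fractionThreshold fractional part above which the count is
#'   rounded up (default 0.4).
#' @return integer grain count(s).
#' @examples
#' countRegion(c(100, 250, 139), 100)  # 1 3 1
#' @export
countRegion <- function(s, sOpt, fractionThreshold = 0.4) {
  stopifnot(sOpt > 0)
  q <- s / sOpt
  fl <- floor(q)
  as.integer(fl + (q - fl > fractionThreshold))
}

#' Count all grains
#'
#' Sums the per-region grain counts. Regions at sorted positions below
#' point A are noise and contribute nothing; every other region
#' contributes [countRegion()] of its area.
#'
#' @param curve an [AreaCurve-class] object.
#' @param table region table from [labelRegions()].
#' @param sOpt optimal single-grain area.
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return list with \code{nGrain}, \code{sOpt} and \code{regions}, a
#'   data.frame with per-region sorted index, noise flag and count.
#' @export
countGrains <- function(curve, table, sOpt, config = pipelineConfig()) {
  tab <- if (is.data.frame(table)) table else table$table
  m <- nrow(tab)
  sortedIndex <- integer(m)
  sortedIndex[curve@ordering] <- seq_len(m)
  isNoise <- sortedIndex < curve@indexA
  counts <- countRegion(tab$area, sOpt, config$fractionThreshold)
  counts[isNoise] <- 0L
  regions <- data.frame(label = tab$label, area = tab$area,
                        sortedIndex = sortedIndex, isNoise = isNoise,
                        count = counts)
  list(nGrain = sum(counts), sOpt = sOpt, regions = regions)
}
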