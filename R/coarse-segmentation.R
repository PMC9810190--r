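#' Clipped color-difference features
#'
#' Computes the per-pixel feature pair used for coarse segmentation:
#' \code{r_b = 30} where \code{R - B >= 60} and \code{R - B} otherwise
#' (negative differences pass through), and the analogous \code{g_b}
#' from \code{G - B}. Clipping compresses the large spread of the
#' red-minus-blue difference over the grain body so that the dimmer
#' border pixels stay with the grain cluster.
#'
#' @param img integer array \code{height x width x 3}, values 0--255.
#' @param clipDelta difference at or above which the feature is clipped
#'   (default 60).
#' @param clipValue value the feature is clipped to (default 30).
#' @return list with integer matrices \code{rb} and \code{gb}.
#' @examples
#' f <- computeColorFeatures(solidImage(1, 1, c(200, 180, 100)))
#' c(f$rb, f$gb)  # 30 30
#' @export
computeColorFeatures <- function(img, clipDelta = 60, clipValue = 30) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  rb <- img[, , 1, drop = TRUE] - img[, , 3, drop = TRUE]
  gb <- img[, , 2, drop = TRUE] - img[, , 3, drop = TRUE]
  rb[rb >= clipDelta] <- clipValue
  gb[gb >= clipDelta] <- clipValue
  list(rb = matrix(as.integer(rb), d[1], d[2]),
       gb = matrix(as.integer(gb), d[1], d[2]))
}

#' Two-center k-means segmentation in feature space
#'
#' Lloyd iterations with squared-Euclidean distance and the fixed initial
#' centers (0,0) for the background/white cluster and (40,40) for the
#' grain cluster, so the whole segmentation is deterministic. Pixels
#' equidistant from both centers go to cluster 1 (background); an empty
#' cluster keeps its previous center. The foreground is the cluster whose
#' final center lies farther from the origin.
#'
#' Internally the iteration runs over the unique feature pairs weighted
#' by their pixel counts, which is exactly equivalent to per-pixel Lloyd
#' updates.
#'
#' @param features list with matrices \code{rb}, \code{gb} from
#'   [computeColorFeatures()].
#' @param centers 2 x 2 numeric matrix of initial centers, one per row.
#' @param maxIter iteration cap guarding against oscillation.
#' @return logical matrix: \code{TRUE} for grain foreground.
#' @export
kmeansTwoClusters <- function(features,
                              centers = matrix(c(0, 0, 40, 40), 2, 2,
                                               byrow = TRUE),
                              maxIter = 100L) {
  stopifnot(is.matrix(centers), nrow(centers) == 2L, ncol(centers) == 2L)
  rb <- as.vector(features$rb)
  gb <- as.vector(features$gb)
  # encode feature pairs compactly; differences lie in [-255, 255]
  code <- (rb + 256L) * 512L + (gb + 256L)
  tab <- tabulate(code + 1L, nbins = 512L * 512L)
  keep <- which(tab > 0L)
  w <- tab[keep]
  urb <- (keep - 1L) %/% 512L - 256L
  ugb <- (keep - 1L) %% 512L - 256L

  assign <- rep(NA_integer_, length(keep))
  for (iter in seq_len(maxIter)) {
    d1 <- (urb - centers[1, 1])^2 + (ugb - centers[1, 2])^2
    d2 <- (urb - centers[2, 1])^2 + (ugb - centers[2, 2])^2
    newAssign <- ifelse(d2 < d1, 2L, 1L)  # ties -> cluster 1 (background)
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (k in 1:2) {
      sel <- assign == k
      if (any(sel)) {
        wk <- w[sel]
        centers[k, ] <- c(sum(wk * urb[sel]), sum(wk * ugb[sel])) / sum(wk)
      } # empty cluster: keep the stale center
    }
  }
  fg <- which.max(c(sum(centers[1, ]^2), sum(centers[2, ]^2)))
  if (sum(centers[1, ]^2) == sum(centers[2, ]^2)) fg <- 2L
  pixAssign <- assign[match(code, keep - 1L)]
  mask <- matrix(pixAssign == fg, nrow = nrow(features$rb))
  mask
}

#' Coarse grain segmentation
#'
#' Composition of [computeColorFeatures()] and [kmeansTwoClusters()]:
#' the first-pass binary grain mask. Shadow borders around the grains are
#' still included at this stage and are removed by the refinement step.
#'
#' @inheritParams computeColorFeatures
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return logical matrix: \code{TRUE} for grain foreground.
#' @export
coarseSegment <- function(img, config = pipelineConfig()) {
  feats <- computeColorFeatures(img, config$clipDelta, config$clipValue)
  kmeansTwoClusters(feats, centers = config$kmeansCenters,
                    maxIter = config$kmeansMaxIter)
}
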