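#' Red-component histogram of the foreground
#'
#' Tallies the red channel over the foreground pixels of a mask into 256
#' bins (red values 0--255). This is the histogram in which the shadow
#' border of the grains forms a low-red peak and the grain core a
#' high-red peak.
#'
#' @param img integer array \code{height x width x 3}.
#' @param mask logical matrix, foreground.
#' @return numeric vector of length 256; element \code{v + 1} counts the
#'   foreground pixels with red value \code{v}.
#' @export
redHistogram <- function(img, mask) {
  stopifnot(identical(dim(mask), dim(img)[1:2]))
  red <- img[, , 1][mask]
  if (length(red) == 0L)
    stop("mask contains no foreground pixels; no histogram to build")
  as.numeric(tabulate(red + 1L, nbins = 256L))
}

#' Gaussian smoothing of a 256-bin histogram
#'
#' Discrete convolution with a centered, unit-sum Gaussian kernel
#' (size-100 reading: a symmetric 101-tap kernel). At the histogram
#' edges the truncated kernel is renormalized, and the result is rescaled
#' so that the total mass of the histogram is preserved exactly.
#'
#' @param h numeric vector of length 256, bin counts.
#' @param size nominal kernel size in taps (default 100; a symmetric
#'   kernel of \code{2 * floor(size/2) + 1} taps is used).
#' @param sigma kernel standard deviation in bins (default 7.5).
#' @return numeric vector of length 256, smoothed counts.
#' @export
gaussianSmoothHistogram <- function(h, size = 100, sigma = 7.5) {
  stopifnot(length(h) == 256L, all(h >= 0))
  half <- floor(size / 2)
  x <- seq(-half, half)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(h)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    k <- kern[ok]
    out[i] <- sum(h[j[ok]] * k) / sum(k)
  }
  total <- sum(h)
  smoothedTotal <- sum(out)
  if (smoothedTotal > 0) out <- out * (total / smoothedTotal)
  out
}

#' Least-squares quintic fit of a histogram
#'
#' Fits the trend line \code{f(x) = a x^5 + b x^4 + c x^3 + d x^2 + e x
#' + f} to the 256 (bin, count) pairs by least squares. The fit is
#' computed on a rescaled abscissa for numerical conditioning and the
#' coefficients are mapped back to the bin domain.
#'
#' @param h numeric vector of length 256.
#' @return list with \code{coefficients} (named \code{a} \ldots \code{f},
#'   degree 5 down to the constant) and \code{trend}, the fit evaluated
#'   at bins 0--255.
#' @export
fitQuintic <- function(h) {
  stopifnot(length(h) == 256L)
  x <- 0:255
  xs <- x / 255
  fit <- stats::lm(h ~ xs + I(xs^2) + I(xs^3) + I(xs^4) + I(xs^5))
  cs <- stats::coef(fit)          # c0..c5 on the scaled axis
  cs[is.na(cs)] <- 0
  coefs <- rev(as.numeric(cs) / 255^(0:5))  # a..f on the bin axis
  names(coefs) <- c("a", "b", "c", "d", "e", "f")
  trend <- as.numeric(stats::fitted(fit))
  list(coefficients = coefs, trend = trend)
}

#' Locate the valley threshold on the quintic trend line
#'
#' Evaluates the fitted trend on the integer bins, finds its interior
#' local maxima, keeps the two with the largest fitted value, and takes
#' the minimum of the trend strictly between them as the valley point C;
#' its red value is the refinement threshold d. With fewer than two
#' interior maxima there is no bimodal border/core structure and no
#' threshold is returned (refinement is skipped).
#'
#' @param fit result of [fitQuintic()].
#' @return a [RefinementResult-class] object.
#' @export
findValleyThreshold <- function(fit) {
  f <- fit$trend
  n <- length(f)
  i <- 2:(n - 1)
  peaks <- i[f[i] > f[i - 1] & f[i] > f[i + 1]]
  if (length(peaks) < 2L) {
    return(new("RefinementResult", thresholdD = NA_real_,
               peakA = NA_real_, peakB = NA_real_, valleyC = NA_real_,
               trend = f))
  }
  top <- peaks[order(f[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top); hi <- max(top)
  between <- (lo + 1):(hi - 1)
  valley <- between[which.min(f[between])]
  new("RefinementResult",
      thresholdD = as.numeric(valley - 1L),   # bin index -> red value
      peakA = as.numeric(lo - 1L),
      peakB = as.numeric(hi - 1L),
      valleyC = as.numeric(valley - 1L),
      trend = f)
}

#' Refinement segmentation
#'
#' Removes the dark shadow border from the coarse grain mask: foreground
#' pixels whose red value lies below the valley threshold d are
#' reclassified as background. Without a threshold the mask is returned
#' unchanged. The operation is anti-extensive: the output foreground is
#' always a subset of the input foreground.
#'
#' @param img integer array \code{height x width x 3}.
#' @param mask logical matrix, coarse foreground.
#' @param result a [RefinementResult-class] (or a single numeric
#'   threshold).
#' @return logical matrix, refined foreground.
#' @export
refineMask <- function(img, mask, result) {
  d <- if (is(result, "RefinementResult")) result@thresholdD
       else as.numeric(result)
  if (is.na(d)) return(mask)
  out <- mask
  out[img[, , 1] < d] <- FALSE
  out
}

#' Full refinement step
#'
#' Builds the red histogram of the foreground, smooths it, fits the
#' quintic trend line, locates the valley threshold and applies it.
#' With \code{config$perRegionThreshold = TRUE} a separate histogram and
#' threshold is computed for every connected region of the coarse mask;
#' by default one global histogram and one global threshold are used.
#'
#' @param img integer array \code{height x width x 3}.
#' @param mask logical matrix, coarse foreground (must be nonempty).
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return list with \code{mask} (refined logical matrix) and
#'   \code{result} (the global [RefinementResult-class]; for per-region
#'   mode, the result for the largest region).
#' @export
refineSegmentation <- function(img, mask, config = pipelineConfig()) {
  stepOne <- function(m) {
    h <- redHistogram(img, m)
    hs <- gaussianSmoothHistogram(h, config$histSize, config$histSigma)
    res <- findValleyThreshold(fitQuintic(hs))
    list(mask = refineMask(img, m, res), result = res)
  }
  if (!isTRUE(config$perRegionThreshold)) return(stepOne(mask))
  lab <- labelRegions(mask)
  out <- mask & FALSE
  best <- NULL; bestArea <- -1
  for (r in seq_len(nrow(lab$table))) {
    m <- lab$labels == lab$table$label[r]
    s <- stepOne(m)
    out <- out | s$mask
    if (lab$table$area[r] > bestArea) {
      bestArea <- lab$table$area[r]; best <- s$result
    }
  }
  list(mask = out, result = best)
}
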