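#' Candidate germ mask
#'
#' Germ (and reflection) pixels are the bright pixels outside the grain
#' foreground: gray value strictly greater than the threshold (160) in
#' the non-grain part of the image.
#'
#' @param img integer array \code{height x width x 3}.
#' @param grainMask logical matrix, refined grain foreground.
#' @param grayThreshold gray level above which a non-grain pixel is a
#'   germ candidate (default 160, strict inequality).
#' @return logical matrix of candidate germ pixels.
#' @export
germMask <- function(img, grainMask, grayThreshold = 160) {
  stopifnot(identical(dim(grainMask), dim(img)[1:2]))
  !grainMask & toGray(img) > grayThreshold
}

#' Measure germ candidates: area, perimeter and grain contact
#'
#' For every 8-connected component of the germ mask, measures its area
#' \code{s_bud}, its perimeter \code{p} (count of component pixels with
#' at least one 4-neighbor outside the component; image borders count as
#' outside), its grain-intersection length \code{l} (count of those
#' boundary pixels with at least one 8-neighbor in grain foreground),
#' and the set of grain regions so touched. By construction
#' \code{0 <= l <= p}.
#'
#' @param germLabels integer label matrix of germ components (from
#'   [labelRegions()] of the germ mask), or a logical germ mask.
#' @param grainLabels integer label matrix of grain regions; noise
#'   regions should already carry label 0.
#' @return data.frame: \code{label}, \code{area}, \code{perimeter},
#'   \code{intersection}, \code{lpRatio}, \code{nAdjacentGrains}, and a
#'   list column \code{adjacentGrains}.
#' @export
measureContact <- function(germLabels, grainLabels) {
  if (is.logical(germLabels)) germLabels <- labelRegions(germLabels)$labels
  stopifnot(identical(dim(germLabels), dim(grainLabels)))
  k <- max(germLabels)
  empty <- data.frame(label = integer(0), area = integer(0),
                      perimeter = integer(0), intersection = integer(0),
                      lpRatio = numeric(0), nAdjacentGrains = integer(0))
  if (k == 0L) {
    empty$adjacentGrains <- list()
    return(empty)
  }
  nr <- nrow(germLabels); nc <- ncol(germLabels)
  pad <- function(m) {
    out <- matrix(0L, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- m
    out
  }
  gp <- pad(germLabels)
  rp <- pad(grainLabels)
  shift <- function(m, dr, dc)
    as.vector(m[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)])
  own <- as.vector(germLabels)
  inG <- own > 0L

  four <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  boundary <- rep(FALSE, length(own))
  for (d in four)
    boundary <- boundary | (inG & shift(gp, d[1], d[2]) != own)

  eight <- c(four, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  touch <- rep(FALSE, length(own))
  pairs <- vector("list", length(eight))
  for (e in seq_along(eight)) {
    d <- eight[[e]]
    nb <- shift(rp, d[1], d[2])
    hit <- boundary & nb > 0L
    touch <- touch | hit
    pairs[[e]] <- cbind(own[hit], nb[hit])
  }
  pairs <- unique(do.call(rbind, pairs))

  area <- tabulate(own[inG], nbins = k)
  p <- tabulate(own[boundary], nbins = k)
  l <- tabulate(own[boundary & touch], nbins = k)
  adj <- rep(list(integer(0)), k)
  if (length(pairs)) {
    byGerm <- split(pairs[, 2], pairs[, 1])
    adj[as.integer(names(byGerm))] <- lapply(byGerm,
                                             function(v) sort(unique(v)))
  }
  out <- data.frame(label = seq_len(k), area = area, perimeter = p,
                    intersection = l, lpRatio = ifelse(p > 0, l / p, NA),
                    nAdjacentGrains = lengths(adj))
  out$adjacentGrains <- adj
  # label ids need not be contiguous (e.g. ground-truth germ ids)
  out[out$area > 0L, , drop = FALSE]
}

#' Filter germ candidates by area
#'
#' A candidate is a plausible germ only when its area lies strictly
#' between \code{sOpt / 50} and \code{sOpt / 3}: smaller blobs are
#' invisible noise, larger ones are grain-sized and cannot be a germ.
#'
#' @param candidates data.frame from [measureContact()].
#' @param sOpt optimal single-grain area.
#' @param loDivisor,hiDivisor divisors defining the open area window
#'   (defaults 50 and 3).
#' @return the subset of \code{candidates} passing the window.
#' @examples
#' df <- data.frame(label = 1:3, area = c(59, 500, 1000))
#' filterByArea(df, 3000)$label  # 2
#' @export
filterByArea <- function(candidates, sOpt, loDivisor = 50, hiDivisor = 3) {
  stopifnot(sOpt > 0)
  keep <- candidates$area > sOpt / loDivisor &
          candidates$area < sOpt / hiDivisor
  candidates[keep, , drop = FALSE]
}

#' Count germinated grains
#'
#' A measured, area-accepted candidate counts as one germinated grain
#' when it touches at least one grain region (\code{l >= 1}) and its
#' contact ratio \code{l/p} is strictly below \code{ratioMax}: a fully
#' emerged germ shares only a small part of its boundary with the grain,
#' while a germ still inside the hull has a large contact ratio. Each
#' candidate is counted at most once however many grains it touches.
#'
#' @param candidates data.frame from [measureContact()] after
#'   [filterByArea()].
#' @param nGrain total grain count (for the rate).
#' @param ratioMax contact-ratio bound (default 0.4).
#' @return list with \code{nBud}, \code{germinationRate} (\code{NA} and
#'   flagged when \code{nGrain} is 0) and \code{accepted}, a logical
#'   vector over the candidates.
#' @export
countGerminated <- function(candidates, nGrain, ratioMax = 0.4) {
  accepted <- candidates$intersection >= 1L &
              candidates$lpRatio < ratioMax
  accepted[is.na(accepted)] <- FALSE
  nb <- sum(accepted)
  rate <- if (nGrain > 0L) nb / nGrain else NA_real_
  list(nBud = as.integer(nb), germinationRate = rate,
       rateDefined = nGrain > 0L, accepted = accepted)
}
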