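#' @import methods
NULL

#' Sorted area-distribution curve of grain connected regions
#'
#' Holds the ascending-sorted areas of the connected regions of a grain
#' mask, the Gaussian-smoothed curve, its discrete Laplacian, and the two
#' turning points that bracket the single-grain plateau: point A (end of
#' the noise regions) and point B (last stable point before cluster areas
#' take over).
#'
#' @slot areas numeric, region areas sorted ascending (pixels).
#' @slot smoothed numeric, areas after 3-tap Gaussian smoothing.
#' @slot laplacian numeric, discrete Laplacian of the smoothed curve;
#'   endpoints are 0 by convention.
#' @slot indexA,indexB integer, 1-based turning-point indices into
#'   \code{areas}; regions at sorted positions below \code{indexA} are
#'   treated as noise.
#' @slot ordering integer, permutation such that
#'   \code{areas == regionArea[ordering]} for the region table the curve
#'   was built from.
#' @export
setClass("AreaCurve",
  representation(
    areas = "numeric",
    smoothed = "numeric",
    laplacian = "numeric",
    indexA = "integer",
    indexB = "integer",
    ordering = "integer"
  )
)

setValidity("AreaCurve", function(object) {
  m <- length(object@areas)
  msg <- character(0)
  if (m < 1L) msg <- c(msg, "curve must contain at least one region")
  if (is.unsorted(object@areas)) msg <- c(msg, "areas must be ascending")
  if (length(object@smoothed) != m || length(object@laplacian) != m)
    msg <- c(msg, "smoothed and laplacian must match areas in length")
  if (object@indexA < 1L || object@indexB < object@indexA ||
      object@indexB > m)
    msg <- c(msg, "need 1 <= indexA <= indexB <= length(areas)")
  if (length(msg)) msg else TRUE
})

#' Red-histogram valley threshold for refinement segmentation
#'
#' Result of locating the valley between the shadow-border peak and the
#' grain-core peak on the quintic trend line fitted to the red-component
#' histogram of the foreground. When the trend line has fewer than two
#' interior maxima there is no bimodal structure and \code{thresholdD} is
#' \code{NA}: refinement is skipped.
#'
#' @slot thresholdD numeric, red value in 0--255 below which foreground
#'   pixels are reclassified as background, or \code{NA}.
#' @slot peakA,peakB numeric, red values (0--255) of the two dominant
#'   maxima of the trend line (\code{peakA < peakB}), or \code{NA}.
#' @slot valleyC numeric, red value of the minimum of the trend line
#'   strictly between the peaks; equals \code{thresholdD}.
#' @slot trend numeric, the fitted quintic evaluated on red values
#'   0--255 (diagnostics).
#' @export
setClass("RefinementResult",
  representation(
    thresholdD = "numeric",
    peakA = "numeric",
    peakB = "numeric",
    valleyC = "numeric",
    trend = "numeric"
  )
)

setValidity("RefinementResult", function(object) {
  if (!is.na(object@thresholdD)) {
    ok <- object@peakA < object@valleyC && object@valleyC < object@peakB &&
      object@thresholdD == object@valleyC
    if (!ok) return("need peakA < valleyC < peakB and thresholdD == valleyC")
  }
  if (length(object@trend) && length(object@trend) != 256L)
    return("trend must be evaluated on the 256 red values")
  TRUE
})

#' Germination analysis report
#'
#' End-to-end result of the pipeline: total grain count, germinated
#' count, germination rate, the estimated optimal single-grain area with
#' the plateau bounds it came from, the refinement threshold, and
#' per-region / per-candidate audit tables.
#'
#' @slot nGrain integer, total number of grains.
#' @slot nBud integer, number of germinated grains.
#' @slot germinationRate numeric, \code{nBud / nGrain}; \code{NA} when no
#'   grains were found (undefined rate).
#' @slot sOpt numeric, optimal single-grain area (pixels); \code{NA} when
#'   no grains were found.
#' @slot sA,sB numeric, minimum and maximum single-grain areas (the areas
#'   at turning points A and B).
#' @slot thresholdD numeric, refinement threshold (red value), \code{NA}
#'   when refinement was skipped.
#' @slot regions data.frame, one row per grain connected region: label,
#'   area, sorted index, noise flag, grain count.
#' @slot germs data.frame, one row per germ candidate: label, area,
#'   perimeter \code{p}, grain-intersection length \code{l}, \code{l/p},
#'   number of adjacent grain regions, status and reason.
#' @export
setClass("GerminationReport",
  representation(
    nGrain = "integer",
    nBud = "integer",
    germinationRate = "numeric",
    sOpt = "numeric",
    sA = "numeric",
    sB = "numeric",
    thresholdD = "numeric",
    regions = "data.frame",
    germs = "data.frame"
  )
)

setValidity("GerminationReport", function(object) {
  msg <- character(0)
  if (object@nGrain < 0L || object@nBud < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (object@nGrain > 0L) {
    r <- object@germinationRate
    # rate can exceed 1 on pathological scenes where bright noise is
    # miscounted as germs; it can never be negative or undefined
    if (is.na(r) || r < 0)
      msg <- c(msg, "germinationRate must be defined and non-negative
                     when grains exist")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic grain scene
#'
#' Describes a reproducible synthetic photograph of rice grains on a dark
#' background: yellow elliptical grains with darker shadow rims, optional
#' touching clusters, white germ protrusions, and white reflection noise.
#' Build with [sceneSpec()]; render with [generateScene()].
#'
#' @slot seed integer RNG seed.
#' @slot nGrains integer, number of grains.
#' @slot grainAxes numeric(2), grain ellipse semi-axes in pixels.
#' @slot areaJitter numeric, relative jitter on the grain area; both
#'   semi-axes scale by the square root of the drawn factor.
#' @slot adhesionFraction numeric in [0,1], fraction of grains placed in
#'   touching clusters.
#' @slot clusterSizes integer, admissible cluster multiplicities.
#' @slot germinationFraction numeric in [0,1], fraction of grains that
#'   carry a germ.
#' @slot germAxes numeric(2), germ ellipse semi-axes in pixels.
#' @slot borderShadowWidth numeric, width (pixels) of the darkened rim.
#' @slot shadowRed,coreRed numeric, mean red level of rim and core.
#' @slot noiseReflections integer, count of detached white blobs.
#' @slot noiseDroplets integer, count of white droplet blobs attached to
#'   grain edges (a documented false-germ error source).
#' @slot noiseSpecks integer, count of tiny grain-colored specks (noise
#'   regions exercising the point-A exclusion).
#' @slot backgroundLevel numeric(3), background RGB.
#' @slot noiseSd numeric, sd of Gaussian pixel noise (gray levels).
#' @slot imageSize integer(2) or 0-length for automatic sizing.
#' @slot scale numeric, linear scale factor applied to all geometry.
#' @slot antialias logical, render with 2x supersampling (soft edges).
#' @export
setClass("SceneSpec",
  representation(
    seed = "integer",
    nGrains = "integer",
    grainAxes = "numeric",
    areaJitter = "numeric",
    adhesionFraction = "numeric",
    clusterSizes = "integer",
    germinationFraction = "numeric",
    germAxes = "numeric",
    borderShadowWidth = "numeric",
    shadowRed = "numeric",
    coreRed = "numeric",
    noiseReflections = "integer",
    noiseDroplets = "integer",
    noiseSpecks = "integer",
    backgroundLevel = "numeric",
    noiseSd = "numeric",
    imageSize = "integer",
    scale = "numeric",
    antialias = "logical"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  frac <- c(object@adhesionFraction, object@germinationFraction)
  if (any(frac < 0 | frac > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@nGrains < 1L) msg <- c(msg, "need at least one grain")
  if (length(object@grainAxes) != 2L || any(object@grainAxes <= 0))
    msg <- c(msg, "grainAxes must be two positive semi-axes")
  if (length(object@germAxes) != 2L || any(object@germAxes <= 0))
    msg <- c(msg, "germAxes must be two positive semi-axes")
  if (any(object@backgroundLevel < 0 | object@backgroundLevel > 255))
    msg <- c(msg, "backgroundLevel must be RGB in 0-255")
  if (any(object@clusterSizes < 2L))
    msg <- c(msg, "cluster multiplicities must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic grain scene
#'
#' @slot nGrains integer, true grain count.
#' @slot nGerminated integer, true germinated count.
#' @slot grainLabels integer matrix, per-pixel grain id (0 = none).
#' @slot germLabels integer matrix, per-pixel germ id (0 = none); germ id
#'   equals the id of the grain it grows from.
#' @slot clusters data.frame, one row per placed cluster: cluster id and
#'   multiplicity (1 = isolated grain).
#' @export
setClass("GroundTruth",
  representation(
    nGrains = "integer",
    nGerminated = "integer",
    grainLabels = "matrix",
    germLabels = "matrix",
    clusters = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  if (object@nGerminated > object@nGrains)
    return("nGerminated cannot exceed nGrains")
  if (!identical(dim(object@grainLabels), dim(object@germLabels)))
    return("grain and germ label matrices must share dimensions")
  TRUE
})
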