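#' Pipeline configuration
#'
#' All tunable constants of the pipeline with their standard defaults:
#' the feature clip (differences of 60 and above map to 30), the fixed
#' k-means centers (0,0) and (40,40), the histogram smoothing kernel
#' (size 100, sigma 7.5), the area-curve smoothing (3 taps, sigma 0.65),
#' the plateau-jump ratio 1.2, the fractional counting threshold 0.4,
#' the germ gray threshold 160, the germ area window divisors 50 and 3,
#' and the contact-ratio bound 0.4.
#'
#' @param ... named overrides of any default.
#' @return a named list of class \code{grainGermConfig}.
#' @examples
#' cfg <- pipelineConfig(grayThreshold = 170)
#' cfg$grayThreshold
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    clipDelta = 60,
    clipValue = 30,
    kmeansCenters = matrix(c(0, 0, 40, 40), 2, 2, byrow = TRUE),
    kmeansMaxIter = 100L,
    histSize = 100,
    histSigma = 7.5,
    perRegionThreshold = FALSE,
    connectivity = 8L,
    curveLen = 3,
    curveSigma = 0.65,
    pointAMinDip = 0.05,
    ratioThreshold = 1.2,
    pointBConvention = "last-stable",  # or "post-jump"
    smoothedAreasForB = FALSE,
    fractionThreshold = 0.4,
    grayThreshold = 160,
    areaLoDivisor = 50,
    areaHiDivisor = 3,
    lpRatio = 0.4
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "grainGermConfig"
  cfg
}

emptyReport <- function(thresholdD = NA_real_) {
  new("GerminationReport", nGrain = 0L, nBud = 0L,
      germinationRate = NA_real_, sOpt = NA_real_, sA = NA_real_,
      sB = NA_real_, thresholdD = thresholdD,
      regions = data.frame(label = integer(0), area = integer(0),
                           sortedIndex = integer(0), isNoise = logical(0),
                           count = integer(0)),
      germs = data.frame(label = integer(0), area = integer(0),
                         perimeter = integer(0), intersection = integer(0),
                         lpRatio = numeric(0), nAdjacentGrains = integer(0),
                         status = character(0), reason = character(0)))
}

#' Run the full germination-rate pipeline
#'
#' Coarse k-means segmentation, red-histogram refinement, area-curve
#' grain counting, and contact-geometry germ detection, producing a
#' [GerminationReport-class]. Deterministic end to end: the same image
#' always yields the same report. An image with no detectable grains
#' yields a zero-grain report with an undefined rate rather than an
#' error.
#'
#' @param img an RGB image (integer array \code{height x width x 3},
#'   values 0--255) or a path readable by [readRgbImage()].
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return a [GerminationReport-class] object. The attribute
#'   \code{"masks"} carries the refined grain mask and the accepted germ
#'   mask for overlay rendering.
#' @examples
#' scene <- generateScene(sceneSpec(seed = 7, nGrains = 12,
#'                                  germinationFraction = 0.5))
#' runPipeline(scene$image)
#' @export
runPipeline <- function(img, config = pipelineConfig()) {
  if (is.character(img)) img <- readRgbImage(img)
  coarse <- coarseSegment(img, config)
  if (!any(coarse)) return(emptyReport())

  refined <- refineSegmentation(img, coarse, config)
  mask <- refined$mask
  d <- refined$result@thresholdD
  if (!any(mask)) return(emptyReport(d))

  lab <- labelRegions(mask, config$connectivity)
  curve <- buildAreaCurve(lab$table, config)
  cand <- curve@areas[curve@indexA:curve@indexB]
  sopt <- optimalGrainArea(cand)
  counting <- countGrains(curve, lab, sopt, config)

  # grain labels with noise regions zeroed, for germ adjacency
  grainLabels <- lab$labels
  noise <- counting$regions$label[counting$regions$isNoise]
  if (length(noise)) grainLabels[grainLabels %in% noise] <- 0L

  gm <- germMask(img, mask, config$grayThreshold)
  germLab <- labelRegions(gm, config$connectivity)
  measured <- measureContact(germLab$labels, grainLabels)
  inWindow <- measured$area > sopt / config$areaLoDivisor &
              measured$area < sopt / config$areaHiDivisor
  windowed <- measured[inWindow, , drop = FALSE]
  verdict <- countGerminated(windowed, counting$nGrain, config$lpRatio)

  status <- rep("rejected", nrow(measured))
  reason <- ifelse(measured$area <= sopt / config$areaLoDivisor,
                   "area too small",
                   ifelse(measured$area >= sopt / config$areaHiDivisor,
                          "area too large", ""))
  sub <- which(inWindow)
  reason[sub] <- ifelse(verdict$accepted, "",
                        ifelse(windowed$intersection < 1L,
                               "not adjacent to a grain",
                               "contact ratio l/p too large"))
  status[sub][verdict$accepted] <- "accepted"
  germs <- measured[, c("label", "area", "perimeter", "intersection",
                        "lpRatio", "nAdjacentGrains")]
  germs$status <- status
  germs$reason <- reason

  report <- new("GerminationReport",
                nGrain = as.integer(counting$nGrain),
                nBud = verdict$nBud,
                germinationRate = verdict$germinationRate,
                sOpt = as.numeric(sopt),
                sA = curve@areas[curve@indexA],
                sB = curve@areas[curve@indexB],
                thresholdD = d,
                regions = counting$regions,
                germs = germs)
  acceptedLabels <- windowed$label[verdict$accepted]
  attr(report, "masks") <- list(
    grain = mask,
    germ = matrix(germLab$labels %in% acceptedLabels,
                  nrow = nrow(mask)))
  report
}

#' Absolute and relative error of a prediction
#'
#' \code{abs = |A - B|} and \code{rel = |A - B| / A * 100} (percent),
#' where A is the true value and B the predicted one. With A = 0 the
#' relative error is undefined and returned as \code{NA} with
#' \code{relDefined = FALSE}.
#'
#' @param truth true value A.
#' @param predicted predicted value B.
#' @return list with \code{absolute}, \code{relative} (percent) and
#'   \code{relDefined}.
#' @examples
#' evaluateCounts(100, 99)  # absolute 1, relative 1
#' @export
evaluateCounts <- function(truth, predicted) {
  a <- abs(truth - predicted)
  list(absolute = a,
       relative = if (truth != 0) a / truth * 100 else NA_real_,
       relDefined = truth != 0)
}

#' Serialize a report to JSON
#'
#' @param report a [GerminationReport-class] object.
#' @param path output path; omit to return the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
writeReport <- function(report, path = NULL) {
  germs <- report@germs
  obj <- list(
    n_grains = report@nGrain,
    n_germinated = report@nBud,
    germination_rate = report@germinationRate,
    germination_rate_percent = if (is.na(report@germinationRate))
      NA_real_ else 100 * report@germinationRate,
    s_opt = report@sOpt,
    s_A = report@sA,
    s_B = report@sB,
    threshold_d = report@thresholdD,
    regions = report@regions,
    germs = germs
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Batch evaluation over a directory of scenes
#'
#' Runs the pipeline on every PNG in a directory. When a ground-truth
#' JSON (as written by [writeScene()]) sits next to an image, the
#' grain-count relative error and germination-rate absolute error are
#' computed per image and summarized (mean and sd).
#'
#' @param dir directory containing \code{*.png} images and optional
#'   \code{*_truth.json} files.
#' @param config pipeline configuration, see [pipelineConfig()].
#' @return data.frame, one row per image, with a \code{"summary"}
#'   attribute holding mean/sd of both error metrics.
#' @export
batchRun <- function(dir, config = pipelineConfig()) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    rep <- runPipeline(f, config)
    row <- data.frame(image = basename(f), nGrain = rep@nGrain,
                      nBud = rep@nBud, rate = rep@germinationRate,
                      trueGrains = NA_integer_, trueGerminated = NA_integer_,
                      grainRelErrorPct = NA_real_, rateAbsErrorPct = NA_real_)
    tf <- sub("\\.png$", "_truth.json", f)
    if (file.exists(tf)) {
      truth <- jsonlite::fromJSON(tf)
      row$trueGrains <- truth$n_grains
      row$trueGerminated <- truth$n_germinated
      row$grainRelErrorPct <-
        evaluateCounts(truth$n_grains, rep@nGrain)$relative
      trueRate <- truth$n_germinated / truth$n_grains
      predRate <- if (is.na(rep@germinationRate)) 0 else rep@germinationRate
      row$rateAbsErrorPct <- 100 * abs(trueRate - predRate)
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && any(!is.na(out$grainRelErrorPct))) {
    attr(out, "summary") <- list(
      meanGrainRelErrorPct = mean(out$grainRelErrorPct, na.rm = TRUE),
      sdGrainRelErrorPct = stats::sd(out$grainRelErrorPct, na.rm = TRUE),
      meanRateAbsErrorPct = mean(out$rateAbsErrorPct, na.rm = TRUE),
      sdRateAbsErrorPct = stats::sd(out$rateAbsErrorPct, na.rm = TRUE))
  }
  out
}
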