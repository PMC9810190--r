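#' @rdname GerminationReport-class
#' @export
setMethod("nGrain", "GerminationReport", function(x) x@nGrain)

#' @rdname GerminationReport-class
#' @export
setMethod("nBud", "GerminationReport", function(x) x@nBud)

#' @rdname GerminationReport-class
#' @export
setMethod("germinationRate", "GerminationReport",
          function(x) x@germinationRate)

#' @rdname GerminationReport-class
#' @export
setMethod("sOpt", "GerminationReport", function(x) x@sOpt)

#' @rdname GerminationReport-class
#' @export
setMethod("thresholdD", "GerminationReport", function(x) x@thresholdD)

#' @rdname RefinementResult-class
#' @export
setMethod("thresholdD", "RefinementResult", function(x) x@thresholdD)

#' @rdname AreaCurve-class
#' @export
setMethod("areas", "AreaCurve", function(x) x@areas)

#' @rdname GroundTruth-class
#' @export
setMethod("nGrains", "GroundTruth", function(x) x@nGrains)

#' @rdname GroundTruth-class
#' @export
setMethod("nGerminated", "GroundTruth", function(x) x@nGerminated)

setMethod("show", "GerminationReport", function(object) {
  rate <- object@germinationRate
  cat("GerminationReport\n")
  cat("  grains:     ", object@nGrain, "\n", sep = "")
  cat("  germinated: ", object@nBud, "\n", sep = "")
  cat("  rate:       ",
      if (is.na(rate)) "undefined (no grains)"
      else sprintf("%.4f (%.1f%%)", rate, 100 * rate), "\n", sep = "")
  cat("  s_opt:      ",
      if (is.na(object@sOpt)) "NA" else round(object@sOpt), " px",
      "  [s_A = ", round(object@sA), ", s_B = ", round(object@sB), "]\n",
      sep = "")
  cat("  threshold d:",
      if (is.na(object@thresholdD)) " none (refinement skipped)"
      else paste0(" ", object@thresholdD), "\n", sep = "")
  cat("  regions: ", nrow(object@regions),
      "   germ candidates: ", nrow(object@germs), "\n", sep = "")
})

setMethod("show", "AreaCurve", function(object) {
  m <- length(object@areas)
  cat("AreaCurve with ", m, " regions\n", sep = "")
  cat("  point A at index ", object@indexA,
      " (s_A = ", object@areas[object@indexA], ")\n", sep = "")
  cat("  point B at index ", object@indexB,
      " (s_B = ", object@areas[object@indexB], ")\n", sep = "")
})

setMethod("show", "RefinementResult", function(object) {
  if (is.na(object@thresholdD)) {
    cat("RefinementResult: no bimodal structure, refinement skipped\n")
  } else {
    cat("RefinementResult: peaks at red ", object@peakA, " and ",
        object@peakB, ", valley threshold d = ", object@thresholdD,
        "\n", sep = "")
  }
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec: ", object@nGrains, " grains (seed ", object@seed, ")\n",
      "  adhesion ", object@adhesionFraction,
      ", germination ", object@germinationFraction,
      ", grain semi-axes ", paste(object@grainAxes, collapse = "x"),
      " px\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", object@nGrains, " grains, ",
      object@nGerminated, " germinated (rate ",
      sprintf("%.3f", object@nGerminated / object@nGrains), ")\n", sep = "")
})
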