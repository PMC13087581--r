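#' @rdname WellTimeseries-class
setMethod("wellId", "WellTimeseries", function(object) object@wellId)

#' @rdname WellTimeseries-class
setMethod("signalKind", "WellTimeseries", function(object) object@signalKind)

#' @rdname curveTimes
setMethod("curveTimes", "WellTimeseries", function(object) object@times)

#' @rdname curveTimes
setMethod("curveValues", "WellTimeseries", function(object) object@values)

#' @rdname curveTimes
setMethod("curveTimes", "GrowthCurve", function(object) object@times)

#' @rdname curveTimes
setMethod("curveValues", "GrowthCurve", function(object) object@values)

#' @rdname GrowthCurve-class
setMethod("curveId", "GrowthCurve", function(object) object@curveId)

#' @rdname GrowthCurve-class
setMethod("construct", "GrowthCurve", function(object) object@construct)

#' @rdname GrowthCurve-class
setMethod("medium", "GrowthCurve", function(object) object@medium)

#' @rdname GrowthCurve-class
setMethod("bioReplicate", "GrowthCurve", function(object) object@bioReplicate)

#' @rdname GrowthCurve-class
setMethod("stages", "GrowthCurve", function(object) object@stage)

#' @rdname GrowthCurve-class
setMethod("curveId", "GrowthMetrics", function(object) object@curveId)

#' @rdname GrowthCurve-class
setMethod("construct", "GrowthMetrics", function(object) object@construct)

#' @rdname GrowthCurve-class
setMethod("medium", "GrowthMetrics", function(object) object@medium)

#' @rdname GrowthCurve-class
setMethod("bioReplicate", "GrowthMetrics",
          function(object) object@bioReplicate)

#' @rdname carryingCapacity
setMethod("carryingCapacity", "LogisticFit", function(object) object@K)

#' @rdname carryingCapacity
setMethod("growthRate", "LogisticFit", function(object) object@r)

#' @rdname carryingCapacity
setMethod("initialPopulation", "LogisticFit", function(object) object@N0)

#' @rdname carryingCapacity
setMethod("maxGrowthRate", "LogisticFit",
          function(object) object@r * object@K / 4)

#' @rdname carryingCapacity
setMethod("carryingCapacity", "GrowthMetrics",
          function(object) object@carryingCapacity)

#' @rdname carryingCapacity
setMethod("growthRate", "GrowthMetrics", function(object) object@fit@r)

#' @rdname carryingCapacity
setMethod("initialPopulation", "GrowthMetrics", function(object) object@fit@N0)

#' @rdname carryingCapacity
setMethod("maxGrowthRate", "GrowthMetrics",
          function(object) object@maxGrowthRate)

#' @rdname maxSlopeTime
setMethod("maxSlopeTime", "GrowthMetrics", function(object) {
  structure(object@maxSlopeTime, boundary = object@boundaryInflection)
})

#' @rdname lagTime
setMethod("lagTime", "GrowthMetrics", function(object) {
  structure(object@lagTime, boundary = object@boundaryInflection)
})

#' @rdname GroupComparison-class
setMethod("uStatistic", "GroupComparison", function(object) object@U)

#' @rdname GroupComparison-class
setMethod("pValue", "GroupComparison", function(object) object@pValue)

setMethod("show", "PlateLayout", function(object) {
  e <- object@entries
  cat(sprintf("PlateLayout: %d wells (%d sample, %d blank)\n",
              nrow(e), sum(e$role == "sample"), sum(e$role == "blank")))
  smp <- e[e$role == "sample", , drop = FALSE]
  if (nrow(smp))
    cat("  constructs:", paste(unique(smp$construct), collapse = ", "), "\n",
        " media:", paste(unique(e$medium), collapse = ", "), "\n")
})

setMethod("show", "WellTimeseries", function(object) {
  cat(sprintf("WellTimeseries %s [%s]: %d points, 0-%.2f h, signal %.3g-%.3g\n",
              object@wellId, object@signalKind, length(object@times),
              max(object@times), min(object@values), max(object@values)))
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve %s: %d points, stages [%s]\n", object@curveId,
              length(object@times), paste(object@stage, collapse = " > ")))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf(
    "LogisticFit: K = %.4g, N0 = %.4g, r = %.4g /h (sse %.4g, %s, n = %d)\n",
    object@K, object@N0, object@r, object@sse,
    if (object@converged) "converged" else "NOT converged", object@nPoints))
})

setMethod("show", "GrowthMetrics", function(object) {
  cat(sprintf("GrowthMetrics %s:\n", object@curveId))
  cat(sprintf("  max slope time  %8.3f h%s\n", object@maxSlopeTime,
              if (object@boundaryInflection) "  (boundary)" else ""))
  cat(sprintf("  lag time        %8.3f h\n", object@lagTime))
  cat(sprintf("  max growth rate %8.4g /h\n", object@maxGrowthRate))
  cat(sprintf("  carrying cap.   %8.4g\n", object@carryingCapacity))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison [%s] %s (n=%d) vs %s (n=%d): U = %g, p = %.4g (%s%s)\n",
    object@metric, object@groupA, object@nA, object@groupB, object@nB,
    object@U, object@pValue, object@method,
    if (object@degenerate) ", degenerate" else ""))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig [%s]: %g h at %.4g h cadence, seed %d\n",
              object@mode, object@durationH, object@samplingIntervalH,
              object@seed))
  cat(sprintf("  %d group(s): %s; noise sd %.3g K, peak %s\n",
              nrow(object@groups),
              paste(object@groups$construct, collapse = ", "),
              object@noiseSd,
              if (object@peakEnabled) sprintf("a=%.2g", object@peakAmplitude)
              else "off"))
})
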