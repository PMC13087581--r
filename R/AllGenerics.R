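#' @rdname WellTimeseries-class
#' @param object a plategrowth object.
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))

#' @rdname WellTimeseries-class
#' @export
setGeneric("signalKind", function(object) standardGeneric("signalKind"))

#' @rdname GrowthCurve-class
#' @param object a plategrowth object.
#' @export
setGeneric("curveId", function(object) standardGeneric("curveId"))

#' @rdname GrowthCurve-class
#' @export
setGeneric("construct", function(object) standardGeneric("construct"))

#' @rdname GrowthCurve-class
#' @export
setGeneric("medium", function(object) standardGeneric("medium"))

#' @rdname GrowthCurve-class
#' @export
setGeneric("bioReplicate", function(object) standardGeneric("bioReplicate"))

#' @rdname GrowthCurve-class
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))

#' Extract times and values
#'
#' @param object a [WellTimeseries-class] or [GrowthCurve-class].
#' @return numeric vector of elapsed hours / signal values.
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))

#' @rdname curveTimes
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))

#' Fitted-model quantities
#'
#' Accessors for [LogisticFit-class] and [GrowthMetrics-class]:
#' \code{carryingCapacity} (K), \code{growthRate} (r),
#' \code{initialPopulation} (N0), \code{maxGrowthRate} (r K / 4).
#'
#' @param object a fit or metrics object.
#' @return a single numeric.
#' @export
setGeneric("carryingCapacity",
           function(object) standardGeneric("carryingCapacity"))

#' @rdname carryingCapacity
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname carryingCapacity
#' @export
setGeneric("initialPopulation",
           function(object) standardGeneric("initialPopulation"))

#' @rdname carryingCapacity
#' @export
setGeneric("maxGrowthRate", function(object) standardGeneric("maxGrowthRate"))

#' Maximum-slope time of a fitted logistic model
#'
#' For a logistic fit with K > 2 N0 the growth rate dN/dt is maximal at the
#' interior inflection time log((K - N0) / N0) / r, where the population
#' equals K/2. When K <= 2 N0 the slope over observable time t >= 0 is
#' maximal at t = 0; the method then returns 0 with attribute
#' \code{boundary = TRUE} (a negative closed-form time is not observable in
#' the assay).
#'
#' @param object a [LogisticFit-class] (computed) or [GrowthMetrics-class]
#'   (stored).
#' @return hours; attribute \code{boundary} flags the K <= 2 N0 case.
#' @examples
#' fit <- new("LogisticFit", K = 1000, N0 = 1, r = 0.1, sse = 0,
#'            converged = TRUE, nPoints = 100L, message = "")
#' maxSlopeTime(fit)  # log(999)/0.1 = 69.0675
#' @export
setGeneric("maxSlopeTime", function(object) standardGeneric("maxSlopeTime"))

#' Lag time of a fitted logistic model
#'
#' The lag phase is the period after inoculation with little net population
#' growth. It is quantified by the classical tangent construction: the
#' tangent to N(t) at the inflection point is intersected with the
#' horizontal line N = N0, giving
#' t_lag = mu - 2/r + 4 N0 / (r K), clipped below at 0, where mu is
#' [maxSlopeTime()]. For boundary-inflection fits (K <= 2 N0) the lag time
#' is 0 with attribute \code{boundary = TRUE}.
#'
#' @param object a [LogisticFit-class] or [GrowthMetrics-class].
#' @return hours.
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))

#' @rdname GroupComparison-class
#' @param object a [GroupComparison-class].
#' @export
setGeneric("uStatistic", function(object) standardGeneric("uStatistic"))

#' @rdname GroupComparison-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
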