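#' @import methods
NULL

.SIGNAL_KINDS <- c("RNU", "OD600")
.LAYOUT_ROLES <- c("sample", "blank")
.STAGES <- c("blank_corrected", "control_normalized", "clamped", "rebased",
             "smoothed", "averaged")

#' PlateLayout: well-to-condition mapping for one plate run
#'
#' Maps well addresses to construct, growth medium, biological and technical
#' replicate identity, and role (\code{"sample"} or \code{"blank"}). Blank
#' wells carry non-inoculated medium and need no construct; every sample well
#' must name a construct and a medium.
#'
#' @slot entries data.frame with columns \code{well}, \code{construct},
#'   \code{medium}, \code{bio_replicate}, \code{tech_replicate}, \code{role}.
#' @seealso [readLayout()], [simulatePlate()]
#' @export
setClass("PlateLayout", slots = c(entries = "data.frame"))

setValidity("PlateLayout", function(object) {
  e <- object@entries
  need <- c("well", "construct", "medium", "bio_replicate", "tech_replicate",
            "role")
  miss <- setdiff(need, names(e))
  if (length(miss))
    return(paste("layout is missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(e$well))
    return(paste("duplicate well id(s):",
                 paste(unique(e$well[duplicated(e$well)]), collapse = ", ")))
  bad <- setdiff(unique(e$role), .LAYOUT_ROLES)
  if (length(bad))
    return(paste("unknown role token(s):", paste(bad, collapse = ", ")))
  if (any(is.na(e$medium) | !nzchar(e$medium)))
    return("every entry (including blanks) must carry a medium label")
  smp <- e[e$role == "sample", , drop = FALSE]
  if (nrow(smp) && any(is.na(smp$construct) | !nzchar(smp$construct)))
    return("sample wells must name a construct")
  if (nrow(smp) &&
      (any(!is.finite(smp$bio_replicate) | smp$bio_replicate < 1) ||
       any(!is.finite(smp$tech_replicate) | smp$tech_replicate < 1)))
    return("sample replicate indices must be positive integers")
  TRUE
})

#' WellTimeseries: the raw signal trace of one well
#'
#' Times are elapsed hours from the well's first measurement (so
#' \code{times[1] == 0}), strictly increasing, with at least 5 points (the
#' smallest window the smoother accepts).
#'
#' @slot wellId well address, e.g. "A1".
#' @slot times numeric, elapsed hours.
#' @slot values numeric signal, same length as \code{times}.
#' @slot signalKind \code{"RNU"} (nephelometry) or \code{"OD600"}
#'   (spectrophotometry).
#' @export
setClass("WellTimeseries",
         slots = c(wellId = "character", times = "numeric",
                   values = "numeric", signalKind = "character"))

setValidity("WellTimeseries", function(object) {
  if (length(object@wellId) != 1L || !nzchar(object@wellId))
    return("wellId must be a single non-empty string")
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) < 5L)
    return(sprintf("well %s has %d points; at least 5 are required",
                   object@wellId, length(object@times)))
  if (any(diff(object@times) <= 0))
    return(sprintf("well %s: times must be strictly increasing",
                   object@wellId))
  if (abs(object@times[1L]) > 1e-9)
    return(sprintf("well %s: times must start at 0 (elapsed hours)",
                   object@wellId))
  if (!(object@signalKind %in% .SIGNAL_KINDS))
    return(paste("signalKind must be one of",
                 paste(.SIGNAL_KINDS, collapse = ", ")))
  TRUE
})

#' GrowthCurve: a preprocessed, analysis-ready growth trace
#'
#' One curve per biological replicate after the correction chain; the
#' \code{stage} slot records which preprocessing steps have been applied, in
#' order, and no step may appear twice.
#'
#' @slot curveId label, typically "construct/medium/bio<k>".
#' @slot construct,medium character labels.
#' @slot bioReplicate integer biological replicate index.
#' @slot techReplicate integer technical replicate index, or NA after
#'   technical averaging.
#' @slot times,values the processed trace.
#' @slot stage character vector, subset of
#'   blank_corrected, control_normalized, clamped, rebased, smoothed, averaged.
#' @export
setClass("GrowthCurve",
         slots = c(curveId = "character", construct = "character",
                   medium = "character", bioReplicate = "integer",
                   techReplicate = "integer", times = "numeric",
                   values = "numeric", stage = "character"))

setValidity("GrowthCurve", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (anyDuplicated(object@stage))
    return("a preprocessing stage cannot be applied twice")
  bad <- setdiff(object@stage, .STAGES)
  if (length(bad))
    return(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' LogisticFit: fitted logistic growth model for one curve
#'
#' Parameters of N(t) = K / (1 + ((K - N0)/N0) exp(-r t)) estimated by
#' bounded least squares; all three parameters are constrained positive.
#'
#' @slot K carrying capacity (signal units).
#' @slot N0 population at time zero (signal units).
#' @slot r growth rate (per hour).
#' @slot sse sum of squared residuals.
#' @slot converged logical optimizer status.
#' @slot nPoints number of fitted points.
#' @slot message optimizer status message.
#' @seealso [fitLogistic()], [maxSlopeTime()], [lagTime()]
#' @export
setClass("LogisticFit",
         slots = c(K = "numeric", N0 = "numeric", r = "numeric",
                   sse = "numeric", converged = "logical",
                   nPoints = "integer", message = "character"))

setValidity("LogisticFit", function(object) {
  for (s in c("K", "N0", "r")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single positive finite number", s))
  }
  if (object@sse < 0) return("sse must be non-negative")
  TRUE
})

#' GrowthMetrics: derived scalar metrics for one growth curve
#'
#' @slot curveId,construct,medium character labels; bioReplicate integer.
#' @slot maxSlopeTime model inflection time, hours (0 when the inflection
#'   lies at or before t = 0, see \code{boundaryInflection}).
#' @slot lagTime tangent-construction lag time, hours.
#' @slot maxGrowthRate model slope at inflection, r K / 4, signal units/h.
#' @slot carryingCapacity fitted K.
#' @slot empiricalMaxSlopeTime data-level maximum forward-difference slope
#'   time, hours.
#' @slot boundaryInflection TRUE when K <= 2 N0, i.e. the logistic slope is
#'   maximal at t = 0 over observable time.
#' @slot fit the underlying [LogisticFit-class].
#' @slot stage preprocessing provenance copied from the curve.
#' @export
setClass("GrowthMetrics",
         slots = c(curveId = "character", construct = "character",
                   medium = "character", bioReplicate = "integer",
                   maxSlopeTime = "numeric", lagTime = "numeric",
                   maxGrowthRate = "numeric", carryingCapacity = "numeric",
                   empiricalMaxSlopeTime = "numeric",
                   boundaryInflection = "logical", fit = "LogisticFit",
                   stage = "character"))

#' GroupComparison: Mann-Whitney U comparison of a metric between two groups
#'
#' @slot metric metric label, e.g. "max_slope_time".
#' @slot groupA,groupB construct labels.
#' @slot nA,nB sample sizes.
#' @slot U the test statistic, min(U_A, U_B); the complementary value is
#'   nA*nB - U.
#' @slot pValue two-sided p-value.
#' @slot method "exact" or "normal_approx".
#' @slot degenerate TRUE when all values are identical across both groups
#'   (p is then 1 by convention).
#' @export
setClass("GroupComparison",
         slots = c(metric = "character", groupA = "character",
                   groupB = "character", nA = "integer", nB = "integer",
                   U = "numeric", pValue = "numeric", method = "character",
                   degenerate = "logical"))

setValidity("GroupComparison", function(object) {
  if (object@U < 0 || object@U > object@nA * object@nB / 2 + 1e-9)
    return("U must lie in [0, nA*nB/2] under the minimum convention")
  if (!(object@pValue > 0 && object@pValue <= 1))
    return("p-value must lie in (0, 1]")
  if (!(object@method %in% c("exact", "normal_approx")))
    return("method must be 'exact' or 'normal_approx'")
  TRUE
})

#' SimulationConfig: parameters of the synthetic plate generator
#'
#' Defaults emulate the nephelometric assay design: 10-minute sampling over
#' 180 h, 3 biological x 3 technical replicates per construct, triplicate
#' non-inoculated blanks, an empty-vector background-growth control group,
#' and (in nephelometric mode) a multiplicative peak-then-decline scattering
#' artifact. Use [simulationConfig()] to construct.
#'
#' @slot mode "nephelometric" or "spectrophotometric".
#' @slot durationH assay duration, hours.
#' @slot samplingIntervalH sampling cadence, hours.
#' @slot groups data.frame: construct, K, r, mu (true max-slope time, h),
#'   n_bio, n_tech.
#' @slot controlConstruct label of the background-growth control group.
#' @slot controlBackground named numeric c(K, r) for the control group;
#'   length 0 disables control wells.
#' @slot blankLevel baseline signal of non-inoculated medium.
#' @slot noiseSd Gaussian noise sd, as a fraction of each group's K.
#' @slot bioRateCv sd of the lognormal per-biological-replicate multiplier
#'   on r.
#' @slot peakEnabled,peakAmplitude,peakOnset,peakDecay the nephelometric
#'   peak artifact: factor 1 + a (N/K) exp(-decay * max(0, t - t_onset)),
#'   with t_onset the first time N(t) >= onset * K.
#' @slot blankDrift linear blank drift, signal units per hour (0 = none).
#' @slot testMedium medium label given to simulated wells.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
         slots = c(mode = "character", durationH = "numeric",
                   samplingIntervalH = "numeric", groups = "data.frame",
                   controlConstruct = "character",
                   controlBackground = "numeric", blankLevel = "numeric",
                   noiseSd = "numeric", bioRateCv = "numeric",
                   peakEnabled = "logical", peakAmplitude = "numeric",
                   peakOnset = "numeric", peakDecay = "numeric",
                   blankDrift = "numeric", testMedium = "character",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!(object@mode %in% c("nephelometric", "spectrophotometric")))
    return("mode must be 'nephelometric' or 'spectrophotometric'")
  if (object@durationH <= 0 || object@samplingIntervalH <= 0)
    return("durationH and samplingIntervalH must be positive")
  g <- object@groups
  need <- c("construct", "K", "r", "mu", "n_bio", "n_tech")
  if (!all(need %in% names(g)))
    return(paste("groups needs columns:", paste(need, collapse = ", ")))
  if (nrow(g) && (any(g$K <= 0) || any(g$r <= 0) || any(g$mu <= 0)))
    return("group K, r and mu must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@peakAmplitude < 0) return("peakAmplitude must be >= 0")
  if (length(object@controlBackground) &&
      (length(object@controlBackground) != 2 ||
       any(object@controlBackground <= 0)))
    return("controlBackground must be empty or positive c(K, r)")
  TRUE
})

#' RunConfig: configuration of an end-to-end pipeline run
#'
#' Exactly one input source must be present: either CSV paths (timeseries +
#' layout) or a [SimulationConfig-class]. Use [runConfig()] to construct.
#'
#' @slot timeseriesPath,layoutPath input CSV paths (length 0 when simulating).
#' @slot simConfig list holding one SimulationConfig (empty when reading).
#' @slot signalKind "RNU" or "OD600".
#' @slot testMedium medium whose samples get control normalization.
#' @slot controlConstruct negative-control construct label; NA disables
#'   control normalization.
#' @slot comparisons list of character pairs of constructs to compare.
#' @slot metric metric compared between groups.
#' @slot unit statistical unit: "bio" (technical replicates averaged, the
#'   default) or "tech" (each technical replicate is a unit).
#' @slot outDir output directory.
#' @slot seed integer seed.
#' @slot verbose logical.
#' @export
setClass("RunConfig",
         slots = c(timeseriesPath = "character", layoutPath = "character",
                   simConfig = "list", signalKind = "character",
                   testMedium = "character", controlConstruct = "character",
                   comparisons = "list", metric = "character",
                   unit = "character", outDir = "character",
                   seed = "integer", verbose = "logical"))

setValidity("RunConfig", function(object) {
  hasPaths <- length(object@timeseriesPath) == 1L
  hasSim <- length(object@simConfig) == 1L
  if (hasPaths == hasSim)
    return("exactly one of (timeseriesPath + layoutPath, simConfig) must be given")
  if (hasPaths && length(object@layoutPath) != 1L)
    return("layoutPath is required alongside timeseriesPath")
  if (hasSim && !is(object@simConfig[[1L]], "SimulationConfig"))
    return("simConfig must hold a SimulationConfig")
  if (!(object@signalKind %in% .SIGNAL_KINDS))
    return("signalKind must be 'RNU' or 'OD600'")
  if (!(object@unit %in% c("bio", "tech")))
    return("unit must be 'bio' or 'tech'")
  TRUE
})
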