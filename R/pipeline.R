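## End-to-end orchestration: (simulate | read) -> preprocess -> fit ->
## metrics -> group comparisons -> CSV outputs + run manifest.

# stable non-cryptographic hash of the deparsed config, for run provenance
.configHash <- function(object) {
  s <- paste(deparse(object), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Construct a pipeline run configuration
#'
#' Exactly one input source must be given: \code{timeseriesPath} +
#' \code{layoutPath}, or \code{simConfig}.
#'
#' @param timeseriesPath,layoutPath input CSVs (see [readTimeseries()],
#'   [readLayout()]).
#' @param simConfig a [SimulationConfig-class] to generate inputs instead.
#' @param signalKind "RNU" or "OD600".
#' @param testMedium medium whose samples are control-normalized.
#' @param controlConstruct negative-control construct; NA disables
#'   normalization.
#' @param comparisons list of character pairs c(groupA, groupB); NULL
#'   compares all pairs of non-control constructs.
#' @param metric metric for the group comparisons.
#' @param unit statistical unit, "bio" (default; technical replicates are
#'   averaged before fitting) or "tech" (one unit per technical replicate).
#' @param outDir output directory.
#' @param seed integer seed (also used for simulation).
#' @param verbose log each stage per curve.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(timeseriesPath = NULL, layoutPath = NULL,
                      simConfig = NULL, signalKind = "RNU",
                      testMedium = "citrulline", controlConstruct = "ccdB",
                      comparisons = NULL, metric = "max_slope_time",
                      unit = c("bio", "tech"), outDir = "plategrowth-out",
                      seed = 1L, verbose = FALSE) {
  unit <- match.arg(unit)
  new("RunConfig",
      timeseriesPath = as.character(timeseriesPath %||% character()),
      layoutPath = as.character(layoutPath %||% character()),
      simConfig = if (is.null(simConfig)) list() else list(simConfig),
      signalKind = signalKind, testMedium = testMedium,
      controlConstruct = as.character(controlConstruct),
      comparisons = comparisons %||% list(), metric = metric, unit = unit,
      outDir = outDir, seed = as.integer(seed), verbose = verbose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end growth-curve pipeline
#'
#' Reads (or simulates) a plate, runs the preprocessing chain, fits the
#' logistic model to every curve, derives the growth metrics, compares the
#' requested construct pairs, and writes \code{metrics.csv},
#' \code{comparisons.csv} and \code{run_manifest.txt} (config echo, config
#' hash, seed, package version, stage provenance) to the output directory.
#' When simulating, the simulated inputs are also written
#' (\code{timeseries.csv}, \code{layout.csv}, \code{ground_truth.csv}).
#' No timestamps are written, so a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config a [RunConfig-class].
#' @return invisibly, list(metrics, comparisons, paths).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  log <- function(...) if (config@verbose) message(sprintf(...))

  if (length(config@simConfig)) {
    sc <- config@simConfig[[1L]]
    log("simulating plate (mode %s, seed %d)", sc@mode, config@seed)
    sim <- simulatePlate(sc, seed = config@seed)
    traces <- sim$traces
    layout <- sim$layout
    writeSimulation(sim, config@outDir)
  } else {
    log("reading %s", config@timeseriesPath)
    traces <- readTimeseries(config@timeseriesPath, config@signalKind)
    layout <- readLayout(config@layoutPath)
  }

  curves <- preprocessPipeline(
    traces, layout, testMedium = config@testMedium,
    controlConstruct = if (length(config@controlConstruct) &&
                             !is.na(config@controlConstruct))
      config@controlConstruct else NA_character_,
    averageTechnical = config@unit == "bio")
  for (cv in curves)
    log("curve %s: stages [%s]", cv@curveId, paste(cv@stage, collapse = " > "))

  metrics <- lapply(curves, function(cv) {
    fit <- fitLogistic(cv)
    log("curve %s: K=%.4g r=%.4g mu=%.3f h%s", cv@curveId, fit@K, fit@r,
        as.numeric(maxSlopeTime(fit)),
        if (fit@converged) "" else " (not converged)")
    computeMetrics(fit, cv)
  })
  if (!length(metrics))
    stop("no sample curves produced; nothing to analyze", call. = FALSE)

  pairs <- config@comparisons
  if (!length(pairs)) {
    cons <- unique(vapply(metrics, construct, character(1L)))
    pairs <- if (length(cons) >= 2L)
      utils::combn(cons, 2L, simplify = FALSE) else list()
  }
  comparisons <- lapply(pairs, function(p)
    compareConstructs(metrics, config@metric, p[[1L]], p[[2L]]))

  paths <- writeResults(metrics, comparisons, config@outDir)
  manifest <- file.path(config@outDir, "run_manifest.txt")
  writeLines(c(
    sprintf("plategrowth version: %s",
            as.character(utils::packageVersion("plategrowth"))),
    sprintf("config hash: %s", .configHash(config)),
    sprintf("seed: %d", config@seed),
    sprintf("statistical unit: %s", config@unit),
    sprintf("metric: %s", config@metric),
    "stage provenance:",
    vapply(metrics, function(m) sprintf("  %s: %s", m@curveId,
                                        paste(m@stage, collapse = " > ")),
           character(1L)),
    "config:",
    paste0("  ", deparse(config))), manifest)
  invisible(list(metrics = metrics, comparisons = comparisons,
                 paths = c(paths, manifest = manifest)))
}
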