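## Synthetic plate generator. Emulates the liquid complementation assay:
## logistic growth with group-specific inflection times, triplicate
## non-inoculated blanks, an empty-vector background-growth control group,
## 3 bio x 3 tech replicates per construct, and (nephelometric mode) a
## multiplicative peak-then-decline scattering artifact.

#' Construct a simulation configuration
#'
#' Defaults depend on \code{mode}. Nephelometric: 10-minute sampling
#' (1/6 h) over 180 h, the peak artifact enabled. Spectrophotometric:
#' 12-hour sampling (twice daily, ~15 points), no peak artifact, heavier
#' noise (manual cuvette measurements).
#'
#' The default groups are two transporter constructs with equal carrying
#' capacity and growth rate but different true maximum-slope times (65 vs
#' 72 h), i.e. the biologically interesting contrast is a lag difference.
#' Each well's N0 is solved exactly from the group's (K, r, mu) via
#' N0 = K / (1 + exp(r mu)); biological replicates perturb r by a lognormal
#' multiplier with sd \code{bioRateCv} on the log scale (3\% day-to-day
#' rate variability between independent cultures), and the per-replicate
#' true mu is recomputed from the closed form, so ground truth stays exact.
#'
#' @param mode "nephelometric" or "spectrophotometric".
#' @param durationH assay length, hours.
#' @param samplingIntervalH cadence, hours.
#' @param groups data.frame with columns construct, K, r, mu, n_bio, n_tech.
#' @param controlConstruct label for the background-growth control group.
#' @param controlBackground c(K, r) of the control group (N0 = 1
#'   inoculum convention); NULL disables control wells.
#' @param blankLevel baseline signal of non-inoculated medium.
#' @param noiseSd Gaussian noise sd as a fraction of the group's K (blank
#'   wells use the same fraction of \code{blankLevel}).
#' @param bioRateCv sd of the lognormal biological-replicate effect on r.
#' @param peakEnabled,peakAmplitude,peakOnset,peakDecay nephelometric
#'   artifact: signal factor 1 + a (N/K) exp(-decay max(0, t - t_onset))
#'   with t_onset the first time N(t) >= onset K.
#' @param blankDrift linear blank drift, signal units/h.
#' @param testMedium medium label written into the layout.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(mode = c("nephelometric", "spectrophotometric"),
                             durationH = 180,
                             samplingIntervalH = NULL,
                             groups = NULL,
                             controlConstruct = "ccdB",
                             controlBackground = c(K = 50, r = 0.05),
                             blankLevel = 10,
                             noiseSd = NULL,
                             bioRateCv = 0.03,
                             peakEnabled = NULL,
                             peakAmplitude = 0.3,
                             peakOnset = 0.5,
                             peakDecay = 0.02,
                             blankDrift = 0,
                             testMedium = "citrulline",
                             seed = 1L) {
  mode <- match.arg(mode)
  neph <- mode == "nephelometric"
  if (is.null(samplingIntervalH)) samplingIntervalH <- if (neph) 1 / 6 else 12
  if (is.null(noiseSd)) noiseSd <- if (neph) 0.02 else 0.05
  if (is.null(peakEnabled)) peakEnabled <- neph
  if (is.null(groups))
    groups <- data.frame(
      construct = c("AtLHT1", "PtrLHT1.2"),
      K = c(1000, 1000), r = c(0.1, 0.1), mu = c(65, 72),
      n_bio = 3L, n_tech = 3L, stringsAsFactors = FALSE)
  if (is.null(controlBackground)) controlBackground <- numeric()
  new("SimulationConfig", mode = mode, durationH = durationH,
      samplingIntervalH = samplingIntervalH, groups = groups,
      controlConstruct = controlConstruct,
      controlBackground = controlBackground, blankLevel = blankLevel,
      noiseSd = noiseSd, bioRateCv = bioRateCv,
      peakEnabled = peakEnabled, peakAmplitude = peakAmplitude,
      peakOnset = peakOnset, peakDecay = peakDecay,
      blankDrift = blankDrift, testMedium = testMedium,
      seed = as.integer(seed))
}

.simTimes <- function(config)
  seq(0, config@durationH, by = config@samplingIntervalH)

# All group rows including the background-growth control, with each group's
# N0 solved from (K, r, mu); the control uses the N0 = 1 inoculum convention.
.simGroups <- function(config) {
  g <- config@groups
  g$N0 <- g$K / (1 + exp(g$r * g$mu))
  if (length(config@controlBackground) == 2L) {
    cb <- config@controlBackground
    g <- rbind(g, data.frame(
      construct = config@controlConstruct, K = cb[[1L]], r = cb[[2L]],
      mu = log(pmax(cb[[1L]] - 1, 1e-12)) / cb[[2L]], n_bio = 3L,
      n_tech = 3L, N0 = 1, stringsAsFactors = FALSE))
  }
  g
}

#' Simulate the signal trace of one well
#'
#' Noiseless base signal: blank level (+ optional drift) plus the logistic
#' population N(t; K, N0, r). In nephelometric mode with the peak artifact
#' enabled, N(t) is multiplied by
#' 1 + a (N/K) exp(-decay max(0, t - t_onset)) — a density-gated
#' amplification of the scattering signal that relaxes exponentially,
#' producing the characteristic peak, decline and plateau. Gaussian noise
#' with sd \code{noiseSd * K} is added. Uses the current RNG state; seed the
#' RNG (or use [simulatePlate()]) for reproducibility.
#'
#' @param config a [SimulationConfig-class].
#' @param construct group label (must be in the config's groups or be the
#'   control construct).
#' @param bio,tech replicate indices (metadata only).
#' @param rate realized growth rate for this well's biological replicate;
#'   default the group-level r.
#' @param wellId well address to stamp on the trace.
#' @return a [WellTimeseries-class]; attribute \code{truth} carries the
#'   named vector c(K, N0, r, mu) actually simulated.
#' @export
simulateWell <- function(config, construct, bio = 1L, tech = 1L,
                         rate = NULL, wellId = "A1") {
  g <- .simGroups(config)
  row <- g[g$construct == construct, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("unknown group '%s'", construct), call. = FALSE)
  t <- .simTimes(config)
  r <- if (is.null(rate)) row$r else rate
  N <- logisticEval(row$K, row$N0, r, t)
  if (config@peakEnabled && config@mode == "nephelometric") {
    onsetIdx <- which(N >= config@peakOnset * row$K)
    tOnset <- if (length(onsetIdx)) t[onsetIdx[1L]] else Inf
    N <- N * (1 + config@peakAmplitude * (N / row$K) *
                exp(-config@peakDecay * pmax(0, t - tOnset)))
  }
  values <- config@blankLevel + config@blankDrift * t + N +
    stats::rnorm(length(t), 0, config@noiseSd * row$K)
  mu <- if (row$K > 2 * row$N0) log((row$K - row$N0) / row$N0) / r else 0
  structure(new("WellTimeseries", wellId = wellId, times = t,
                values = values, signalKind = if (config@mode ==
                  "nephelometric") "RNU" else "OD600"),
            truth = c(K = row$K, N0 = row$N0, r = r, mu = mu))
}

#' Simulate a full plate with layout and ground truth
#'
#' Emits n_bio x n_tech sample wells per group (including the
#' background-growth control group, if configured), plus triplicate blank
#' wells (baseline + noise only). Well positions are drawn at random from
#' the 96-well grid — sample positions vary between simulated runs — but
#' deterministically for a given seed. Biological-replicate rates are drawn
#' once per (group, bio) and shared by that replicate's technical wells.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides \code{config@seed}.
#' @return list with \code{traces} (list of [WellTimeseries-class]),
#'   \code{layout} (a [PlateLayout-class]) and \code{truth} (data.frame:
#'   well, construct, medium, bio_replicate, tech_replicate, K, N0, r,
#'   mu_true — one row per sample well).
#' @examples
#' sim <- simulatePlate(simulationConfig(seed = 7))
#' length(sim$traces)  # 2*9 samples + 9 control + 3 blanks = 30
#' @export
simulatePlate <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(as.integer(seed))
  g <- .simGroups(config)
  nSample <- sum(g$n_bio * g$n_tech)
  nWells <- nSample + 3L
  grid <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, 8L))
  if (nWells > length(grid))
    stop(sprintf("layout needs %d wells; a 96-well plate has 96", nWells),
         call. = FALSE)
  pos <- sample(grid, nWells)

  # per-(group, bio) lognormal rate effects, drawn in fixed order
  rates <- list()
  for (i in seq_len(nrow(g)))
    rates[[g$construct[i]]] <- g$r[i] *
      exp(stats::rnorm(g$n_bio[i], 0, config@bioRateCv))

  traces <- list(); layoutRows <- list(); truthRows <- list()
  w <- 0L
  for (i in seq_len(nrow(g))) {
    for (b in seq_len(g$n_bio[i])) {
      rBio <- rates[[g$construct[i]]][b]
      for (k in seq_len(g$n_tech[i])) {
        w <- w + 1L
        tr <- simulateWell(config, g$construct[i], b, k, rate = rBio,
                           wellId = pos[w])
        traces[[pos[w]]] <- tr
        layoutRows[[w]] <- data.frame(
          well = pos[w], construct = g$construct[i],
          medium = config@testMedium, bio_replicate = b, tech_replicate = k,
          role = "sample", stringsAsFactors = FALSE)
        tru <- attr(tr, "truth")
        truthRows[[w]] <- data.frame(
          well = pos[w], construct = g$construct[i],
          medium = config@testMedium, bio_replicate = b, tech_replicate = k,
          K = tru[["K"]], N0 = tru[["N0"]], r = tru[["r"]],
          mu_true = tru[["mu"]], stringsAsFactors = FALSE)
      }
    }
  }
  t <- .simTimes(config)
  sk <- if (config@mode == "nephelometric") "RNU" else "OD600"
  for (j in 1:3) {
    w <- w + 1L
    values <- config@blankLevel + config@blankDrift * t +
      stats::rnorm(length(t), 0, config@noiseSd * config@blankLevel)
    traces[[pos[w]]] <- new("WellTimeseries", wellId = pos[w], times = t,
                            values = values, signalKind = sk)
    layoutRows[[w]] <- data.frame(
      well = pos[w], construct = NA_character_, medium = config@testMedium,
      bio_replicate = NA_integer_, tech_replicate = NA_integer_,
      role = "blank", stringsAsFactors = FALSE)
  }
  list(traces = traces,
       layout = new("PlateLayout", entries = do.call(rbind, layoutRows)),
       truth = do.call(rbind, truthRows))
}

#' Write a simulated plate to CSV files
#'
#' Writes \code{timeseries.csv}, \code{layout.csv} and
#' \code{ground_truth.csv} in the dialects read by [readTimeseries()] and
#' [readLayout()].
#'
#' @param sim result of [simulatePlate()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  long <- do.call(rbind, lapply(sim$traces, function(tr)
    data.frame(well = tr@wellId, time_h = tr@times, value = tr@values,
               stringsAsFactors = FALSE)))
  paths <- c(timeseries = file.path(dir, "timeseries.csv"),
             layout = file.path(dir, "layout.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(long, paths[["timeseries"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$layout@entries, paths[["layout"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
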