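## Correction and preprocessing chain, applied per technical replicate in
## this order: blank correction -> (test-medium samples only) negative-control
## normalization -> pre-minimum clamping -> initial-value rebasing ->
## Savitzky-Golay smoothing -> technical-replicate averaging.

# shared-grid check: every time point within half the median sampling
# interval of the reference grid
.sameGrid <- function(t1, t2) {
  if (length(t1) != length(t2)) return(FALSE)
  tol <- stats::median(diff(t1)) / 2
  all(abs(t1 - t2) <= tol)
}

#' Blank-correct a well trace
#'
#' Subtracts, at each time point, the mean signal of the non-inoculated blank
#' wells of the same growth medium. Negative results are retained (clamping
#' and rebasing handle them downstream). Blanks must share the trace's time
#' grid to within half a sampling interval.
#'
#' @param trace a [WellTimeseries-class].
#' @param blanks non-empty list of blank [WellTimeseries-class] on the same
#'   medium and grid.
#' @return the corrected [WellTimeseries-class].
#' @export
blankCorrect <- function(trace, blanks) {
  if (!length(blanks))
    stop(sprintf("no blank wells available for trace %s", trace@wellId),
         call. = FALSE)
  for (b in blanks)
    if (!.sameGrid(trace@times, b@times))
      stop(sprintf(
        "blank %s is not on the same time grid as trace %s (tolerance: half a sampling interval)",
        b@wellId, trace@wellId), call. = FALSE)
  bm <- rowMeans(vapply(blanks, slot, numeric(length(trace@times)), "values"))
  initialize(trace, values = trace@values - bm)
}

#' Normalize a test-medium trace by the negative-control background
#'
#' Subtracts the per-time-point mean of the (blank-corrected) empty-vector
#' negative-control traces from a test-medium sample trace, removing
#' background growth that does not reflect transporter activity. Applied
#' only to traces from the test medium; for any other medium the trace is
#' returned unchanged with a warning.
#'
#' @param trace blank-corrected [WellTimeseries-class].
#' @param controls non-empty list of blank-corrected control traces on the
#'   same medium and grid.
#' @param medium the trace's medium label (from the layout).
#' @param testMedium medium to which normalization applies.
#' @return the normalized [WellTimeseries-class].
#' @export
controlNormalize <- function(trace, controls, medium = "citrulline",
                             testMedium = "citrulline") {
  if (!identical(medium, testMedium)) {
    warning(sprintf(
      "control normalization applies to the test medium ('%s'); trace %s is on '%s' and was left unchanged",
      testMedium, trace@wellId, medium), call. = FALSE)
    return(trace)
  }
  if (!length(controls))
    stop(sprintf("no negative-control traces available for trace %s",
                 trace@wellId), call. = FALSE)
  for (b in controls)
    if (!.sameGrid(trace@times, b@times))
      stop(sprintf("control %s is not on the same time grid as trace %s",
                   b@wellId, trace@wellId), call. = FALSE)
  cm <- rowMeans(vapply(controls, slot, numeric(length(trace@times)),
                        "values"))
  initialize(trace, values = trace@values - cm)
}

#' Clamp all values before the curve minimum
#'
#' Finds the global minimum of the sequence and sets every value before its
#' first occurrence in time to that minimum. Values at and after the first
#' minimum are unchanged. Idempotent and total.
#'
#' @param values numeric sequence.
#' @return clamped numeric sequence.
#' @examples
#' clampPreMinimum(c(5, 3, 2, 4, 9))  # 2 2 2 4 9
#' @export
clampPreMinimum <- function(values) {
  stopifnot(length(values) > 0L)
  i <- which.min(values)  # first occurrence
  if (i > 1L) values[seq_len(i - 1L)] <- values[i]
  values
}

#' Rebase a clamped sequence so the initial population is 1 unit
#'
#' Additive shift: \code{v - v[1] + 1}. All pairwise differences (and hence
#' the empirical maximum-slope time) are preserved; a multiplicative
#' rescaling would distort blank-corrected values near zero.
#'
#' @param values numeric sequence, already clamped.
#' @return shifted sequence with \code{values[1] == 1} exactly.
#' @export
rebaseInitial <- function(values) {
  stopifnot(length(values) > 0L)
  values - values[1L] + 1
}

#' Savitzky-Golay window size for n samples
#'
#' The smallest odd integer >= max(5, round(0.10 n)): the filter window
#' covers 10\% of the samples, rounded, made odd, with floor 5.
#'
#' @param n number of samples.
#' @return odd integer window length.
#' @examples
#' sgWindow(1008)  # 101
#' sgWindow(14)    # 5
#' @export
sgWindow <- function(n) {
  w <- max(5L, as.integer(round(0.10 * n)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Smooth a growth curve with a Savitzky-Golay filter
#'
#' Local least-squares polynomial smoothing of order 2 with window
#' [sgWindow()] (10\% of the samples). An order-2 filter reproduces any
#' quadratic signal exactly, so curvature at the inflection is preserved.
#' Terminal points are fitted within one-sided windows at the sequence ends;
#' no data is fabricated by padding. The time grid must be uniform to within
#' 10\% of the median step (plate readers jitter by seconds against a
#' 10-minute cadence).
#'
#' @param values numeric sequence, length >= 5.
#' @param times matching time grid, hours.
#' @return smoothed sequence, same length.
#' @export
savgolSmooth <- function(values, times) {
  n <- length(values)
  if (n < 5L)
    stop("at least 5 points are required for smoothing", call. = FALSE)
  stopifnot(length(times) == n)
  dt <- diff(times)
  m <- stats::median(dt)
  if (any(abs(dt - m) > 0.10 * m))
    stop("time grid deviates more than 10% from the median sampling interval; cannot smooth",
         call. = FALSE)
  as.numeric(signal::sgolayfilt(values, p = 2, n = sgWindow(n)))
}

#' Average technical-replicate growth curves
#'
#' Pointwise arithmetic mean of curves sharing a time grid and a
#' (construct, medium, biological replicate) identity. The result carries
#' the biological-replicate identity and gains the \code{"averaged"} stage.
#'
#' @param curves non-empty list of [GrowthCurve-class].
#' @return one [GrowthCurve-class].
#' @export
averageReplicates <- function(curves) {
  stopifnot(length(curves) >= 1L)
  ref <- curves[[1L]]
  for (cv in curves[-1L]) {
    if (!.sameGrid(ref@times, cv@times))
      stop("cannot average curves on different time grids", call. = FALSE)
    if (!identical(cv@construct, ref@construct) ||
        !identical(cv@medium, ref@medium) ||
        !identical(cv@bioReplicate, ref@bioReplicate))
      stop("cannot average curves from different (construct, medium, bio_replicate) groups",
           call. = FALSE)
  }
  vals <- rowMeans(vapply(curves, slot, numeric(length(ref@times)), "values"))
  new("GrowthCurve",
      curveId = sprintf("%s/%s/bio%d", ref@construct, ref@medium,
                        ref@bioReplicate),
      construct = ref@construct, medium = ref@medium,
      bioReplicate = ref@bioReplicate, techReplicate = NA_integer_,
      times = ref@times, values = vals,
      stage = unique(c(ref@stage, "averaged")))
}

#' Run the full preprocessing chain on a plate
#'
#' Per technical-replicate well: blank correction against the mean of the
#' same-medium blank wells; for samples on the test medium, subtraction of
#' the mean background growth of the negative-control construct
#' (blank-corrected); pre-minimum clamping; rebasing of the initial
#' population to 1 unit; Savitzky-Golay smoothing. Technical replicates are
#' then averaged into one [GrowthCurve-class] per
#' (construct, medium, biological replicate).
#'
#' Negative-control wells on the test medium are consumed as the
#' normalization reference and are not returned as sample curves (their
#' normalized mean is identically zero by construction); on other media they
#' are processed like any construct.
#'
#' @param traces list of [WellTimeseries-class] (e.g. from
#'   [readTimeseries()]).
#' @param layout a [PlateLayout-class] covering every trace.
#' @param testMedium medium whose sample curves are control-normalized.
#' @param controlConstruct negative-control construct label; \code{NA}
#'   disables control normalization.
#' @param averageTechnical average technical replicates (default). With
#'   \code{FALSE}, one curve per technical replicate is returned (used when
#'   the statistical unit is the technical replicate).
#' @return list of [GrowthCurve-class], one per sample group (or per
#'   technical replicate).
#' @export
preprocessPipeline <- function(traces, layout, testMedium = "citrulline",
                               controlConstruct = "ccdB",
                               averageTechnical = TRUE) {
  stopifnot(is(layout, "PlateLayout"))
  e <- layout@entries
  byWell <- setNames(traces, vapply(traces, wellId, character(1L)))
  miss <- setdiff(names(byWell), e$well)
  if (length(miss))
    stop(sprintf("layout does not cover well(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  e <- e[e$well %in% names(byWell), , drop = FALSE]

  # blank correction, per medium
  corrected <- list()
  for (i in seq_len(nrow(e))) {
    if (e$role[i] != "sample") next
    bw <- e$well[e$role == "blank" & e$medium == e$medium[i]]
    blanks <- byWell[intersect(bw, names(byWell))]
    if (!length(blanks))
      stop(sprintf("no blank wells for medium '%s' (needed by well %s)",
                   e$medium[i], e$well[i]), call. = FALSE)
    corrected[[e$well[i]]] <- tryCatch(
      blankCorrect(byWell[[e$well[i]]], blanks),
      error = function(err) stop(sprintf("well %s: %s", e$well[i],
                                         conditionMessage(err)),
                                 call. = FALSE))
  }
  smp <- e[e$role == "sample", , drop = FALSE]

  # negative-control normalization on the test medium
  doNorm <- !is.na(controlConstruct) &&
    any(smp$medium == testMedium & smp$construct != controlConstruct)
  if (doNorm) {
    ctlWells <- smp$well[smp$medium == testMedium &
                           smp$construct == controlConstruct]
    if (!length(ctlWells))
      stop(sprintf(
        "control normalization requested but no '%s' wells found on medium '%s'",
        controlConstruct, testMedium), call. = FALSE)
    ctl <- corrected[ctlWells]
    for (w in smp$well[smp$medium == testMedium &
                         smp$construct != controlConstruct])
      corrected[[w]] <- controlNormalize(corrected[[w]], ctl,
                                         medium = testMedium,
                                         testMedium = testMedium)
  }

  # clamp -> rebase -> smooth, per technical replicate
  keep <- smp
  if (!is.na(controlConstruct))
    keep <- keep[!(keep$medium == testMedium &
                     keep$construct == controlConstruct), , drop = FALSE]
  perTech <- lapply(seq_len(nrow(keep)), function(i) {
    w <- keep$well[i]
    tr <- corrected[[w]]
    v <- clampPreMinimum(tr@values)
    v <- rebaseInitial(v)
    v <- tryCatch(savgolSmooth(v, tr@times),
                  error = function(err) stop(sprintf("well %s: %s", w,
                                                     conditionMessage(err)),
                                             call. = FALSE))
    st <- c("blank_corrected",
            if (doNorm && keep$medium[i] == testMedium) "control_normalized",
            "clamped", "rebased", "smoothed")
    new("GrowthCurve",
        curveId = sprintf("%s/%s/bio%d/tech%d", keep$construct[i],
                          keep$medium[i], keep$bio_replicate[i],
                          keep$tech_replicate[i]),
        construct = keep$construct[i], medium = keep$medium[i],
        bioReplicate = as.integer(keep$bio_replicate[i]),
        techReplicate = as.integer(keep$tech_replicate[i]),
        times = tr@times, values = v, stage = st)
  })
  if (!averageTechnical) return(perTech)

  key <- vapply(perTech, function(cv)
    sprintf("%s/%s/bio%d", cv@construct, cv@medium, cv@bioReplicate),
    character(1L))
  unname(lapply(split(perTech, factor(key, levels = unique(key))),
                averageReplicates))
}
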