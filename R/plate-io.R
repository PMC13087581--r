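## Long-format plate reader I/O. Dialects:
##   timeseries CSV: well,time_h,value          (UTF-8, decimal point)
##   layout CSV:     well,construct,medium,bio_replicate,tech_replicate,role

# "A01" and "A1" both occur in plate exports; normalize to unpadded.
.normalizeWell <- function(well) {
  well <- toupper(trimws(as.character(well)))
  sub("^([A-H])0+([1-9])", "\\1\\2", well)
}

.checkColumns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read a long-format plate time-series CSV
#'
#' Expects columns \code{well,time_h,value}. Rows are grouped by well and
#' sorted by time; each well's times are rebased so its earliest measurement
#' is 0 elapsed hours (all downstream computations depend only on elapsed
#' time). Row order in the file is irrelevant.
#'
#' @param path CSV file path.
#' @param signalKind \code{"RNU"} or \code{"OD600"}.
#' @return named list of [WellTimeseries-class], one per distinct well.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(well = rep("A1", 6), time_h = 0:5 / 6,
#'                      value = c(1, 1, 2, 4, 8, 9)), tf, row.names = FALSE)
#' readTimeseries(tf, "RNU")
#' @export
readTimeseries <- function(path, signalKind = c("RNU", "OD600")) {
  signalKind <- match.arg(signalKind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("well", "time_h", "value"), path)
  df$well <- .normalizeWell(df$well)
  if (!is.numeric(df$time_h) || !is.numeric(df$value) ||
      anyNA(df$time_h) || anyNA(df$value))
    stop(sprintf("'%s': time_h and value must be fully numeric", path),
         call. = FALSE)
  if (any(df$time_h < 0))
    stop(sprintf("'%s': negative time in well %s", path,
                 df$well[which(df$time_h < 0)[1L]]), call. = FALSE)
  dup <- duplicated(df[c("well", "time_h")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate (well, time) row: well %s at t = %g h",
                 df$well[i], df$time_h[i]), call. = FALSE)
  }
  traces <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (nrow(d) < 5L)
      stop(sprintf("well %s has only %d point(s); at least 5 are required",
                   d$well[1L], nrow(d)), call. = FALSE)
    new("WellTimeseries", wellId = d$well[1L],
        times = d$time_h - d$time_h[1L], values = d$value,
        signalKind = signalKind)
  })
  traces[order(names(traces))]
}

#' Read a plate-layout CSV
#'
#' Expects columns
#' \code{well,construct,medium,bio_replicate,tech_replicate,role}. An empty
#' role defaults to \code{"sample"}; blank wells may omit construct and
#' replicate indices but must carry a medium.
#'
#' @param path CSV file path.
#' @return a validated [PlateLayout-class].
#' @export
readLayout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(well = "character"))
  .checkColumns(df, c("well", "construct", "medium", "bio_replicate",
                      "tech_replicate", "role"), path)
  df$well <- .normalizeWell(df$well)
  df$role <- trimws(as.character(df$role))
  df$role[is.na(df$role) | !nzchar(df$role)] <- "sample"
  df$construct <- as.character(df$construct)
  df$medium <- as.character(df$medium)
  df$bio_replicate <- suppressWarnings(as.integer(df$bio_replicate))
  df$tech_replicate <- suppressWarnings(as.integer(df$tech_replicate))
  new("PlateLayout", entries = df)
}

#' Table views of metrics and comparisons
#'
#' Flatten lists of [GrowthMetrics-class] / [GroupComparison-class] into the
#' data.frames serialized by [writeResults()]. Column order is stable and
#' documented there.
#'
#' @param metrics list of GrowthMetrics.
#' @return a data.frame.
#' @export
metricsTable <- function(metrics) {
  stopifnot(length(metrics) > 0L)
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(curve_id = m@curveId, construct = m@construct,
               medium = m@medium, bio_replicate = m@bioReplicate,
               K = m@fit@K, N0 = m@fit@N0, r = m@fit@r,
               max_slope_time_h = m@maxSlopeTime,
               lag_time_h = m@lagTime,
               max_growth_rate = m@maxGrowthRate,
               sse = m@fit@sse, converged = m@fit@converged,
               empirical_max_slope_time_h = m@empiricalMaxSlopeTime,
               stages = paste(m@stage, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname metricsTable
#' @param comparisons list of GroupComparison.
#' @export
comparisonsTable <- function(comparisons) {
  if (!length(comparisons))
    return(data.frame(metric = character(), group_a = character(),
                      group_b = character(), n_a = integer(), n_b = integer(),
                      U = numeric(), p_value = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(comparisons, function(cc) {
    data.frame(metric = cc@metric, group_a = cc@groupA, group_b = cc@groupB,
               n_a = cc@nA, n_b = cc@nB, U = cc@U, p_value = cc@pValue,
               method = cc@method, stringsAsFactors = FALSE)
  }))
}

#' Write per-curve metrics and group comparisons to CSV
#'
#' Writes \code{metrics.csv} with columns
#' \code{curve_id, construct, medium, bio_replicate, K, N0, r,
#' max_slope_time_h, lag_time_h, max_growth_rate, sse, converged,
#' empirical_max_slope_time_h, stages} and \code{comparisons.csv} with
#' columns \code{metric, group_a, group_b, n_a, n_b, U, p_value, method}.
#' Numbers are written with 15 significant digits so a re-read reproduces
#' them to at least 12. The run manifest written by [runPipeline()] carries
#' the config hash and seed identifying these files.
#'
#' @param metrics non-empty list of [GrowthMetrics-class].
#' @param comparisons list of [GroupComparison-class] (may be empty).
#' @param path output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeResults <- function(metrics, comparisons, path) {
  if (!length(metrics))
    stop("metrics list is empty; nothing to write", call. = FALSE)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  mPath <- file.path(path, "metrics.csv")
  cPath <- file.path(path, "comparisons.csv")
  .writeCsv15 <- function(df, f) {
    num <- vapply(df, is.double, logical(1L))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                  trim = TRUE,
                                                  scientific = FALSE))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  }
  .writeCsv15(metricsTable(metrics), mPath)
  .writeCsv15(comparisonsTable(comparisons), cPath)
  invisible(c(metrics = mPath, comparisons = cPath))
}
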