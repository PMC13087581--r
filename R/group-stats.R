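## Mann-Whitney U rank test: exact small-sample null (counting all rank
## subsets) and tie/continuity-corrected normal approximation.

.uCache <- new.env(parent = emptyenv())

# Null counts of U_a for sample sizes (na, nb), no ties: counts[u + 1] is the
# number of the C(na+nb, na) rank subsets with U_a = u. Built by scanning
# ranks 1..n in order; choosing rank i as the k-th smallest of group a
# contributes (i - k) to U_a. Equivalent to full enumeration of all subsets.
.uNullCounts <- function(na, nb) {
  key <- sprintf("%d_%d", na, nb)
  if (!is.null(.uCache[[key]])) return(.uCache[[key]])
  n <- na + nb
  maxU <- na * nb
  f <- matrix(0, nrow = na + 1L, ncol = maxU + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    for (k in seq(min(i, na), 1L)) {
      shift <- i - k
      if (shift > maxU) next
      idx <- seq_len(maxU + 1L - shift)
      f[k + 1L, idx + shift] <- f[k + 1L, idx + shift] + f[k, idx]
    }
  }
  counts <- f[na + 1L, ]
  .uCache[[key]] <- counts
  counts
}

#' Mann-Whitney U test for two independent samples
#'
#' Nonparametric rank test for a location difference. Midranks are used for
#' ties; U_a = R_a - n_a (n_a + 1) / 2 with R_a the rank sum of \code{x},
#' and the reported statistic is U = min(U_a, U_b) (classical-table
#' convention; the opposite direction is n_a n_b - U). The two-sided p-value
#' doubles the exact lower-tail probability P(U <= observed) under the
#' permutation null — computed by counting all C(n_a + n_b, n_a) rank
#' subsets — whenever n_a n_b <= 400 and the pooled data are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. If all values are identical across both groups the
#' comparison is degenerate and p = 1.
#'
#' @param x,y numeric samples (each non-empty).
#' @param metric,groupA,groupB labels stored in the result.
#' @param exactLimit use the exact null when \code{length(x) * length(y)}
#'   is at most this and there are no ties.
#' @return a [GroupComparison-class].
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, metric = "value", groupA = "A", groupB = "B",
                         exactLimit = 400L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(c(x, y))) stop("samples contain NA", call. = FALSE)
  na <- length(x); nb <- length(y); n <- na + nb
  pooled <- c(x, y)

  if (all(pooled == pooled[1L]))
    return(new("GroupComparison", metric = metric, groupA = groupA,
               groupB = groupB, nA = na, nB = nb, U = na * nb / 2,
               pValue = 1, method = "normal_approx", degenerate = TRUE))

  rk <- rank(pooled)  # midranks
  Ra <- sum(rk[seq_len(na)])
  Ua <- Ra - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && na * nb <= exactLimit) {
    counts <- .uNullCounts(na, nb)
    p <- 2 * sum(counts[seq_len(round(U) + 1L)]) / sum(counts)
    method <- "exact"
  } else {
    tg <- table(pooled)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(tg^3 - tg) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(Ua - na * nb / 2) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal_approx"
  }
  new("GroupComparison", metric = metric, groupA = groupA, groupB = groupB,
      nA = na, nB = nb, U = U, pValue = min(1, p), method = method,
      degenerate = FALSE)
}

#' Compare a growth metric between two construct groups
#'
#' Extracts the named metric from each group's [GrowthMetrics-class] records
#' and runs [mannWhitneyU()]. The statistical units are whatever curves the
#' metrics were computed on — by default one per biological replicate, since
#' technical replicates are averaged upstream.
#'
#' @param metrics list of [GrowthMetrics-class].
#' @param metricName one of \code{"max_slope_time"}, \code{"lag_time"},
#'   \code{"max_growth_rate"}, \code{"carrying_capacity"},
#'   \code{"empirical_max_slope_time"}.
#' @param groupA,groupB construct labels.
#' @return a [GroupComparison-class].
#' @export
compareConstructs <- function(metrics, metricName = "max_slope_time",
                              groupA, groupB) {
  slots <- c(max_slope_time = "maxSlopeTime", lag_time = "lagTime",
             max_growth_rate = "maxGrowthRate",
             carrying_capacity = "carryingCapacity",
             empirical_max_slope_time = "empiricalMaxSlopeTime")
  if (!metricName %in% names(slots))
    stop(sprintf("unknown metric '%s'; use one of: %s", metricName,
                 paste(names(slots), collapse = ", ")), call. = FALSE)
  cons <- vapply(metrics, construct, character(1L))
  pick <- function(g) {
    sel <- metrics[cons == g]
    if (!length(sel))
      stop(sprintf("no curves for construct '%s'", g), call. = FALSE)
    vapply(sel, slot, numeric(1L), slots[[metricName]])
  }
  mannWhitneyU(pick(groupA), pick(groupB), metric = metricName,
               groupA = groupA, groupB = groupB)
}
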