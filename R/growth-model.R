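## Logistic growth model N(t) = K / (1 + ((K - N0)/N0) exp(-r t)), fitted by
## bounded least squares; K = carrying capacity, N0 = N(0), r = growth rate.

#' Evaluate the logistic growth model
#'
#' @param K carrying capacity (> 0).
#' @param N0 population at time zero (> 0).
#' @param r growth rate per hour (> 0).
#' @param t time(s), hours.
#' @return N(t), same length as \code{t}.
#' @examples
#' logisticEval(100, 1, 0.1, 0)               # 1
#' logisticEval(100, 1, 0.1, log(99) / 0.1)   # 50 (inflection: K/2)
#' @export
logisticEval <- function(K, N0, r, t) {
  if (any(c(K, N0, r) <= 0) || any(!is.finite(c(K, N0, r))))
    stop("K, N0 and r must be positive", call. = FALSE)
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

#' Empirical maximum-slope time of a growth trace
#'
#' Forward-difference slopes s_i = (v[i+1] - v[i]) / (t[i+1] - t[i]); returns
#' the midpoint of the interval with the largest slope, ties broken by the
#' earliest interval. A flat trace (all slopes equal and zero) returns the
#' first midpoint with attribute \code{degenerate = TRUE}.
#'
#' @param curve a [GrowthCurve-class], or a numeric value sequence (then
#'   \code{times} is required).
#' @param times time grid in hours when \code{curve} is numeric.
#' @return time in hours (possibly with attribute \code{degenerate}).
#' @export
empiricalMaxSlopeTime <- function(curve, times = NULL) {
  if (is(curve, "GrowthCurve")) {
    v <- curve@values; t <- curve@times
  } else {
    v <- as.numeric(curve); t <- times
  }
  stopifnot(length(v) >= 3L, length(t) == length(v))
  s <- diff(v) / diff(t)
  mid <- (t[-1L] + t[-length(t)]) / 2
  if (all(abs(s - s[1L]) < 1e-15) && abs(s[1L]) < 1e-15)
    return(structure(mid[1L], degenerate = TRUE))
  mid[which.max(s)]  # which.max takes the earliest maximal interval
}

#' Initial parameter values for the logistic fit
#'
#' K0 and N0_0 are the maximum and minimum of the curve; the initial rate is
#' obtained by solving the logistic form at the empirical maximum-slope time
#' mu: r0 = log((K0 - N0_0) / N0_0) / mu. When that logarithm's argument is
#' <= 1 (K0 <= 2 N0_0) or mu <= 0 the expression is non-positive or
#' undefined, and r0 falls back to 1 / (time span) — any positive rate of
#' order 1/T lets the optimizer proceed.
#'
#' @param curve a preprocessed [GrowthCurve-class].
#' @return named numeric c(K, N0, r).
#' @export
initParameters <- function(curve) {
  v <- curve@values
  K0 <- max(v)
  N00 <- min(v)
  if (K0 <= N00)
    stop(sprintf("no growth signal in curve %s (flat trace)", curve@curveId),
         call. = FALSE)
  # smoothing can undershoot slightly; the model needs N0 > 0
  N00 <- max(N00, 1e-9 * K0)
  mu <- as.numeric(empiricalMaxSlopeTime(curve))
  span <- diff(range(curve@times))
  r0 <- if ((K0 - N00) / N00 > 1 && mu > 0) log((K0 - N00) / N00) / mu
        else 1 / span
  c(K = K0, N0 = N00, r = r0)
}

#' Fit the logistic growth model by bounded least squares
#'
#' Minimizes the sum of squared residuals between the model and the
#' preprocessed curve over (K, N0, r), all constrained positive (box lower
#' bound 1e-12), starting from [initParameters()]. Levenberg-Marquardt via
#' \pkg{minpack.lm}, relative function tolerance 1e-10, at most 10^4
#' evaluations. On non-convergence the best-found parameters are still
#' returned with \code{converged = FALSE}.
#'
#' @param curve a preprocessed [GrowthCurve-class] with >= 5 points.
#' @return a [LogisticFit-class].
#' @examples
#' t <- seq(0, 180, by = 1)
#' cv <- new("GrowthCurve", curveId = "ex", construct = "A", medium = "m",
#'           bioReplicate = 1L, techReplicate = NA_integer_, times = t,
#'           values = logisticEval(500, 1, 0.08, t), stage = character())
#' fitLogistic(cv)
#' @export
fitLogistic <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  if (length(curve@values) < 5L)
    stop("at least 5 points are required to fit", call. = FALSE)
  p0 <- initParameters(curve)
  t <- curve@times; v <- curve@values
  res <- minpack.lm::nls.lm(
    par = p0, lower = rep(1e-12, 3L),
    fn = function(p) p[1L] / (1 + ((p[1L] - p[2L]) / p[2L]) *
                                exp(-p[3L] * t)) - v,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxfev = 10000L,
                                         maxiter = 1000L))
  p <- res$par
  new("LogisticFit", K = unname(p[1L]), N0 = unname(p[2L]),
      r = unname(p[3L]), sse = sum(res$fvec^2),
      converged = res$info %in% 1:3, nPoints = length(v),
      message = res$message)
}

#' @rdname maxSlopeTime
setMethod("maxSlopeTime", "LogisticFit", function(object) {
  K <- object@K; N0 <- object@N0; r <- object@r
  if (K > 2 * N0) structure(log((K - N0) / N0) / r, boundary = FALSE)
  else structure(0, boundary = TRUE)
})

#' @rdname lagTime
setMethod("lagTime", "LogisticFit", function(object) {
  K <- object@K; N0 <- object@N0; r <- object@r
  if (K <= 2 * N0) return(structure(0, boundary = TRUE))
  mu <- log((K - N0) / N0) / r
  structure(max(0, mu - 2 / r + 4 * N0 / (r * K)), boundary = FALSE)
})

#' Bundle the derived growth metrics for one curve
#'
#' Combines the model-level maximum-slope time and lag time, the maximum
#' growth rate r K / 4 (the logistic slope at its inflection), the carrying
#' capacity, and the data-level empirical maximum-slope time.
#'
#' @param fit a [LogisticFit-class].
#' @param curve the [GrowthCurve-class] the fit was computed from.
#' @return a [GrowthMetrics-class].
#' @export
computeMetrics <- function(fit, curve) {
  mu <- maxSlopeTime(fit)
  lt <- lagTime(fit)
  new("GrowthMetrics", curveId = curve@curveId, construct = curve@construct,
      medium = curve@medium, bioReplicate = curve@bioReplicate,
      maxSlopeTime = as.numeric(mu), lagTime = as.numeric(lt),
      maxGrowthRate = fit@r * fit@K / 4, carryingCapacity = fit@K,
      empiricalMaxSlopeTime = as.numeric(empiricalMaxSlopeTime(curve)),
      boundaryInflection = isTRUE(attr(mu, "boundary")), fit = fit,
      stage = curve@stage)
}
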