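test_that("logisticEval matches its closed-form anchors", {
  expect_equal(logisticEval(100, 1, 0.1, 0), 1)
  expect_equal(logisticEval(100, 1, 0.1, 1000), 100, tolerance = 1e-9)
  expect_equal(logisticEval(100, 1, 0.1, log(99) / 0.1), 50)
  expect_error(logisticEval(-1, 1, 0.1, 0), "positive")
  expect_error(logisticEval(100, 0, 0.1, 0), "positive")
})

test_that("empiricalMaxSlopeTime finds the steepest forward difference", {
  expect_equal(empiricalMaxSlopeTime(c(1, 2, 4, 8, 9), 0:4), 2.5)

  t <- seq(0, 180, by = 1 / 6)
  v <- logisticVals(1000, 1, 0.1, t)
  expect_lt(abs(empiricalMaxSlopeTime(v, t) - log(999) / 0.1), 1 / 6)

  flat <- empiricalMaxSlopeTime(rep(2, 6), 0:5)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_equal(as.numeric(flat), 0.5)  # first interval midpoint
})

test_that("initParameters inverts the logistic at the empirical slope time", {
  t <- seq(0, 180, by = 1 / 6)
  cv <- makeCurve(logisticVals(1000, 1, 0.1, t), t)
  p0 <- initParameters(cv)
  # K0 is the curve maximum: the logistic at t = 180, a hair under K
  expect_equal(unname(p0["K"]), 1000, tolerance = 1e-4)
  expect_equal(unname(p0["N0"]), 1, tolerance = 1e-6)
  expect_equal(unname(p0["r"]), 0.1, tolerance = 1e-3)

  # K0 <= 2 N0_0: log argument <= 1, fallback to 1/span
  shallow <- makeCurve(logisticVals(100, 50, 0.1, t), t)
  expect_equal(unname(initParameters(shallow)["r"]), 1 / 180)

  expect_error(initParameters(makeCurve(rep(3, 10), (0:9))), "no growth")
})

test_that("fitLogistic recovers noiseless generator parameters", {
  t <- seq(0, 180, by = 1 / 6)
  cv <- makeCurve(logisticVals(500, 1, 0.08, t), t)
  fit <- fitLogistic(cv)
  expect_true(fit@converged)
  expect_equal(carryingCapacity(fit), 500, tolerance = 1e-4)
  expect_equal(initialPopulation(fit), 1, tolerance = 1e-4)
  expect_equal(growthRate(fit), 0.08, tolerance = 1e-4)
  expect_lt(fit@sse, 1e-8)

  # refitting the model's own output is a fixed point
  cv2 <- makeCurve(logisticVals(fit@K, fit@N0, fit@r, t), t)
  fit2 <- fitLogistic(cv2)
  expect_equal(c(fit2@K, fit2@N0, fit2@r), c(fit@K, fit@N0, fit@r),
               tolerance = 1e-6)
})

test_that("noiseless recovery holds across the (K, r) plane", {
  # fixed 1:1000 inoculum ratio; sampling runs to saturation (~6/r past
  # the inflection at log(999)/r)
  for (K in c(10, 100, 1e4)) {
    for (r in c(0.02, 0.1, 0.5)) {
      N0 <- K / 1000
      t <- seq(0, (log(999) + 6) / r, length.out = 600)
      fit <- fitLogistic(makeCurve(logisticVals(K, N0, r, t), t))
      expect_equal(fit@K, K, tolerance = 1e-3)
      expect_equal(fit@N0, N0, tolerance = 1e-3)
      expect_equal(fit@r, r, tolerance = 1e-3)
    }
  }
})

test_that("maxSlopeTime matches the closed form and a dense-grid argmax", {
  fit <- new("LogisticFit", K = 1000, N0 = 1, r = 0.1, sse = 0,
             converged = TRUE, nPoints = 100L, message = "")
  mu <- maxSlopeTime(fit)
  expect_equal(as.numeric(mu), log(999) / 0.1, tolerance = 1e-12)
  expect_false(attr(mu, "boundary"))

  # brute-force oracle: argmax of dN/dt on a 0.001 h grid
  tg <- seq(0, 180, by = 0.001)
  dN <- diff(logisticVals(1000, 1, 0.1, tg)) / 0.001
  expect_lt(abs(tg[which.max(dN)] + 0.0005 - as.numeric(mu)), 0.001)

  shallow <- new("LogisticFit", K = 100, N0 = 50, r = 0.1, sse = 0,
                 converged = TRUE, nPoints = 100L, message = "")
  mu2 <- maxSlopeTime(shallow)
  expect_equal(as.numeric(mu2), 0)
  expect_true(attr(mu2, "boundary"))
})

test_that("lagTime follows the inflection-tangent construction", {
  fit <- new("LogisticFit", K = 100, N0 = 1, r = 0.1, sse = 0,
             converged = TRUE, nPoints = 100L, message = "")
  # numeric oracle: intersect the tangent at the inflection with N = N0
  mu <- log(99) / 0.1
  h <- 1e-6
  slope <- (logisticVals(100, 1, 0.1, mu + h) -
              logisticVals(100, 1, 0.1, mu - h)) / (2 * h)
  tl <- mu + (1 - logisticVals(100, 1, 0.1, mu)) / slope
  expect_equal(as.numeric(lagTime(fit)), tl, tolerance = 1e-6)
  expect_equal(as.numeric(lagTime(fit)), 26.3512, tolerance = 1e-4)

  # lag < max-slope time whenever the inflection is interior
  for (N0 in c(0.5, 1, 10, 49)) {
    f <- new("LogisticFit", K = 100, N0 = N0, r = 0.2, sse = 0,
             converged = TRUE, nPoints = 10L, message = "")
    expect_lt(as.numeric(lagTime(f)), as.numeric(maxSlopeTime(f)))
  }
  bound <- new("LogisticFit", K = 100, N0 = 50, r = 0.2, sse = 0,
               converged = TRUE, nPoints = 10L, message = "")
  expect_equal(as.numeric(lagTime(bound)), 0)
  expect_true(attr(lagTime(bound), "boundary"))
})

test_that("computeMetrics bundles the derived quantities coherently", {
  t <- seq(0, 180, by = 0.5)
  cv <- makeCurve(logisticVals(1000, 1, 0.1, t), t)
  m <- computeMetrics(fitLogistic(cv), cv)
  expect_equal(maxGrowthRate(m), growthRate(m) * carryingCapacity(m) / 4)
  expect_equal(maxGrowthRate(m), 25, tolerance = 1e-3)
  expect_equal(carryingCapacity(m), m@fit@K)
  expect_equal(as.numeric(maxSlopeTime(m)), log(999) / 0.1, tolerance = 1e-3)
  expect_lte(as.numeric(lagTime(m)), as.numeric(maxSlopeTime(m)))
  expect_equal(m@empiricalMaxSlopeTime, log(999) / 0.1, tolerance = 0.5)
})

test_that("fitted metrics are time-shift and value-scale equivariant", {
  t <- seq(0, 180, by = 0.5)
  base <- makeCurve(logisticVals(800, 2, 0.09, t), t)
  fit <- fitLogistic(base)

  # time shift: mu shifts by delta, K and r invariant
  delta <- 12
  shifted <- makeCurve(logisticVals(800, 2, 0.09, t), t + delta)
  fitS <- fitLogistic(shifted)
  expect_equal(fitS@K, fit@K, tolerance = 1e-5)
  expect_equal(fitS@r, fit@r, tolerance = 1e-5)
  expect_equal(as.numeric(maxSlopeTime(fitS)),
               as.numeric(maxSlopeTime(fit)) + delta, tolerance = 1e-4)
  # lag shifts by delta up to the small 4 N0 / (r K) term of the refit N0
  expect_lt(abs(as.numeric(lagTime(fitS)) -
                  (as.numeric(lagTime(fit)) + delta)), 0.1)

  # value scale: K, N0, max rate scale; r and mu invariant
  cc <- 7.5
  scaled <- makeCurve(cc * logisticVals(800, 2, 0.09, t), t)
  fitC <- fitLogistic(scaled)
  expect_equal(fitC@K, cc * fit@K, tolerance = 1e-5)
  expect_equal(fitC@N0, cc * fit@N0, tolerance = 1e-4)
  expect_equal(fitC@r, fit@r, tolerance = 1e-5)
  expect_equal(as.numeric(maxSlopeTime(fitC)),
               as.numeric(maxSlopeTime(fit)), tolerance = 1e-4)
  expect_equal(maxGrowthRate(fitC), cc * maxGrowthRate(fit),
               tolerance = 1e-4)
})
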