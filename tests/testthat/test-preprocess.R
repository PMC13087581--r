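test_that("blankCorrect subtracts the per-time blank mean", {
  t <- (0:9) / 6
  tr <- makeTrace(rep(0.50, 10), t)
  blanks <- lapply(c("H1", "H2", "H3"),
                   function(w) makeTrace(rep(0.10, 10), t, well = w))
  expect_equal(curveValues(blankCorrect(tr, blanks)), rep(0.40, 10))

  # correcting each blank against all blanks mean-centers them
  set.seed(1)
  blanks2 <- lapply(1:3, function(i) makeTrace(rnorm(10), t,
                                               well = paste0("H", i)))
  corrected <- vapply(blanks2, function(b)
    curveValues(blankCorrect(b, blanks2)), numeric(10))
  expect_equal(rowMeans(corrected), rep(0, 10))
})

test_that("blankCorrect rejects mismatched time grids", {
  tr <- makeTrace(rep(1, 10), (0:9) / 6)
  coarse <- makeTrace(rep(1, 10), 0:9, well = "H1")
  expect_error(blankCorrect(tr, list(coarse)), "time grid")
  expect_error(blankCorrect(tr, list()), "no blank")
})

test_that("controlNormalize centers against the control mean and respects scope", {
  t <- (0:9) / 6
  tr <- makeTrace(rep(0.80, 10), t)
  ctl <- list(makeTrace(rep(0.05, 10), t, well = "C1"))
  expect_equal(curveValues(controlNormalize(tr, ctl)), rep(0.75, 10))

  set.seed(2)
  ctls <- lapply(1:3, function(i) makeTrace(rnorm(10), t,
                                            well = paste0("C", i)))
  centered <- vapply(ctls, function(x)
    curveValues(controlNormalize(x, ctls)), numeric(10))
  expect_equal(rowMeans(centered), rep(0, 10))

  expect_warning(out <- controlNormalize(tr, ctl, medium = "ammonium"),
                 "ammonium")
  expect_equal(out, tr)  # no-op outside the test medium
  expect_error(controlNormalize(tr, list()), "no negative-control")
})

test_that("clampPreMinimum follows the first-occurrence rule and is idempotent", {
  expect_equal(clampPreMinimum(c(5, 3, 2, 4, 9)), c(2, 2, 2, 4, 9))
  expect_equal(clampPreMinimum(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(clampPreMinimum(c(4, 2, 5, 2, 7)), c(2, 2, 5, 2, 7))
  set.seed(3)
  for (i in 1:25) {
    v <- rnorm(sample(5:50, 1))
    once <- clampPreMinimum(v)
    expect_identical(clampPreMinimum(once), once)
    expect_equal(which.min(once), 1L)  # minimum attained at the start
  }
})

test_that("rebaseInitial pins the first value at 1 and preserves differences", {
  expect_equal(rebaseInitial(c(2, 2, 2, 4, 9)), c(1, 1, 1, 3, 8))
  expect_equal(rebaseInitial(c(1, 5)), c(1, 5))
  set.seed(4)
  v <- cumsum(runif(40))
  out <- rebaseInitial(v)
  expect_identical(out[1], 1)
  expect_equal(diff(out), diff(v))
  expect_equal(outer(out, out, "-"), outer(v, v, "-"))
})

test_that("sgWindow implements the 10%-of-samples odd-window rule", {
  expect_identical(sgWindow(1008), 101L)
  expect_identical(sgWindow(14), 5L)
  expect_identical(sgWindow(100), 11L)
  expect_identical(sgWindow(1081), 109L)
  expect_true(all(vapply(5:300, sgWindow, integer(1)) %% 2L == 1L))
})

test_that("savgolSmooth reproduces quadratics and is linear", {
  for (n in c(14, 100, 1008)) {
    t <- seq(0, 180, length.out = n)
    y <- 3 - 0.8 * t + 0.004 * t^2
    expect_equal(savgolSmooth(y, t), y, tolerance = 1e-9)
  }
  set.seed(5)
  t <- (0:99) / 6
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(savgolSmooth(2 * x - 3 * y, t),
               2 * savgolSmooth(x, t) - 3 * savgolSmooth(y, t),
               tolerance = 1e-10)
  expect_error(savgolSmooth(1:4, (0:3) / 6), "at least 5")
  expect_error(savgolSmooth(rnorm(10), c(0:8, 20)), "grid")
})

test_that("averageReplicates means same-group curves pointwise", {
  cv <- makeCurve(c(1, 2, 3, 4, 5), 0:4, stage = "smoothed")
  expect_equal(curveValues(averageReplicates(list(cv, cv, cv))),
               curveValues(cv))
  a <- makeCurve(c(1, 3, 1, 3, 1), 0:4)
  b <- makeCurve(c(3, 1, 3, 1, 3), 0:4)
  avg <- averageReplicates(list(a, b))
  expect_equal(curveValues(avg), rep(2, 5))
  expect_true("averaged" %in% stages(avg))
  expect_equal(curveValues(averageReplicates(list(a))), curveValues(a))

  other <- makeCurve(c(1, 3, 1, 3, 1), 0:4, bio = 2L)
  expect_error(averageReplicates(list(a, other)), "different")
  offgrid <- makeCurve(c(1, 3, 1, 3, 1), (0:4) * 2)
  expect_error(averageReplicates(list(a, offgrid)), "grids")
})

test_that("preprocessPipeline produces one curve per biological replicate, rebased", {
  cfg <- simulationConfig(samplingIntervalH = 2, seed = 9)
  sim <- simulatePlate(cfg)
  curves <- preprocessPipeline(sim$traces, sim$layout)
  # 2 constructs x 3 bio (ccdB consumed as the normalization reference)
  expect_length(curves, 6L)
  for (cv in curves) {
    expect_equal(stages(cv),
                 c("blank_corrected", "control_normalized", "clamped",
                   "rebased", "smoothed", "averaged"))
    expect_false(curveId(cv) == "" || construct(cv) == "ccdB")
  }
  # rebasing happens before smoothing/averaging, so values[1] stays near 1
  # but exactly 1 on each technical replicate before smoothing
  tech <- preprocessPipeline(sim$traces, sim$layout, averageTechnical = FALSE)
  expect_length(tech, 18L)

  # all-blank plate: empty output, no error
  t <- (0:9) / 6
  blanks <- list(H1 = makeTrace(rnorm(10), t, "H1"))
  lay <- new("PlateLayout", entries = layoutRow("H1", role = "blank"))
  expect_length(preprocessPipeline(blanks, lay), 0L)
})

test_that("rebased technical replicates start at exactly 1 before smoothing", {
  cfg <- simulationConfig(samplingIntervalH = 2, noiseSd = 0,
                          peakEnabled = FALSE, bioRateCv = 0, seed = 10)
  sim <- simulatePlate(cfg)
  traces <- sim$traces
  lay <- sim$layout@entries
  for (w in lay$well[lay$role == "sample"][1:3]) {
    bw <- lay$well[lay$role == "blank"]
    v <- curveValues(blankCorrect(traces[[w]], traces[bw]))
    expect_identical(rebaseInitial(clampPreMinimum(v))[1], 1)
  }
})

test_that("preprocessPipeline reports missing blanks and controls by name", {
  cfg <- simulationConfig(samplingIntervalH = 2, seed = 11)
  sim <- simulatePlate(cfg)
  lay <- sim$layout@entries
  noBlanks <- sim$traces[lay$well[lay$role == "sample"]]
  layNB <- new("PlateLayout",
               entries = lay[lay$role == "sample", , drop = FALSE])
  expect_error(preprocessPipeline(noBlanks, layNB), "no blank.*citrulline")

  keep <- lay$construct != "ccdB" | lay$role == "blank"
  keep[is.na(keep)] <- TRUE
  layNC <- new("PlateLayout", entries = lay[keep, , drop = FALSE])
  expect_error(
    preprocessPipeline(sim$traces[layNC@entries$well], layNC),
    "ccdB")
  # with normalization disabled the same plate goes through
  out <- preprocessPipeline(sim$traces[layNC@entries$well], layNC,
                            controlConstruct = NA)
  expect_length(out, 6L)
})
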