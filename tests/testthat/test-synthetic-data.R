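test_that("simulation is deterministic in config + seed", {
  cfg <- simulationConfig(samplingIntervalH = 2, seed = 21)
  a <- simulatePlate(cfg)
  b <- simulatePlate(cfg)
  expect_identical(lapply(a$traces, curveValues),
                   lapply(b$traces, curveValues))
  expect_identical(a$layout@entries, b$layout@entries)
  expect_identical(a$truth, b$truth)

  c3 <- simulatePlate(cfg, seed = 22)
  expect_false(identical(names(a$traces), names(c3$traces)) &&
                 identical(lapply(a$traces, curveValues),
                           lapply(c3$traces, curveValues)))
})

test_that("noiseless wells equal the logistic closed form plus blank level", {
  cfg <- simulationConfig(noiseSd = 0, peakEnabled = FALSE, bioRateCv = 0,
                          samplingIntervalH = 1, seed = 23)
  set.seed(1)
  tr <- simulateWell(cfg, "AtLHT1")
  tru <- attr(tr, "truth")
  t <- curveTimes(tr)
  expect_equal(curveValues(tr),
               cfg@blankLevel + logisticVals(tru[["K"]], tru[["N0"]],
                                             tru[["r"]], t),
               tolerance = 1e-12)
  # N0 is solved so the true inflection sits at the configured mu
  expect_equal(log((tru[["K"]] - tru[["N0"]]) / tru[["N0"]]) / tru[["r"]],
               cfg@groups$mu[cfg@groups$construct == "AtLHT1"],
               tolerance = 1e-9)
  expect_error(simulateWell(cfg, "unknown"), "unknown group")
})

test_that("the nephelometric artifact produces a peak above the plateau", {
  cfg <- simulationConfig(noiseSd = 0, peakAmplitude = 0.3, bioRateCv = 0,
                          samplingIntervalH = 0.5, seed = 24)
  set.seed(1)
  v <- curveValues(simulateWell(cfg, "AtLHT1"))
  expect_gt(max(v), v[length(v)] * 1.05)  # peak, then decline to plateau
  # spectrophotometric mode never applies the artifact
  cfgS <- simulationConfig("spectrophotometric", noiseSd = 0, bioRateCv = 0,
                           seed = 24)
  set.seed(1)
  vs <- curveValues(simulateWell(cfgS, "AtLHT1"))
  expect_equal(which.max(vs), length(vs))  # monotone to the plateau
})

test_that("simulatePlate emits the documented well complement", {
  cfg <- simulationConfig(samplingIntervalH = 2, seed = 25)
  sim <- simulatePlate(cfg)
  expect_length(sim$traces, 30L)  # 2 x 9 samples + 9 control + 3 blanks
  e <- sim$layout@entries
  expect_equal(sum(e$role == "blank"), 3L)
  expect_equal(sum(e$construct == "ccdB", na.rm = TRUE), 9L)
  expect_equal(nrow(sim$truth), 27L)  # one record per sample well
  expect_true(all(sim$truth$mu_true > 0))
  expect_s4_class(sim$layout, "PlateLayout")

  # blank wells concentrate on the configured baseline
  bw <- e$well[e$role == "blank"]
  for (w in bw) {
    v <- curveValues(sim$traces[[w]])
    tol <- 3 * cfg@noiseSd * cfg@blankLevel / sqrt(length(v))
    expect_lt(abs(mean(v) - cfg@blankLevel), tol * 2)
  }
})

test_that("capacity overflow is rejected", {
  g <- data.frame(construct = paste0("G", 1:11), K = 1000, r = 0.1, mu = 65,
                  n_bio = 3L, n_tech = 3L)
  cfg <- simulationConfig(groups = g, samplingIntervalH = 10, seed = 26)
  expect_error(simulatePlate(cfg), "96")
})

test_that("the pipeline recovers ground truth from a noiseless plate", {
  cfg <- simulationConfig(noiseSd = 0, peakEnabled = FALSE, bioRateCv = 0,
                          controlBackground = NULL, seed = 27)
  sim <- simulatePlate(cfg)
  curves <- preprocessPipeline(sim$traces, sim$layout,
                               controlConstruct = NA)
  expect_length(curves, 6L)
  for (cv in curves) {
    fit <- fitLogistic(cv)
    muHat <- as.numeric(maxSlopeTime(fit))
    muTrue <- sim$truth$mu_true[sim$truth$construct == construct(cv)][1]
    expect_lt(abs(muHat - muTrue), cfg@samplingIntervalH)
  }
})

test_that("writeSimulation round-trips through the readers", {
  cfg <- simulationConfig(samplingIntervalH = 4, seed = 28)
  sim <- simulatePlate(cfg)
  dir <- file.path(tempdir(), "sim-rt")
  paths <- writeSimulation(sim, dir)
  traces <- readTimeseries(paths[["timeseries"]], "RNU")
  expect_setequal(names(traces), names(sim$traces))
  w <- names(traces)[1]
  expect_equal(curveValues(traces[[w]]), curveValues(sim$traces[[w]]),
               tolerance = 1e-12)
  lay <- readLayout(paths[["layout"]])
  expect_equal(nrow(lay@entries), nrow(sim$layout@entries))
})
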