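test_that("activity ratio is the cytoplasm/nucleus quotient", {
  tr <- data.frame(time_min = c(0, 5), nuc_ktr = c(100, 50),
                   cyt_ktr = c(200, 50))
  at <- computeActivityTrace(tr)
  expect_equal(ratioValues(at), c(2, 1))
  # identical channels give the unit trace
  same <- data.frame(time_min = seq(0, 20, 5), nuc_ktr = 5:9, cyt_ktr = 5:9)
  expect_equal(unique(ratioValues(computeActivityTrace(same))), 1)
})

test_that("nonpositive intensities are excluded and flagged", {
  tr <- data.frame(time_min = c(0, 5, 10), nuc_ktr = c(100, -1, 100),
                   cyt_ktr = c(200, 10, 100))
  at <- computeActivityTrace(tr)
  expect_equal(timeMin(at), c(0, 10))
  expect_true("segmentation_error" %in% traceFlags(at))
  expect_equal(coverage(at), 2 / 3)
  allBad <- data.frame(time_min = 0, nuc_ktr = 0, cyt_ktr = 1)
  expect_error(computeActivityTrace(allBad), "empty trace")
})

test_that("generator round trip: tracked sustained cell equals template", {
  mp <- migrationSimParams(nCells = 4, nFrames = 73, inducibleFraction = 1,
                           seed = 9)
  sim <- simulateTrackPopulation(sustainedParams(onsetMin = 60,
                                                 plateau = 1.5, noiseSd = 0),
                                 mp)
  traces <- tracksToTraces(sim$tracks)
  sc <- 30 / (2 * log(9))
  t <- timeMin(traces[[1]])
  tmpl <- 1 + 0.5 / (1 + exp(-(t - 60) / sc))
  for (tr in traces)
    expect_equal(ratioValues(tr), tmpl, tolerance = 1e-9)
})

test_that("trace cleaning applies the coverage and flag rules", {
  mk <- function(id, cov, fl) makeTrace(seq(0, 50, 5), rep(1, 11), id,
                                        coverage = cov, flags = fl)
  traces <- list(mk("a", 0.5, character(0)),
                 mk("b", 1, "track_switch"),
                 mk("c", 0.9, character(0)),
                 mk("d", 0.7, "segmentation_error"))
  out <- cleanTraces(traces)
  expect_equal(vapply(out$retained, cellId, character(1)), "c")
  expect_equal(out$log$reason[out$log$cell_id == "a"], "short")
  expect_equal(out$log$reason[out$log$cell_id == "b"], "switch")
  expect_equal(out$log$reason[out$log$cell_id == "d"], "segmentation")
  # idempotent
  again <- cleanTraces(out$retained)
  expect_equal(length(again$retained), 1)
  expect_equal(nrow(again$log), 0)
  # relaxed coverage keeps short tracks
  relaxed <- cleanTraces(traces, minCoverage = 0.4)
  expect_setequal(vapply(relaxed$retained, cellId, character(1)),
                  c("a", "c"))
})

test_that("localization fold change is final over basal N/C mean", {
  t <- seq(0, 360, 5)
  loc <- new("LocalizationTrace", cellId = "x", timeMin = t,
             ncRatio = c(rep(1, 36), rep(2, 37)))
  expect_equal(localizationFoldChange(loc), 2)
  flat <- new("LocalizationTrace", cellId = "x", timeMin = t,
              ncRatio = rep(1.3, 73))
  expect_equal(localizationFoldChange(flat), 1)
})

test_that("programmed nuclear accumulation is recovered from tracks", {
  mp <- migrationSimParams(nCells = 30, nFrames = 73,
                           inducibleFraction = 1, seed = 21)
  sim <- simulateTrackPopulation(sustainedParams(onsetMin = 180,
                                                 noiseSd = 0.05), mp,
                                 inducibleLocFold = 1.8)
  folds <- vapply(unique(sim$tracks$cell_id), function(id) {
    rows <- sim$tracks[sim$tracks$cell_id == id, ]
    loc <- new("LocalizationTrace", cellId = id, timeMin = rows$time_min,
               ncRatio = rows$nuc_loc / rows$cyt_loc)
    localizationFoldChange(loc)
  }, numeric(1))
  expect_gt(mean(folds), 1.7)
  expect_lt(mean(folds), 1.9)
})

test_that("migration fold change reflects window path lengths", {
  t <- seq(0, 360, 5)
  # constant speed throughout
  tr1 <- data.frame(time_min = t, x_um = t / 5, y_um = 0)
  expect_equal(migrationFoldChange(tr1), 1)
  # 2x speed in the final hour
  x <- cumsum(c(0, ifelse(t[-1] > 300, 2, 1)))
  tr2 <- data.frame(time_min = t, x_um = x, y_um = 0)
  expect_equal(migrationFoldChange(tr2), 2)
  # zero basal path is undefined
  tr3 <- data.frame(time_min = t, x_um = c(rep(0, 61), seq_len(12)),
                    y_um = 0)
  expect_true(is.na(migrationFoldChange(tr3)))
})

test_that("simulated speed-up x3 is recovered across a population", {
  mp <- migrationSimParams(nCells = 100, nFrames = 73,
                           inducibleFraction = 0, biasOnsetMin = 240,
                           speedFactorAfter = 3, positionNoiseUm = 0.1,
                           seed = 14)
  sim <- simulateTrackPopulation(pulseTrainParams(meanRate = 0), mp)
  folds <- vapply(unique(sim$tracks$cell_id), function(id)
    migrationFoldChange(sim$tracks[sim$tracks$cell_id == id, ]),
    numeric(1))
  expect_gt(mean(folds, na.rm = TRUE), 2.5)
  expect_lt(mean(folds, na.rm = TRUE), 3.5)
})

test_that("dynamics classification follows its rules exactly", {
  t <- seq(0, 360, 5)
  plateau <- makeTrace(t, rep(1.6, 73))
  noPeaks <- new("PeakSet", cellId = "p", peakTimes = numeric(0),
                 peakAmplitudes = numeric(0))
  expect_equal(dynamicsLabel(classifyDynamics(noPeaks, plateau)),
               "sustained")
  flat <- makeTrace(t, rep(1, 73))
  expect_equal(dynamicsLabel(classifyDynamics(noPeaks, flat)), "quiescent")
  fourPeaks <- new("PeakSet", cellId = "p",
                   peakTimes = c(60, 120, 180, 240),
                   peakAmplitudes = rep(0.5, 4))
  pulsy <- makeTrace(t, 1 + 0.5 * (sin(t / 10)^40))
  call <- classifyDynamics(fourPeaks, pulsy)
  expect_equal(dynamicsLabel(call), "pulsatile")
  expect_lt(dynamicsFeatures(call)[["duty_cycle"]], 0.8)
  # single peak, low duty -> quiescent
  onePeak <- new("PeakSet", cellId = "p", peakTimes = 60,
                 peakAmplitudes = 0.5)
  expect_equal(dynamicsLabel(classifyDynamics(onePeak, flat)), "quiescent")
})

test_that("population summary matches per-frame statistics", {
  t <- seq(0, 30, 5)
  same <- list(makeTrace(t, rep(1.2, 7), "a"), makeTrace(t, rep(1.2, 7), "b"))
  s <- summarizePopulation(same)
  expect_equal(s$mean, rep(1.2, 7))
  expect_equal(s$q75 - s$q25, rep(0, 7))
  two <- list(makeTrace(t, rep(1, 7), "a"), makeTrace(t, rep(3, 7), "b"))
  expect_equal(summarizePopulation(two)$mean, rep(2, 7))
  # absent frames are omitted per frame
  ragged <- list(makeTrace(t, rep(1, 7), "a"),
                 makeTrace(t[1:3], rep(3, 3), "b"))
  sr <- summarizePopulation(ragged)
  expect_equal(sr$n, c(2, 2, 2, 1, 1, 1, 1))
  expect_equal(sr$mean, c(2, 2, 2, 1, 1, 1, 1))
})

test_that("normal traces give the closed-form interquartile band", {
  set.seed(17)
  t <- seq(0, 360, 5)
  traces <- lapply(1:1000, function(i)
    makeTrace(t, pmax(rnorm(length(t), 1, 0.1), 1e-6), paste0("c", i)))
  s <- summarizePopulation(traces)
  z75 <- qnorm(0.75)  # band is mean +/- 0.6745 sd
  expect_lt(abs(mean(s$q25) - (1 - z75 * 0.1)), 0.01)
  expect_lt(abs(mean(s$q75) - (1 + z75 * 0.1)), 0.01)
})
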