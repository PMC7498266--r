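test_that("inducible center is the population centroid", {
  mk <- function(x, y, pop) data.frame(cell_id = paste0("c", seq_along(x)),
                                       frame = 0, time_min = 0, x_um = x,
                                       y_um = y, population = pop)
  one <- mk(10, 20, "inducible")
  expect_equal(unname(findInducibleCenter(one)), c(10, 20))
  two <- mk(c(0, 10), c(0, 0), "inducible")
  expect_equal(unname(findInducibleCenter(two)), c(5, 0))
  none <- mk(1, 1, "neighbor")
  expect_error(findInducibleCenter(none), "no inducible cells")
  # CLT check: 30 cells ~ N(center, 5 um) per axis
  set.seed(23)
  cl <- mk(rnorm(30, 120, 5), rnorm(30, 80, 5), "inducible")
  ctr <- findInducibleCenter(cl)
  expect_lt(sqrt(sum((ctr - c(120, 80))^2)), 3)
})

test_that("neighbor selection applies the square window and population filter", {
  tracks <- data.frame(
    cell_id = c("in", "edge", "out", "ind"),
    frame = 0, time_min = 0,
    x_um = c(100 + 99, 100 - 100, 100 + 101, 100),
    y_um = c(100 + 99, 100, 100, 100),
    population = c("neighbor", "neighbor", "neighbor", "inducible"))
  sel <- selectNeighborsInWindow(tracks, c(100, 100), 100)
  expect_setequal(unique(sel$cell_id), c("in", "edge"))
})

test_that("interval displacements span exact non-overlapping windows", {
  t <- seq(0, 120, 5)
  still <- data.frame(time_min = t, x_um = 7, y_um = -3)
  d0 <- intervalDisplacements(still)
  expect_equal(nrow(d0), 6)  # 120 min / 20 min
  expect_true(all(d0$dx_um == 0 & d0$dy_um == 0))
  # uniform velocity (1, 0) um/min
  mv <- data.frame(time_min = t, x_um = t, y_um = 0)
  dv <- intervalDisplacements(mv)
  expect_true(all(abs(dv$dx_um - 20) < 1e-12))
  # each 20-min interval covers exactly 4 frames at 5-min sampling
  expect_equal(unique(diff(dv$t_start_min)), 20)
  # a gap spanning an interval start skips that interval
  gap <- mv[!(mv$time_min %in% c(40, 60)), ]
  dg <- intervalDisplacements(gap)
  expect_false(40 %in% dg$t_start_min)
  expect_error(intervalDisplacements(mv, intervalMin = 12),
               "must divide")
})

test_that("migration angles hit the 0/90/180 anchors exactly", {
  ctr <- c(0, 0)
  expect_equal(migrationAngle(c(50, 0), c(-1, 0), ctr), 0)
  expect_equal(migrationAngle(c(50, 0), c(1, 0), ctr), 180)
  expect_equal(migrationAngle(c(50, 0), c(0, 1), ctr), 90)
  expect_true(is.na(migrationAngle(c(50, 0), c(0, 0), ctr)))
})

test_that("angles are invariant under global rotation and translation", {
  set.seed(41)
  for (rep in 1:25) {
    pos <- runif(2, -100, 100); disp <- runif(2, -5, 5)
    ctr <- runif(2, -100, 100)
    a0 <- migrationAngle(pos, disp, ctr)
    th <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -50, 50)
    a1 <- migrationAngle(as.vector(Rm %*% pos) + shift,
                         as.vector(Rm %*% disp),
                         as.vector(Rm %*% ctr) + shift)
    expect_equal(a0, a1, tolerance = 1e-9)
  }
})

test_that("radial histograms conserve counts and cover uniform data", {
  one <- new("AngleSample", condition = "c", epoch = "after",
             anglesDeg = rep(0, 7), nCells = 7L)
  h1 <- radialHistogram(one)
  expect_equal(h1$count[1], 7)
  expect_equal(sum(h1$count), 7)
  set.seed(19)
  u <- new("AngleSample", condition = "c", epoch = "after",
           anglesDeg = runif(1e4, 0, 180), nCells = 100L)
  hu <- radialHistogram(u, 12)
  expect_equal(sum(hu$count), 1e4)
  p <- 1 / 12
  bound <- 3 * sqrt(1e4 * p * (1 - p))
  expect_true(all(abs(hu$count - 1e4 * p) <= bound))
  # boundary angle 180 lands in the last bin
  b <- radialHistogram(new("AngleSample", condition = "c", epoch = "e",
                           anglesDeg = c(0, 180), nCells = 2L))
  expect_equal(b$count[c(1, 12)], c(1, 1))
})

test_that("identical samples give D = 0 and median p = 1", {
  a <- c(10, 20, 30, 40, 50)
  r <- subsampledKsTest(a, a, nIter = 20, nSub = 10, seed = 1)
  expect_equal(unique(r@statD), 0)
  expect_equal(medianP(r), 1)
  expect_equal(r@stars, "ns")
  small <- subsampledKsTest(c(1, 2, 3), c(1, 2, 3), nIter = 5, nSub = 3,
                            seed = 1)
  expect_equal(medianP(small), 1)
})

test_that("with one full-sample iteration the procedure is the classical KS test", {
  set.seed(77)
  a <- runif(300, 0, 180); b <- runif(260, 0, 180)
  mine <- subsampledKsTest(a, b, nIter = 1, nSub = 1000, seed = 5)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(medianP(mine), ref$p.value)
  expect_equal(unique(mine@statD), unname(ref$statistic))
  expect_equal(mine@subsampleSize, c(300L, 260L))
})

test_that("subsampled KS is seed-reproducible and never anticonservative", {
  set.seed(99)
  a <- runif(3000, 0, 180); b <- runif(3000, 0, 180)
  r1 <- subsampledKsTest(a, b, nIter = 50, nSub = 500, seed = 7)
  r2 <- subsampledKsTest(a, b, nIter = 50, nSub = 500, seed = 7)
  expect_identical(r1@pValues, r2@pValues)
  # marginal calibration: per-iteration rejection near nominal, and the
  # median-p decision rule is conservative (see methods vignette)
  rej <- 0; iterRej <- numeric(0)
  for (k in 1:20) {
    set.seed(200 + k)
    x <- runif(2000, 0, 180); y <- runif(2000, 0, 180)
    r <- subsampledKsTest(x, y, nIter = 100, nSub = 500, seed = k)
    rej <- rej + (medianP(r) < 0.05)
    iterRej <- c(iterRej, mean(r@pValues < 0.05))
  }
  expect_lte(rej / 20, 0.1)
  expect_lt(abs(mean(iterRej) - 0.05), 0.05)
})

test_that("collectAngles assembles the windowed-angle workflow", {
  mp <- migrationSimParams(nCells = 80, nFrames = 37, biasKappa = 8,
                           biasOnsetMin = 60, seed = 33)
  sim <- simulateTrackPopulation(pulseTrainParams(meanRate = 0), mp)
  before <- collectAngles(sim$tracks, c(0, 60), epoch = "before")
  after <- collectAngles(sim$tracks, c(60, 180), epoch = "after")
  expect_s4_class(after, "AngleSample")
  expect_true(all(angles(after) >= 0 & angles(after) <= 180))
  expect_gt(nObservations(after), 50)
  # strong bias shifts the angle mass toward 0 after onset
  expect_lt(median(angles(after)), median(angles(before)) - 20)
})
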