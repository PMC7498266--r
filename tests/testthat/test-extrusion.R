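test_that("z-intensity histogram localizes and conserves mass", {
  # one bright plane at z = 5 um in an otherwise empty stack
  st <- array(0L, dim = c(2, 26, 8, 8))
  st[1, 6, , ] <- 100L
  pr <- zIntensityHistogram(st, "inducible")
  expect_equal(pr@zUm[which.max(pr@totalIntensity)], 5)
  expect_equal(sum(pr@totalIntensity > 0), 1)
  # two equal nuclei at z = 3 and 9 um: symmetric bimodal, equal masses
  st2 <- array(0L, dim = c(2, 26, 8, 8))
  st2[2, 4, , ] <- 50L; st2[2, 10, , ] <- 50L
  pr2 <- zIntensityHistogram(st2, "all")
  expect_equal(pr2@totalIntensity[4], pr2@totalIntensity[10])
  expect_equal(sum(pr2@totalIntensity > 0), 2)
  # conservation: profile mass equals the background-corrected stack total
  sim <- simulateZStack(zStackSimParams(nx = 30, ny = 30, nNuclei = 6,
                                        seed = 3))
  vol <- sim$stack[1, , , ]
  px <- as.numeric(vol)
  bg <- median(px[px <= quantile(px, 0.1)])
  prS <- zIntensityHistogram(sim$stack, 1)
  expect_equal(sum(prS@totalIntensity), sum(pmax(vol - bg, 0)),
               tolerance = 1e-9)
})

test_that("Gaussian profile fit recovers exact noiseless parameters", {
  z <- seq(0, 25, 1)
  y <- 80 * exp(-(z - 12)^2 / (2 * 9)) + 5
  fit <- fitGaussianProfile(new("ZIntensityProfile", positionId = "p",
                                channel = "all", zUm = z,
                                totalIntensity = y))
  expect_true(fit@converged)
  expect_equal(fittedMean(fit), 12, tolerance = 0.01)
  expect_equal(fittedSigma(fit), 3, tolerance = 0.01)
  # symmetric profile: fitted mean at the symmetry center
  ys <- exp(-(z - 12.5)^2 / 20) + exp(-(z - 12.5)^2 / 7)
  fs <- fitGaussianProfile(new("ZIntensityProfile", positionId = "p",
                               channel = "all", zUm = z,
                               totalIntensity = ys))
  expect_equal(fittedMean(fs), 12.5, tolerance = 1e-6)
})

test_that("degenerate profiles fall back to moments or error", {
  z <- seq(0, 25, 1)
  flat <- new("ZIntensityProfile", positionId = "p", channel = "all",
              zUm = z, totalIntensity = rep(4, 26))
  ff <- fitGaussianProfile(flat)
  expect_false(ff@converged)
  expect_equal(fittedMean(ff), 12.5)  # mid-range centroid
  zero <- new("ZIntensityProfile", positionId = "p", channel = "all",
              zUm = z, totalIntensity = rep(0, 26))
  expect_error(fitGaussianProfile(zero), "zero total mass")
})

test_that("fitted parameters match a dense grid-search oracle", {
  set.seed(55)
  for (i in 1:12) {
    mu <- runif(1, 6, 19); sg <- runif(1, 1.5, 4)
    amp <- runif(1, 40, 200); off <- runif(1, 0, 10)
    z <- seq(0, 25, 1)
    y <- amp * exp(-(z - mu)^2 / (2 * sg^2)) + off
    fit <- fitGaussianProfile(new("ZIntensityProfile", positionId = "p",
                                  channel = "all", zUm = z,
                                  totalIntensity = y))
    orc <- oracleGridGaussian(z, y)
    expect_lt(abs(fittedMean(fit) - orc$mean), 0.05)
    expect_lt(abs(fittedSigma(fit) - orc$sigma), 0.05)
  }
})

test_that("delta-Z is antisymmetric and zero for identical channels", {
  z <- seq(0, 25, 1)
  mk <- function(mu) fitGaussianProfile(
    new("ZIntensityProfile", positionId = "p", channel = "all", zUm = z,
        totalIntensity = 50 * exp(-(z - mu)^2 / 8) + 2))
  fA <- mk(9); fB <- mk(15)
  expect_equal(deltaZ(fA, fA), 0)
  expect_equal(deltaZ(fA, fB), -deltaZ(fB, fA))
  expect_equal(deltaZ(fB, fA), 6, tolerance = 0.01)
  # unconverged fits flag the result
  bad <- mk(9); bad@converged <- FALSE
  dz <- deltaZ(bad, fA)
  expect_true(is.na(dz))
  expect_true(attr(dz, "unconverged"))
})

test_that("simulated offset stacks recover the programmed delta-Z", {
  res <- vapply(1:6, function(i) {
    sim <- simulateZStack(zStackSimParams(nx = 120, ny = 120,
                                          nNuclei = 80,
                                          extrusionOffsetUm = 6,
                                          seed = 800 + i))
    quantifyExtrusion(sim$stack)$delta_z_um
  }, numeric(1))
  expect_lt(abs(mean(res) - 6), 0.5)
})

test_that("normalization identities and z-shift invariance hold", {
  base <- c(0.2, 0.5, 0.4, 0.1)
  expect_equal(normalizeCondition(6.4, 0.4), 6.0)
  expect_equal(mean(normalizeCondition(base, base)), 0, tolerance = 1e-12)
  expect_error(normalizeCondition(base, numeric(0)), "non-empty")
  # a constant z offset applied to the whole acquisition shifts both
  # fitted means equally and leaves delta-Z (hence normalized delta-Z)
  # unchanged
  z <- seq(0, 25, 1)
  mk <- function(mu, z0) fitGaussianProfile(
    new("ZIntensityProfile", positionId = "p", channel = "all",
        zUm = z + z0, totalIntensity = 50 * exp(-(z - mu)^2 / 8) + 2))
  dz0 <- deltaZ(mk(14, 0), mk(9, 0))
  dz3 <- deltaZ(mk(14, 3), mk(9, 3))
  expect_equal(dz0, dz3, tolerance = 1e-6)
})

test_that("outlier flagging follows the robust MAD rule", {
  expect_true(all(!flagOutliers(rep(2, 5))))
  set.seed(6)
  x <- c(rnorm(19, 0, 1), 10)
  fl <- flagOutliers(x)
  expect_true(fl[20])
  expect_lt(sum(fl[1:19]), 3)
  # idempotent on the retained subset
  fl2 <- flagOutliers(x[!fl])
  expect_equal(sum(fl2), 0)
  expect_error(flagOutliers(c(1, 2, 3)), ">= 4")
})

test_that("condition comparison is a Welch t-test with star coding", {
  a <- c(1, 2, 3, 4)
  same <- compareConditions(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  b <- a + 10
  sw1 <- compareConditions(a, b); sw2 <- compareConditions(b, a)
  expect_equal(sw1$t, -sw2$t)
  expect_equal(sw1$p, sw2$p)
  expect_error(compareConditions(1, a), "at least 2")
  # power: N(0,1) vs N(5,1), n = 16 each
  hits <- 0
  for (i in 1:100) {
    set.seed(i)
    r <- compareConditions(rnorm(16), rnorm(16, 5))
    hits <- hits + (r$p < 0.001)
  }
  expect_gte(hits, 99)
})
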