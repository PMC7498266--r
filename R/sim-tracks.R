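#' Draw from a von Mises distribution
#'
#' Samples angles (radians) from the von Mises distribution with mean
#' direction `mu` and concentration `kappa`, the circular analog of the
#' normal distribution, using the Best-Fisher rejection algorithm.
#' `kappa = 0` reduces to the uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rVonMises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi) + mu
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    i <- 0L
    while (i < n) {
      z <- cos(pi * stats::runif(1))
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        i <- i + 1L
        th[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
      }
    }
  }
  # wrap to (-pi, pi]
  w <- th %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Parameters for simulated coculture migration movies
#'
#' Describes the geometry and motility model used to emulate coculture
#' timelapses: a compact group of inducible cells near the field center
#' surrounded by neighboring cells.  Neighbor step headings follow a von
#' Mises distribution about the direction to the inducible-cell center with
#' concentration `biasKappa` once `biasOnsetMin` has passed (uniform
#' before); `biasKappa = 0` gives unbiased random walks throughout.
#'
#' @param nCells total number of cells.
#' @param fieldSizeUm side of the square field of view, micrometers.
#' @param centerXy length-2 center of the inducible group, micrometers.
#' @param speedUmPerFrame step length per frame, micrometers.
#' @param biasKappa von Mises concentration of neighbor headings toward the
#'   center (0 = unbiased).
#' @param frameIntervalMin acquisition interval, minutes.
#' @param nFrames number of frames.
#' @param inducibleFraction fraction of cells in the inducible population.
#' @param biasOnsetMin time after which the migration bias (and any speed
#'   change) applies; use the induction time to obtain before/after epochs.
#' @param clusterSdUm spatial spread of the inducible group.
#' @param inducibleSpeedFactor speed multiplier for inducible cells (the
#'   group is near-stationary on this timescale).
#' @param positionNoiseUm sd of isotropic localization noise added to the
#'   recorded (not the true) positions.
#' @param speedFactorAfter neighbor speed multiplier applied after
#'   `biasOnsetMin`.
#' @param seed integer seed or `NULL`.
#' @return list of class `"MigrationSimParams"`.
#' @export
migrationSimParams <- function(nCells = 100, fieldSizeUm = 400,
                               centerXy = c(fieldSizeUm / 2, fieldSizeUm / 2),
                               speedUmPerFrame = 2, biasKappa = 0,
                               frameIntervalMin = 5, nFrames = 73,
                               inducibleFraction = 0.1, biasOnsetMin = 0,
                               clusterSdUm = 15, inducibleSpeedFactor = 0.1,
                               positionNoiseUm = 0, speedFactorAfter = 1,
                               seed = NULL) {
  if (nCells < 1) stop("nCells must be >= 1")
  if (biasKappa < 0) stop("biasKappa must be >= 0")
  if (inducibleFraction < 0 || inducibleFraction > 1)
    stop("inducibleFraction must lie in [0, 1]")
  if (speedUmPerFrame < 0) stop("speedUmPerFrame must be >= 0")
  structure(list(nCells = nCells, fieldSizeUm = fieldSizeUm,
                 centerXy = centerXy, speedUmPerFrame = speedUmPerFrame,
                 biasKappa = biasKappa, frameIntervalMin = frameIntervalMin,
                 nFrames = nFrames, inducibleFraction = inducibleFraction,
                 biasOnsetMin = biasOnsetMin, clusterSdUm = clusterSdUm,
                 inducibleSpeedFactor = inducibleSpeedFactor,
                 positionNoiseUm = positionNoiseUm,
                 speedFactorAfter = speedFactorAfter, seed = seed),
            class = "MigrationSimParams")
}

# Map a C/N activity ratio r to nuclear/cytoplasmic reporter intensities
# with a conserved per-cell total, so that cyt/nuc reproduces r exactly.
ktrIntensities <- function(r, total = 200) {
  list(nuc = total / (1 + r), cyt = total * r / (1 + r))
}

#' Simulate a tracked coculture population
#'
#' Joins single-cell activity dynamics and cell motility into a per-cell,
#' per-frame tracking table of the kind produced by nuclear tracking of
#' coculture timelapses.  Inducible cells receive activity traces drawn
#' from `traceParams` (with per-cell seeds derived from the master seed);
#' neighboring cells stay at baseline unless a paracrine wave is requested,
#' in which case each neighbor receives one activity pulse whose onset is
#' delayed proportionally to its distance from the inducible-cell center
#' (`onset = triggerMin + distance / speedUmPerMin`), a purely kinematic
#' emulation of radially propagating activity waves.
#'
#' @param traceParams [pulseTrainParams()] or [sustainedParams()] describing
#'   inducible-cell dynamics (its timing fields are overridden by the motion
#'   parameters' frame grid).
#' @param motionParams a [migrationSimParams()] object.
#' @param waveParams `NULL`, or `list(speedUmPerMin =, triggerMin =)` to
#'   propagate a neighbor activity wave.
#' @param inducibleLocFold final/basal nuclear accumulation fold programmed
#'   into the inducible cells' kinase-localization channel (logistic rise at
#'   the sustained onset or mid-movie).
#' @return list with `tracks` (data.frame: cell_id, frame, time_min, x_um,
#'   y_um, nuc_ktr, cyt_ktr, nuc_loc, cyt_loc, population, valid) and
#'   `truth` (per-cell class/peak times/onsets, bias kappa, center).
#' @export
#' @examples
#' sim <- simulateTrackPopulation(
#'   pulseTrainParams(meanRate = 2),
#'   migrationSimParams(nCells = 20, nFrames = 12, seed = 3))
#' head(sim$tracks)
simulateTrackPopulation <- function(traceParams,
                                    motionParams = migrationSimParams(),
                                    waveParams = NULL,
                                    inducibleLocFold = 1) {
  mp <- motionParams
  withSeed(mp$seed, {
    nInd <- round(mp$nCells * mp$inducibleFraction)
    pop <- c(rep("inducible", nInd), rep("neighbor", mp$nCells - nInd))
    t <- (seq_len(mp$nFrames) - 1L) * mp$frameIntervalMin
    ids <- sprintf("cell_%04d", seq_len(mp$nCells))

    # initial positions: inducible cluster at the center, neighbors uniform
    x0 <- ifelse(pop == "inducible",
                 stats::rnorm(mp$nCells, mp$centerXy[1], mp$clusterSdUm),
                 stats::runif(mp$nCells, 0, mp$fieldSizeUm))
    y0 <- ifelse(pop == "inducible",
                 stats::rnorm(mp$nCells, mp$centerXy[2], mp$clusterSdUm),
                 stats::runif(mp$nCells, 0, mp$fieldSizeUm))

    X <- matrix(0, mp$nFrames, mp$nCells)
    Y <- matrix(0, mp$nFrames, mp$nCells)
    X[1, ] <- x0; Y[1, ] <- y0
    if (mp$nFrames > 1) for (f in 2:mp$nFrames) {
      biased <- t[f - 1] >= mp$biasOnsetMin
      for (i in seq_len(mp$nCells)) {
        sp <- mp$speedUmPerFrame *
          if (pop[i] == "inducible") mp$inducibleSpeedFactor else 1
        if (pop[i] == "neighbor" && biased) sp <- sp * mp$speedFactorAfter
        toC <- atan2(mp$centerXy[2] - Y[f - 1, i],
                     mp$centerXy[1] - X[f - 1, i])
        kap <- if (pop[i] == "neighbor" && biased) mp$biasKappa else 0
        th <- rVonMises(1, toC, kap)
        X[f, i] <- X[f - 1, i] + sp * cos(th)
        Y[f, i] <- Y[f - 1, i] + sp * sin(th)
      }
    }
    if (mp$positionNoiseUm > 0) {
      X <- X + stats::rnorm(length(X), 0, mp$positionNoiseUm)
      Y <- Y + stats::rnorm(length(Y), 0, mp$positionNoiseUm)
    }

    # activity ratios per cell
    seeds <- childSeeds(if (is.null(mp$seed)) 1L else mp$seed, mp$nCells)
    dist0 <- sqrt((x0 - mp$centerXy[1])^2 + (y0 - mp$centerXy[2])^2)
    R <- matrix(NA_real_, mp$nFrames, mp$nCells)
    truthCells <- vector("list", mp$nCells)
    baseline <- traceParams$baseline
    noiseSd <- traceParams$noiseSd
    for (i in seq_len(mp$nCells)) {
      if (pop[i] == "inducible") {
        tp <- traceParams
        tp$durationMin <- max(t)
        tp$frameIntervalMin <- mp$frameIntervalMin
        tp$seed <- seeds[i]
        sim <- simulateTrace(tp, cellId = ids[i])
        R[, i] <- ratioValues(sim$trace)
        truthCells[[i]] <- c(sim$truth[c("class", "peakTimes")],
                             list(onsetMin = sim$truth$onsetMin))
      } else if (!is.null(waveParams)) {
        onset <- waveParams$triggerMin + dist0[i] / waveParams$speedUmPerMin
        amp <- if (!is.null(traceParams$pulseAmplitude))
          traceParams$pulseAmplitude else traceParams$plateau - baseline
        wid <- if (!is.null(traceParams$pulseWidthMin))
          traceParams$pulseWidthMin else 25
        y <- baseline + amp * exp(-(t - onset)^2 / (2 * fwhmToSigma(wid)^2))
        if (noiseSd > 0)
          y <- y + withSeed(seeds[i], stats::rnorm(length(t), 0, noiseSd))
        R[, i] <- pmax(y, .Machine$double.eps)
        truthCells[[i]] <- list(class = "wave", peakTimes = onset,
                                onsetMin = onset)
      } else {
        y <- rep(baseline, mp$nFrames)
        if (noiseSd > 0)
          y <- y + withSeed(seeds[i], stats::rnorm(mp$nFrames, 0, noiseSd))
        R[, i] <- pmax(y, .Machine$double.eps)
        truthCells[[i]] <- list(class = "quiescent",
                                peakTimes = numeric(0), onsetMin = NA_real_)
      }
    }

    # kinase-localization channel: logistic nuclear accumulation for
    # inducible cells when requested, flat otherwise
    L <- matrix(1, mp$nFrames, mp$nCells)
    if (inducibleLocFold != 1 && any(pop == "inducible")) {
      onset <- if (!is.null(traceParams$onsetMin)) traceParams$onsetMin
               else max(t) / 2
      sc <- max(mp$frameIntervalMin, 30) / (2 * log(9))
      prof <- 1 + (inducibleLocFold - 1) / (1 + exp(-(t - onset) / sc))
      L[, pop == "inducible"] <- prof
    }

    ktr <- ktrIntensities(as.vector(R))
    loc <- ktrIntensities(1 / as.vector(L))  # cyt/nuc = 1/L, so nuc/cyt = L
    tracks <- data.frame(
      cell_id = rep(ids, each = mp$nFrames),
      frame = rep(seq_len(mp$nFrames) - 1L, mp$nCells),
      time_min = rep(t, mp$nCells),
      x_um = as.vector(X), y_um = as.vector(Y),
      nuc_ktr = ktr$nuc, cyt_ktr = ktr$cyt,
      nuc_loc = loc$nuc, cyt_loc = loc$cyt,
      population = rep(pop, each = mp$nFrames),
      valid = TRUE, stringsAsFactors = FALSE)

    names(truthCells) <- ids
    truth <- list(cells = truthCells, biasKappa = mp$biasKappa,
                  centerXy = mp$centerXy, biasOnsetMin = mp$biasOnsetMin,
                  inducibleLocFold = inducibleLocFold,
                  population = stats::setNames(pop, ids))
    list(tracks = tracks, truth = truth)
  })
}
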