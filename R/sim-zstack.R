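#' Parameters for simulated two-channel confocal z-stacks
#'
#' Describes a coculture monolayer imaged as a z-stack: nuclei are rendered
#' as isotropic 3-D Gaussian blobs on a pixel grid, with inducible-cell
#' nuclear centers drawn from `N(monolayerZMeanUm + extrusionOffsetUm,
#' monolayerZSdUm)` and all other nuclei from `N(monolayerZMeanUm,
#' monolayerZSdUm)`.  Channel 1 marks inducible nuclei only; channel 2
#' marks all nuclei, mirroring dual nuclear labeling of cocultures.
#' Voxel values are quantized to 16-bit integer counts as a detector would.
#'
#' @param nx,ny image size in pixels.
#' @param pixelSizeUm lateral pixel size, micrometers.
#' @param zMinUm,zMaxUm,zStepUm z range and step, micrometers (default a
#'   25 um range at 1 um steps).
#' @param nNuclei number of nuclei in the field.
#' @param inducibleFraction fraction of nuclei in the inducible population.
#' @param monolayerZMeanUm,monolayerZSdUm monolayer nuclear height
#'   distribution, micrometers (z = 0 at the lowest acquired plane,
#'   increasing apically).
#' @param extrusionOffsetUm true apical displacement of inducible nuclei
#'   (the ground-truth delta-Z), micrometers.
#' @param nucleusSigmaUm Gaussian radius of a rendered nucleus.
#' @param blobAmplitude peak voxel intensity of one nucleus, counts.
#' @param background mean background level, counts.
#' @param intensityNoiseSd Gaussian noise sd, counts.
#' @param seed integer seed or `NULL`.
#' @return list of class `"ZStackSimParams"`.
#' @export
zStackSimParams <- function(nx = 200, ny = 200, pixelSizeUm = 1,
                            zMinUm = 0, zMaxUm = 25, zStepUm = 1,
                            nNuclei = 150, inducibleFraction = 0.1,
                            monolayerZMeanUm = 8, monolayerZSdUm = 1.5,
                            extrusionOffsetUm = 0, nucleusSigmaUm = 2.5,
                            blobAmplitude = 500, background = 10,
                            intensityNoiseSd = 2, seed = NULL) {
  if (zStepUm <= 0) stop("zStepUm must be > 0")
  if (zMaxUm <= zMinUm) stop("zMaxUm must exceed zMinUm")
  if (extrusionOffsetUm < 0) stop("extrusionOffsetUm must be >= 0")
  if (inducibleFraction < 0 || inducibleFraction > 1)
    stop("inducibleFraction must lie in [0, 1]")
  structure(list(nx = nx, ny = ny, pixelSizeUm = pixelSizeUm,
                 zMinUm = zMinUm, zMaxUm = zMaxUm, zStepUm = zStepUm,
                 nNuclei = nNuclei, inducibleFraction = inducibleFraction,
                 monolayerZMeanUm = monolayerZMeanUm,
                 monolayerZSdUm = monolayerZSdUm,
                 extrusionOffsetUm = extrusionOffsetUm,
                 nucleusSigmaUm = nucleusSigmaUm,
                 blobAmplitude = blobAmplitude, background = background,
                 intensityNoiseSd = intensityNoiseSd, seed = seed),
            class = "ZStackSimParams")
}

# Render one 3-D Gaussian blob into `vol` (dims z, y, x) in place-ish;
# returns the updated array.  Separable exponentials over a bounded box.
renderBlob <- function(vol, zGrid, yGrid, xGrid, cx, cy, cz, sigma, amp) {
  gx <- exp(-(xGrid - cx)^2 / (2 * sigma^2))
  gy <- exp(-(yGrid - cy)^2 / (2 * sigma^2))
  gz <- exp(-(zGrid - cz)^2 / (2 * sigma^2))
  ix <- which(gx > 1e-4); iy <- which(gy > 1e-4); iz <- which(gz > 1e-4)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  blob <- amp * outer(gz[iz], outer(gy[iy], gx[ix]))
  vol[iz, iy, ix] <- vol[iz, iy, ix] + blob
  vol
}

#' Simulate a two-channel confocal z-stack with known ground truth
#'
#' @param params a [zStackSimParams()] object.
#' @param positionId identifier recorded in the ground truth.
#' @return list with `stack` (integer array `[channel, z, y, x]`, channel 1
#'   = inducible nuclei, channel 2 = all nuclei), `zStepUm`, and `truth`
#'   (true offset, per-nucleus centers and populations, rendered blob
#'   totals per channel, and `clipped`, set when the displaced height
#'   distribution would place appreciable nuclear mass outside the z
#'   range).
#' @export
#' @examples
#' sim <- simulateZStack(zStackSimParams(nx = 40, ny = 40, nNuclei = 10,
#'                                       seed = 1))
#' dim(sim$stack)
simulateZStack <- function(params, positionId = "pos_1") {
  p <- params
  withSeed(p$seed, {
    zGrid <- seq(p$zMinUm, p$zMaxUm, by = p$zStepUm)
    xGrid <- (seq_len(p$nx) - 0.5) * p$pixelSizeUm
    yGrid <- (seq_len(p$ny) - 0.5) * p$pixelSizeUm
    nz <- length(zGrid)

    nInd <- round(p$nNuclei * p$inducibleFraction)
    popn <- c(rep("inducible", nInd), rep("neighbor", p$nNuclei - nInd))
    cx <- stats::runif(p$nNuclei, 0, p$nx * p$pixelSizeUm)
    cy <- stats::runif(p$nNuclei, 0, p$ny * p$pixelSizeUm)
    muZ <- ifelse(popn == "inducible",
                  p$monolayerZMeanUm + p$extrusionOffsetUm,
                  p$monolayerZMeanUm)
    cz <- stats::rnorm(p$nNuclei, muZ, p$monolayerZSdUm)

    # warn (via ground truth) when the programmed offset pushes an
    # appreciable fraction of the displaced distribution out of range
    upperTail <- 1 - stats::pnorm(p$zMaxUm, p$monolayerZMeanUm +
                                    p$extrusionOffsetUm, p$monolayerZSdUm)
    lowerTail <- stats::pnorm(p$zMinUm, p$monolayerZMeanUm,
                              p$monolayerZSdUm)
    clipped <- (upperTail + lowerTail) > 0.01

    chInd <- array(0, dim = c(nz, p$ny, p$nx))
    chAll <- array(0, dim = c(nz, p$ny, p$nx))
    for (i in seq_len(p$nNuclei)) {
      chAll <- renderBlob(chAll, zGrid, yGrid, xGrid, cx[i], cy[i], cz[i],
                          p$nucleusSigmaUm, p$blobAmplitude)
      if (popn[i] == "inducible")
        chInd <- renderBlob(chInd, zGrid, yGrid, xGrid, cx[i], cy[i], cz[i],
                            p$nucleusSigmaUm, p$blobAmplitude)
    }
    blobTotals <- c(inducible = sum(chInd), all = sum(chAll))

    addNoise <- function(v) {
      v <- v + p$background
      if (p$intensityNoiseSd > 0)
        v <- v + stats::rnorm(length(v), 0, p$intensityNoiseSd)
      array(pmin(65535, pmax(0, round(v))), dim = dim(v))
    }
    stack <- array(0L, dim = c(2L, nz, p$ny, p$nx))
    stack[1, , , ] <- addNoise(chInd)
    stack[2, , , ] <- addNoise(chAll)
    storage.mode(stack) <- "integer"

    truth <- list(positionId = positionId,
                  extrusionOffsetUm = p$extrusionOffsetUm,
                  centers = data.frame(x_um = cx, y_um = cy, z_um = cz,
                                       population = popn,
                                       stringsAsFactors = FALSE),
                  blobTotals = blobTotals, clipped = clipped,
                  params = unclass(p))
    list(stack = stack, zStepUm = p$zStepUm, zMinUm = p$zMinUm,
         truth = truth)
  })
}
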