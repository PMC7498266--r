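#' Z-intensity histogram of one channel of a z-stack
#'
#' Per-plane total pixel intensity after background subtraction — up to
#' normalization, the intensity-weighted nuclear-height density of the
#' labeled population.  The background is estimated per stack and channel
#' as the median of the lowest-decile pixels and subtracted from every
#' pixel, clipping at zero.
#'
#' @param stack numeric array `[channel, z, y, x]` (see [simulateZStack()]
#'   and [readStack()]).
#' @param channel channel index, or `"inducible"` (1) / `"all"` (2).
#' @param zStepUm z step in micrometers.
#' @param zMinUm z coordinate of the lowest plane.
#' @param positionId identifier stored in the profile.
#' @return a [ZIntensityProfile].
#' @export
zIntensityHistogram <- function(stack, channel, zStepUm = 1, zMinUm = 0,
                                positionId = "pos_1") {
  chLabel <- if (is.character(channel)) channel else
    c("inducible", "all")[min(channel, 2)]
  ch <- if (is.character(channel))
    match(channel, c("inducible", "all")) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > dim(stack)[1])
    stop("unknown channel")
  vol <- stack[ch, , , , drop = TRUE]
  if (length(dim(vol)) != 3) stop("stack must be [channel, z, y, x]")
  px <- as.numeric(vol)
  bg <- stats::median(px[px <= stats::quantile(px, 0.1)])
  corrected <- pmax(vol - bg, 0)
  total <- apply(corrected, 1, sum)
  z <- zMinUm + (seq_along(total) - 1) * zStepUm
  new("ZIntensityProfile", positionId = positionId, channel = chLabel,
      zUm = z, totalIntensity = total)
}

#' Least-squares Gaussian fit of a z-intensity profile
#'
#' Fits `amplitude * exp(-(z - mean)^2 / (2 sigma^2)) + offset` to the
#' profile, initialized at moment estimates (intensity-weighted centroid
#' and sd, minimum plane value as offset).  On optimizer failure the
#' moment estimates are returned with `converged = FALSE`; such fits are
#' excluded from downstream condition statistics.
#'
#' @param profile a [ZIntensityProfile] with positive total mass.
#' @return a [GaussianFit].
#' @export
#' @examples
#' z <- 0:25
#' y <- 80 * exp(-(z - 12)^2 / (2 * 9)) + 3
#' pr <- new("ZIntensityProfile", positionId = "p", channel = "all",
#'           zUm = as.numeric(z), totalIntensity = y)
#' fittedMean(fitGaussianProfile(pr))
fitGaussianProfile <- function(profile) {
  z <- profile@zUm; y <- profile@totalIntensity
  if (sum(y) <= 0) stop("profile has zero total mass")
  step <- z[2] - z[1]
  m0 <- sum(z * y) / sum(y)
  s0 <- sqrt(max(sum(y * (z - m0)^2) / sum(y), (step / 2)^2))
  off0 <- min(y)
  amp0 <- max(y) - off0
  moments <- function(conv) new("GaussianFit", meanUm = m0, sigmaUm = s0,
    amplitude = amp0, offset = off0,
    rss = sum((y - (amp0 * exp(-(z - m0)^2 / (2 * s0^2)) + off0))^2),
    converged = conv, zRangeUm = range(z), zStepUm = step)
  if (amp0 <= 0) return(moments(FALSE))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ amp * exp(-(z - mu)^2 / (2 * sg^2)) + off,
      start = list(amp = amp0, mu = m0, sg = s0, off = off0),
      lower = c(0, min(z) - step, step / 4, -Inf),
      upper = c(Inf, max(z) + step, diff(range(z)), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(moments(FALSE))
  cf <- stats::coef(fit)
  new("GaussianFit", meanUm = unname(cf["mu"]), sigmaUm = unname(cf["sg"]),
      amplitude = unname(cf["amp"]), offset = unname(cf["off"]),
      rss = sum(stats::residuals(fit)^2), converged = TRUE,
      zRangeUm = range(z), zStepUm = step)
}

#' Extrusion statistic: difference of fitted z-profile means
#'
#' `deltaZ = fitted mean of the inducible channel - fitted mean of the
#' reference (all-cell) channel`, in micrometers; positive values mean the
#' inducible nuclei sit apical to the monolayer.  Defined only when both
#' fits converged.
#'
#' @param fitInducible,fitAll [GaussianFit] objects for the two channels.
#' @return delta-Z in micrometers, or `NA` with attribute
#'   `unconverged = TRUE` when either fit did not converge.
#' @export
deltaZ <- function(fitInducible, fitAll) {
  if (!fitInducible@converged || !fitAll@converged) {
    out <- NA_real_
    attr(out, "unconverged") <- TRUE
    return(out)
  }
  fittedMean(fitInducible) - fittedMean(fitAll)
}

#' Per-stack extrusion quantification
#'
#' Convenience wrapper: z-intensity histograms of both channels, Gaussian
#' fits, and the delta-Z statistic for one stack.
#'
#' @param stack array `[channel, z, y, x]` with channel 1 = inducible,
#'   channel 2 = all nuclei.
#' @inheritParams zIntensityHistogram
#' @return one-row data.frame: `position`, `delta_z_um`, `converged`.
#' @export
quantifyExtrusion <- function(stack, zStepUm = 1, zMinUm = 0,
                              positionId = "pos_1") {
  fi <- fitGaussianProfile(zIntensityHistogram(stack, "inducible", zStepUm,
                                               zMinUm, positionId))
  fa <- fitGaussianProfile(zIntensityHistogram(stack, "all", zStepUm,
                                               zMinUm, positionId))
  dz <- deltaZ(fi, fa)
  data.frame(position = positionId, delta_z_um = as.numeric(dz),
             converged = fi@converged && fa@converged,
             stringsAsFactors = FALSE)
}

#' Normalize extrusion results to a baseline condition
#'
#' Subtracts the mean baseline (parental) delta-Z from every observation,
#' so that the baseline condition's normalized mean is exactly zero (the
#' dashed line of the condition plots).
#'
#' @param deltaZUm numeric delta-Z observations, micrometers.
#' @param baselineDeltaZUm non-empty numeric vector of baseline (parental)
#'   delta-Z observations.
#' @return numeric vector of normalized delta-Z values.
#' @export
normalizeCondition <- function(deltaZUm, baselineDeltaZUm) {
  if (!length(baselineDeltaZUm)) stop("baseline must be non-empty")
  deltaZUm - mean(baselineDeltaZUm, na.rm = TRUE)
}

#' Flag outlier observations by a robust deviation rule
#'
#' Default rule: an observation is an outlier when its absolute deviation
#' from the median exceeds `k` times the MAD-based robust standard
#' deviation.  Flagged observations are retained in the output but are
#' meant to be excluded from condition means and tests.  The rule is
#' idempotent.
#'
#' @param values numeric observations (>= 4 required).
#' @param k deviation multiplier.
#' @return logical vector, `TRUE` for outliers.
#' @export
flagOutliers <- function(values, k = 3) {
  stopifnot(length(values) >= 4)
  med <- stats::median(values, na.rm = TRUE)
  s <- stats::mad(values, na.rm = TRUE)  # already scaled to sd
  if (s == 0) return(rep(FALSE, length(values)))
  abs(values - med) > k * s
}

#' Compare two extrusion conditions by Welch's t-test
#'
#' Two-sided two-sample t-test (unequal-variance form) between two sets of
#' (normalized, non-outlier) delta-Z observations, with star coding.
#'
#' @param a,b numeric observations, at least 2 each.
#' @return list with `t`, `p`, `stars`, `df`.
#' @export
compareConditions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 non-missing observations per condition required")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       stars = pStars(tt$p.value), df = unname(tt$parameter))
}
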