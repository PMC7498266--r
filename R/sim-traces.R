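#' Parameters for simulated pulsatile ERK activity traces
#'
#' Defines the pulse-train model used to emulate pulsatile single-cell ERK
#' activity: pulse apex times follow a homogeneous Poisson process thinned
#' by a refractory period, each pulse is a symmetric Gaussian bump in time,
#' and i.i.d. Gaussian noise is added per frame.  Defaults mirror a 6 h
#' movie acquired every 5 min.
#'
#' Pulse centers are restricted to lie at least `edgeMarginMin` from either
#' end of the movie (default one pulse width) so that every true pulse is
#' fully observed: a pulse truncated by the acquisition window has no
#' well-defined in-window apex, and ground-truth recovery is only well
#' posed for complete pulses.  Set `edgeMarginMin = 0` to allow clipped
#' pulses.
#'
#' @param durationMin movie length in minutes.
#' @param frameIntervalMin acquisition interval in minutes.
#' @param meanRate pulse rate in pulses per hour (before refractory
#'   thinning).
#' @param pulseAmplitude pulse height in ratio units.
#' @param pulseWidthMin pulse full width at half maximum, minutes.
#' @param baseline resting cytoplasm/nucleus ratio.
#' @param noiseSd per-frame additive Gaussian noise, ratio units.
#' @param refractoryMin minimum spacing between retained pulse centers.
#' @param edgeMarginMin exclusion margin at both trace ends, minutes.
#' @param seed integer seed or `NULL`.
#' @return a list of class `"PulseTrainParams"`.
#' @export
#' @examples
#' p <- pulseTrainParams(meanRate = 2, seed = 1)
#' sim <- simulateTrace(p)
#' peakCount(countPeaks(sim$trace))
pulseTrainParams <- function(durationMin = 360, frameIntervalMin = 5,
                             meanRate = 2, pulseAmplitude = 0.5,
                             pulseWidthMin = 25, baseline = 1,
                             noiseSd = 0.05, refractoryMin = 40,
                             edgeMarginMin = pulseWidthMin, seed = NULL) {
  if (durationMin <= 0 || frameIntervalMin <= 0)
    stop("durationMin and frameIntervalMin must be > 0")
  if (pulseWidthMin < frameIntervalMin)
    stop("pulseWidthMin must be >= frameIntervalMin")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (meanRate < 0) stop("meanRate must be >= 0")
  if (edgeMarginMin < 0) stop("edgeMarginMin must be >= 0")
  structure(list(durationMin = durationMin,
                 frameIntervalMin = frameIntervalMin, meanRate = meanRate,
                 pulseAmplitude = pulseAmplitude,
                 pulseWidthMin = pulseWidthMin, baseline = baseline,
                 noiseSd = noiseSd, refractoryMin = refractoryMin,
                 edgeMarginMin = edgeMarginMin, seed = seed),
            class = "PulseTrainParams")
}

#' Parameters for simulated sustained ERK activity traces
#'
#' Sustained dynamics are modeled as a logistic step from `baseline` to
#' `plateau` centered at `onsetMin`, with `riseTimeMin` the 10-90% rise
#' time, plus i.i.d. Gaussian noise.
#'
#' @param onsetMin time of half-maximal rise, minutes.
#' @param plateau post-rise cytoplasm/nucleus ratio (> baseline).
#' @param riseTimeMin 10-90% rise time, minutes.
#' @inheritParams pulseTrainParams
#' @return a list of class `"SustainedParams"`.
#' @export
sustainedParams <- function(onsetMin = 60, plateau = 1.5, riseTimeMin = 30,
                            baseline = 1, noiseSd = 0.05, durationMin = 360,
                            frameIntervalMin = 5, seed = NULL) {
  if (durationMin <= 0 || frameIntervalMin <= 0)
    stop("durationMin and frameIntervalMin must be > 0")
  if (plateau <= baseline) stop("plateau must exceed baseline")
  if (onsetMin < 0 || onsetMin >= durationMin)
    stop("onsetMin must lie in [0, durationMin)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(onsetMin = onsetMin, plateau = plateau,
                 riseTimeMin = riseTimeMin, baseline = baseline,
                 noiseSd = noiseSd, durationMin = durationMin,
                 frameIntervalMin = frameIntervalMin, seed = seed),
            class = "SustainedParams")
}

# Gaussian bump width: FWHM -> sigma.
fwhmToSigma <- function(w) w / (2 * sqrt(2 * log(2)))

# Draw Poisson pulse times on [margin, duration - margin] and thin by the
# refractory period (keep the first of any pair closer than refractoryMin).
drawPulseTimes <- function(params) {
  lo <- params$edgeMarginMin
  hi <- params$durationMin - params$edgeMarginMin
  if (hi <= lo || params$meanRate == 0) return(numeric(0))
  lambda <- params$meanRate / 60 * (hi - lo)
  n <- stats::rpois(1, lambda)
  if (n == 0) return(numeric(0))
  t0 <- sort(stats::runif(n, lo, hi))
  keep <- t0[1]
  for (ti in t0[-1])
    if (ti - keep[length(keep)] >= params$refractoryMin)
      keep <- c(keep, ti)
  keep
}

# Closed-form noiseless templates; exposed internally so tests can compare
# generated signals against them exactly.
pulseTemplate <- function(t, peakTimes, params) {
  s <- fwhmToSigma(params$pulseWidthMin)
  y <- rep(params$baseline, length(t))
  for (tp in peakTimes)
    y <- y + params$pulseAmplitude * exp(-(t - tp)^2 / (2 * s^2))
  y
}

sustainedTemplate <- function(t, params) {
  # logistic scale such that the 10-90% rise spans riseTimeMin
  sc <- params$riseTimeMin / (2 * log(9))
  params$baseline + (params$plateau - params$baseline) /
    (1 + exp(-(t - params$onsetMin) / sc))
}

#' Simulate a single-cell ERK activity trace with known ground truth
#'
#' Generates one [ActivityTrace] from either pulse-train or sustained
#' parameters, together with the ground truth needed for recovery tests.
#'
#' @param params a [pulseTrainParams()] or [sustainedParams()] object.
#' @param cellId identifier for the generated trace.
#' @return list with elements `trace` ([ActivityTrace]) and `truth` (list
#'   with `class` in pulsatile/sustained/quiescent, `peakTimes`, and the
#'   generating parameters).
#' @export
#' @examples
#' sim <- simulateTrace(pulseTrainParams(meanRate = 2, seed = 7))
#' sim$truth$peakTimes
simulateTrace <- function(params, cellId = "sim_1") {
  UseMethod("simulateTrace")
}

#' @export
simulateTrace.PulseTrainParams <- function(params, cellId = "sim_1") {
  withSeed(params$seed, {
    t <- seq(0, params$durationMin, by = params$frameIntervalMin)
    pk <- drawPulseTimes(params)
    y <- pulseTemplate(t, pk, params)
    if (params$noiseSd > 0) y <- y + stats::rnorm(length(t), 0, params$noiseSd)
    y <- pmax(y, .Machine$double.eps)
    trace <- new("ActivityTrace", cellId = cellId, timeMin = t, ratio = y,
                 coverage = 1, flags = character(0))
    truth <- list(class = if (length(pk)) "pulsatile" else "quiescent",
                  peakTimes = pk, params = unclass(params))
    list(trace = trace, truth = truth)
  })
}

#' @export
simulateTrace.SustainedParams <- function(params, cellId = "sim_1") {
  withSeed(params$seed, {
    t <- seq(0, params$durationMin, by = params$frameIntervalMin)
    y <- sustainedTemplate(t, params)
    if (params$noiseSd > 0) y <- y + stats::rnorm(length(t), 0, params$noiseSd)
    y <- pmax(y, .Machine$double.eps)
    trace <- new("ActivityTrace", cellId = cellId, timeMin = t, ratio = y,
                 coverage = 1, flags = character(0))
    truth <- list(class = "sustained", peakTimes = numeric(0),
                  onsetMin = params$onsetMin, params = unclass(params))
    list(trace = trace, truth = truth)
  })
}
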