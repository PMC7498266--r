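#' Peak-caller configuration
#'
#' Tunable parameters of the activity-peak caller.  An activity peak is a
#' local maximum whose rise from the preceding (Gaussian-refined) minimum
#' exceeds `minAmplitude`, whose rate of change between that minimum and
#' the maximum exceeds `minSlope`, and which is followed before the trace
#' end by a fall of at least `fallFraction` of the rise — the last rule is
#' what distinguishes a pulse from the onset of a sustained plateau.
#'
#' @param smoothWindow centered moving-mean window in frames used for
#'   extremum localization (1 = no smoothing).  The default 3 preserves
#'   20-30 min pulses sampled at 5 min.
#' @param fitHalfWidth half-width in frames of the Gaussian refinement
#'   window around each extremum.
#' @param minAmplitude minimum rise (ratio units) from the preceding
#'   minimum.
#' @param minSlope minimum rate of change, ratio units per minute.
#' @param fallFraction required fall after the peak, as a fraction of the
#'   rise.
#' @param noiseMult trace-adaptive noise floor: the rise must also exceed
#'   `noiseMult` times the trace's robust noise sd (median absolute
#'   successive difference / sqrt(2)), so the effective amplitude
#'   threshold scales with measurement noise; 0 disables.
#' @return list of class `"PeakConfig"`.
#' @export
peakConfig <- function(smoothWindow = 3L, fitHalfWidth = 2L,
                       minAmplitude = 0.15, minSlope = 0.005,
                       fallFraction = 0.5, noiseMult = 3) {
  stopifnot(smoothWindow >= 1, fitHalfWidth >= 1, minAmplitude >= 0,
            minSlope >= 0, fallFraction >= 0, fallFraction <= 1,
            noiseMult >= 0)
  structure(list(smoothWindow = as.integer(smoothWindow),
                 fitHalfWidth = as.integer(fitHalfWidth),
                 minAmplitude = minAmplitude, minSlope = minSlope,
                 fallFraction = fallFraction, noiseMult = noiseMult),
            class = "PeakConfig")
}

# Locate local maxima and minima of a series, ties broken toward the
# earlier frame (zero first differences are backward-filled with the next
# nonzero difference so a plateau's first point is the extremum).
localExtrema <- function(s) {
  n <- length(s)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- sign(diff(s))
  if (!any(d != 0)) return(list(maxima = integer(0), minima = integer(0)))
  # backward-fill zeros with the next nonzero sign, then forward-fill any
  # trailing plateau with the preceding sign
  filled <- d
  nxt <- 0
  for (k in rev(seq_along(d))) {
    if (d[k] != 0) nxt <- d[k] else filled[k] <- nxt
  }
  prev <- 0
  for (k in seq_along(filled)) {
    if (filled[k] != 0) prev <- filled[k] else filled[k] <- prev
  }
  i <- 2:(n - 1)
  list(maxima = i[filled[i - 1] > 0 & filled[i] < 0],
       minima = i[filled[i - 1] < 0 & filled[i] > 0])
}

# Least-squares Gaussian refinement of one extremum on the *raw* trace:
# fits amp * exp(-(t - mu)^2 / (2 sg^2)) + off (sign-flipped for minima)
# over points within +/- halfWidth frames of the candidate, returning the
# sub-frame extremum time and value.  Degenerate windows (too few points,
# constant values, non-convergence, or a fitted center escaping the
# window) fall back to the raw frame value.
fitExtremum <- function(t, x, tCenter, halfWidthFrames, frameInterval,
                        maximum = TRUE) {
  tol <- frameInterval * (halfWidthFrames + 0.01)
  i <- which(abs(t - tCenter) <= tol)
  raw <- which.min(abs(t - tCenter))
  fallback <- list(time = t[raw], value = x[raw], refined = FALSE)
  if (length(i) < 4) return(fallback)
  tw <- t[i]; xw <- if (maximum) x[i] else -x[i]
  if (max(xw) - min(xw) < .Machine$double.eps * 100) return(fallback)
  st <- list(amp = max(xw) - min(xw), mu = tCenter,
             sg = frameInterval * halfWidthFrames, off = min(xw))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      xw ~ amp * exp(-(tw - mu)^2 / (2 * sg^2)) + off, start = st,
      lower = c(0, min(tw), frameInterval / 4, -Inf),
      upper = c(Inf, max(tw), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  cf <- stats::coef(fit)
  val <- cf[["amp"]] + cf[["off"]]
  if (!is.finite(val) || !is.finite(cf[["mu"]])) return(fallback)
  # a fitted apex escaping the window's data range marks an ill-conditioned
  # fit (few points, 4 parameters): keep the raw extremum instead.  The
  # true apex can only exceed the sampled maximum by the sampling loss,
  # a small fraction of the local amplitude.
  slack <- 0.15 * (max(xw) - min(xw))
  if (val > max(xw) + slack || val < min(xw) - slack) return(fallback)
  list(time = cf[["mu"]], value = if (maximum) val else -val,
       refined = TRUE)
}

#' Count ERK activity peaks in a single-cell trace
#'
#' Detects activity pulses in a cleaned [ActivityTrace]: the trace is
#' lightly smoothed (moving mean) to localize candidate local maxima and
#' minima, each extremum is refined by a least-squares Gaussian (inverted
#' for minima) fit over a small window of raw frames to obtain sub-frame
#' extremum times and values, and a candidate maximum is called a peak when
#' the rise from the preceding fitted minimum, the rate of change between
#' them, and a subsequent fall all pass the [peakConfig()] thresholds.
#' Plateaus that never fall are not peaks.
#'
#' Internal gaps in the trace are linearly interpolated for smoothing and
#' extremum localization only; amplitude measurements use raw frames.
#'
#' @param trace an [ActivityTrace] with at least 5 frames.
#' @param config a [peakConfig()].
#' @return a [PeakSet].
#' @export
#' @examples
#' sim <- simulateTrace(pulseTrainParams(meanRate = 2, noiseSd = 0, seed = 2))
#' peakCount(countPeaks(sim$trace))
countPeaks <- function(trace, config = peakConfig()) {
  t <- timeMin(trace); x <- ratioValues(trace)
  n <- length(t)
  if (n < 5) stop("trace must have at least 5 frames")
  if (n < 2 * config$fitHalfWidth + 1)
    stop("trace shorter than the Gaussian fit window")
  interval <- inferFrameInterval(t)
  # effective amplitude threshold: fixed floor or noise-adaptive floor,
  # whichever is larger
  # robust noise estimate from the residual about a 3-frame moving mean
  # (x_i minus the local mean has sd sigma*sqrt(2/3) for white noise, and
  # the slow pulse signal contributes only its curvature, which is small
  # at this sampling)
  sigmaHat <- if (length(x) > 4)
    stats::mad(x - movingMean(x, 3L)) / sqrt(2 / 3) else 0
  minAmp <- max(config$minAmplitude, config$noiseMult * sigmaHat)

  g <- interpToGrid(t, x, interval)
  s <- movingMean(g$x, config$smoothWindow)
  ext <- localExtrema(s)
  if (!length(ext$maxima))
    return(new("PeakSet", cellId = cellId(trace), peakTimes = numeric(0),
               peakAmplitudes = numeric(0)))

  # Gaussian refinement operates on the smoothed series: the fit averages
  # over the window, so extremum values are far less noise-inflated than
  # single raw frames, while symmetric smoothing leaves apex times
  # unbiased.
  fitMax <- lapply(g$time[ext$maxima], fitExtremum, t = g$time, x = s,
                   halfWidthFrames = config$fitHalfWidth,
                   frameInterval = interval, maximum = TRUE)
  fitMin <- lapply(g$time[ext$minima], fitExtremum, t = g$time, x = s,
                   halfWidthFrames = config$fitHalfWidth,
                   frameInterval = interval, maximum = FALSE)
  minVals <- vapply(fitMin, `[[`, numeric(1), "value")

  peakT <- numeric(0); peakA <- numeric(0)
  for (j in seq_along(ext$maxima)) {
    fm <- fitMax[[j]]
    iMaxGrid <- ext$maxima[j]
    # preceding valley: the deepest fitted minimum between the previous
    # candidate maximum and this one (so flank noise dips do not truncate
    # the rise, and the shallow dip of a noise-split apex yields a small
    # rise that is rejected); at the trace start, the pre-peak smoothed
    # minimum
    lower <- if (j > 1) ext$maxima[j - 1] else 0L
    between <- which(ext$minima > lower & ext$minima < iMaxGrid)
    if (length(between)) {
      pm <- fitMin[[between[which.min(minVals[between])]]]
    } else {
      pre <- seq_len(iMaxGrid)
      k <- pre[which.min(s[pre])]
      pm <- list(time = g$time[k], value = s[k])
    }
    rise <- fm$value - pm$value
    if (rise <= minAmp) next
    # rate of change is measured from the pulse onset: the last time
    # before the apex at which the smoothed trace sits within 10% of the
    # rise above the valley.  For a valley hugging the peak this is the
    # valley time; for an isolated pulse after a long flat baseline it is
    # the departure from baseline, so a distant minimum cannot dilute the
    # slope of a genuinely fast rise.
    pre <- seq_len(iMaxGrid)
    onsetIdx <- pre[s[pre] <= pm$value + 0.1 * rise]
    tOnset <- if (length(onsetIdx)) g$time[max(onsetIdx)] else pm$time
    dt <- fm$time - tOnset
    if (dt <= 0 || rise / dt <= config$minSlope) next
    # subsequent fall: lowest smoothed level between the peak and trace end
    after <- s[iMaxGrid:length(s)]
    fall <- fm$value - min(after)
    if (fall < config$fallFraction * rise) next
    peakT <- c(peakT, fm$time); peakA <- c(peakA, rise)
  }
  ord <- order(peakT)
  peakT <- peakT[ord]; peakA <- peakA[ord]
  # two fitted apexes within one frame are the same peak: keep the larger
  keep <- rep(TRUE, length(peakT))
  if (length(peakT) > 1) for (j in 2:length(peakT)) {
    if (peakT[j] - peakT[j - 1] < interval) {
      if (peakA[j] >= peakA[j - 1]) keep[j - 1] <- FALSE else keep[j] <- FALSE
    }
  }
  new("PeakSet", cellId = cellId(trace), peakTimes = peakT[keep],
      peakAmplitudes = peakA[keep])
}
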