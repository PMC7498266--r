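#' @import methods
NULL

#' ActivityTrace: one cell's ERK activity time course
#'
#' Holds the cytoplasm/nucleus KTR intensity ratio of a single cell over
#' time.  The ERK kinase translocation reporter leaves the nucleus when ERK
#' is active, so a higher cytoplasm/nucleus ratio reports higher ERK
#' activity.  Frames dropped during ratio computation (segmentation errors,
#' missing detections) simply do not appear in `timeMin`; gaps must remain
#' integer multiples of the acquisition interval.
#'
#' @slot cellId character scalar, cell identifier.
#' @slot timeMin numeric, strictly increasing frame times in minutes.
#' @slot ratio numeric, cytoplasm/nucleus KTR intensity ratio per retained
#'   frame (dimensionless, > 0).
#' @slot coverage numeric in (0, 1], fraction of experiment frames present.
#' @slot flags character, any of `"track_switch"`, `"segmentation_error"`.
#'
#' @seealso [computeActivityTrace()], [cleanTraces()], [countPeaks()]
#' @export
setClass("ActivityTrace",
  representation(cellId = "character", timeMin = "numeric",
                 ratio = "numeric", coverage = "numeric",
                 flags = "character"),
  prototype(cellId = NA_character_, timeMin = numeric(0), ratio = numeric(0),
            coverage = 1, flags = character(0)))

setValidity("ActivityTrace", function(object) {
  msg <- character(0)
  if (length(object@timeMin) != length(object@ratio))
    msg <- c(msg, "timeMin and ratio must have equal length")
  if (length(object@timeMin) > 1 && any(diff(object@timeMin) <= 0))
    msg <- c(msg, "timeMin must be strictly increasing")
  if (any(!is.finite(object@ratio)) || any(object@ratio <= 0))
    msg <- c(msg, "ratio must be finite and > 0 at all retained frames")
  if (length(object@coverage) != 1 || is.na(object@coverage) ||
      object@coverage <= 0 || object@coverage > 1)
    msg <- c(msg, "coverage must be a scalar in (0, 1]")
  if (!all(object@flags %in% c("track_switch", "segmentation_error")))
    msg <- c(msg, "unknown flag")
  if (length(object@timeMin) > 2) {
    d <- diff(object@timeMin)
    base <- min(d)
    if (any(abs(d / base - round(d / base)) > 1e-6))
      msg <- c(msg, "time gaps must be integer multiples of the frame interval")
  }
  if (length(msg)) msg else TRUE
})

#' LocalizationTrace: nuclear/cytoplasmic localization of the tagged kinase
#'
#' Time course of the nucleus/cytoplasm intensity ratio of the fluorescently
#' tagged ERK kinase itself (distinct from the KTR activity reporter): a
#' rising N/C ratio reports nuclear translocation of the kinase.
#'
#' @slot cellId character scalar.
#' @slot timeMin numeric, strictly increasing minutes.
#' @slot ncRatio numeric > 0, nucleus/cytoplasm intensity ratio.
#' @seealso [localizationFoldChange()]
#' @export
setClass("LocalizationTrace",
  representation(cellId = "character", timeMin = "numeric",
                 ncRatio = "numeric"),
  prototype(cellId = NA_character_, timeMin = numeric(0),
            ncRatio = numeric(0)))

setValidity("LocalizationTrace", function(object) {
  msg <- character(0)
  if (length(object@timeMin) != length(object@ncRatio))
    msg <- c(msg, "timeMin and ncRatio must have equal length")
  if (length(object@timeMin) > 1 && any(diff(object@timeMin) <= 0))
    msg <- c(msg, "timeMin must be strictly increasing")
  if (any(!is.finite(object@ncRatio)) || any(object@ncRatio <= 0))
    msg <- c(msg, "ncRatio must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' PeakSet: called activity peaks for one cell
#'
#' @slot cellId character scalar.
#' @slot peakTimes numeric, strictly increasing peak apex times in minutes
#'   (sub-frame resolution from Gaussian refinement).
#' @slot peakAmplitudes numeric > 0, rise from the preceding fitted minimum
#'   to each fitted maximum, in ratio units.
#' @seealso [countPeaks()], [peakCount()]
#' @export
setClass("PeakSet",
  representation(cellId = "character", peakTimes = "numeric",
                 peakAmplitudes = "numeric"),
  prototype(cellId = NA_character_, peakTimes = numeric(0),
            peakAmplitudes = numeric(0)))

setValidity("PeakSet", function(object) {
  msg <- character(0)
  if (length(object@peakTimes) != length(object@peakAmplitudes))
    msg <- c(msg, "peakTimes and peakAmplitudes must have equal length")
  if (length(object@peakTimes) > 1 && any(diff(object@peakTimes) <= 0))
    msg <- c(msg, "peakTimes must be strictly increasing")
  if (any(object@peakAmplitudes <= 0))
    msg <- c(msg, "peakAmplitudes must be > 0")
  if (length(msg)) msg else TRUE
})

#' DynamicsCall: per-cell dynamics classification
#'
#' Formalizes the pulsatile/sustained dichotomy of single-cell ERK dynamics
#' as a pure function of trace features: a cell is `sustained` when its duty
#' cycle (fraction of post-induction frames above the activity threshold)
#' exceeds the sustained cutoff, `pulsatile` when not sustained but showing
#' at least the minimum number of called peaks, `quiescent` otherwise.
#'
#' @slot cellId character scalar.
#' @slot label one of `"pulsatile"`, `"sustained"`, `"quiescent"`.
#' @slot features named numeric: `peak_count`, `duty_cycle`,
#'   `final_window_mean`.
#' @seealso [classifyDynamics()]
#' @export
setClass("DynamicsCall",
  representation(cellId = "character", label = "character",
                 features = "numeric"))

setValidity("DynamicsCall", function(object) {
  msg <- character(0)
  if (!object@label %in% c("pulsatile", "sustained", "quiescent"))
    msg <- c(msg, "label must be pulsatile, sustained or quiescent")
  need <- c("peak_count", "duty_cycle", "final_window_mean")
  if (!all(need %in% names(object@features)))
    msg <- c(msg, paste("features must contain",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AngleSample: migration angles for one condition and epoch
#'
#' Collection of per-cell, per-interval migration angles in degrees, where
#' 0 deg is motion directly toward the inducible-cell group center and
#' 180 deg directly away.  Angles are folded to [0, 180] because the
#' toward/away statistic is symmetric about the center axis.
#'
#' @slot condition character scalar condition label.
#' @slot epoch character scalar, conventionally `"before"` or `"after"`.
#' @slot anglesDeg numeric in [0, 180].
#' @slot nCells integer, number of distinct cells contributing.
#' @seealso [migrationAngle()], [radialHistogram()], [subsampledKsTest()]
#' @export
setClass("AngleSample",
  representation(condition = "character", epoch = "character",
                 anglesDeg = "numeric", nCells = "integer"),
  prototype(condition = NA_character_, epoch = NA_character_,
            anglesDeg = numeric(0), nCells = 0L))

setValidity("AngleSample", function(object) {
  msg <- character(0)
  a <- object@anglesDeg
  if (any(!is.finite(a)) || any(a < 0) || any(a > 180))
    msg <- c(msg, "all angles must lie in [0, 180] degrees")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SubsamplingKSResult: subsampled two-sample KS test summary
#'
#' Result of the subsampling procedure used to compare large migration-angle
#' samples: repeated subsamples of fixed size are drawn from each group, a
#' two-sample Kolmogorov-Smirnov test is run per iteration, and the median
#' p-value over iterations is reported (with the usual star coding).
#'
#' @slot medianP numeric in [0, 1].
#' @slot nIterations integer >= 1.
#' @slot subsampleSize integer of length 2, the per-group subsample sizes
#'   actually used.
#' @slot statD numeric, per-iteration KS D statistics.
#' @slot pValues numeric, per-iteration p-values.
#' @slot stars character scalar star code for `medianP`.
#' @seealso [subsampledKsTest()]
#' @export
setClass("SubsamplingKSResult",
  representation(medianP = "numeric", nIterations = "integer",
                 subsampleSize = "integer", statD = "numeric",
                 pValues = "numeric", stars = "character"))

setValidity("SubsamplingKSResult", function(object) {
  msg <- character(0)
  if (object@medianP < 0 || object@medianP > 1)
    msg <- c(msg, "medianP must lie in [0, 1]")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (length(object@pValues) != object@nIterations ||
      length(object@statD) != object@nIterations)
    msg <- c(msg, "per-iteration vectors must have length nIterations")
  if (length(msg)) msg else TRUE
})

#' ZIntensityProfile: summed channel intensity as a function of z
#'
#' Per-plane total (background-corrected) pixel intensity of one channel of
#' a confocal z-stack, the raw material of the extrusion statistic: up to
#' normalization this is the intensity-weighted nuclear-height density.
#'
#' @slot positionId character scalar imaging-position identifier.
#' @slot channel character scalar, conventionally `"inducible"` or `"all"`.
#' @slot zUm numeric, ascending z grid in micrometers with constant step.
#' @slot totalIntensity numeric >= 0, one value per plane.
#' @seealso [zIntensityHistogram()], [fitGaussianProfile()]
#' @export
setClass("ZIntensityProfile",
  representation(positionId = "character", channel = "character",
                 zUm = "numeric", totalIntensity = "numeric"))

setValidity("ZIntensityProfile", function(object) {
  msg <- character(0)
  z <- object@zUm
  if (length(z) < 5L) msg <- c(msg, "profile must have at least 5 planes")
  if (length(z) != length(object@totalIntensity))
    msg <- c(msg, "zUm and totalIntensity must have equal length")
  if (length(z) > 1) {
    d <- diff(z)
    if (any(d <= 0)) msg <- c(msg, "zUm must be strictly increasing")
    else if (max(d) - min(d) > 1e-6 * mean(d))
      msg <- c(msg, "zUm must have a constant step")
  }
  if (any(object@totalIntensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GaussianFit: least-squares Gaussian fit of a z-intensity profile
#'
#' Parameters of the model `amplitude * exp(-(z - mean)^2 / (2 sigma^2)) +
#' offset` fitted to a [ZIntensityProfile].  When the optimizer fails the
#' moment estimates are returned with `converged = FALSE`.
#'
#' @slot meanUm fitted center in micrometers.
#' @slot sigmaUm fitted width (> 0) in micrometers.
#' @slot amplitude fitted amplitude, arbitrary units.
#' @slot offset fitted baseline, arbitrary units.
#' @slot rss residual sum of squares.
#' @slot converged logical optimizer status.
#' @slot zRangeUm numeric length-2, z range of the fitted profile.
#' @slot zStepUm z step of the fitted profile.
#' @seealso [fitGaussianProfile()], [deltaZ()]
#' @export
setClass("GaussianFit",
  representation(meanUm = "numeric", sigmaUm = "numeric",
                 amplitude = "numeric", offset = "numeric", rss = "numeric",
                 converged = "logical", zRangeUm = "numeric",
                 zStepUm = "numeric"))

setValidity("GaussianFit", function(object) {
  msg <- character(0)
  if (object@sigmaUm <= 0) msg <- c(msg, "sigmaUm must be > 0")
  if (length(object@zRangeUm) == 2 && is.finite(object@zStepUm)) {
    lo <- object@zRangeUm[1] - object@zStepUm
    hi <- object@zRangeUm[2] + object@zStepUm
    if (object@meanUm < lo || object@meanUm > hi)
      msg <- c(msg, "meanUm must lie within [zMin - step, zMax + step]")
  }
  if (length(msg)) msg else TRUE
})
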