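#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases cellId,ActivityTrace-method
setMethod("cellId", "ActivityTrace", function(object) object@cellId)
#' @rdname accessors
setMethod("cellId", "LocalizationTrace", function(object) object@cellId)
#' @rdname accessors
setMethod("cellId", "PeakSet", function(object) object@cellId)
#' @rdname accessors
setMethod("cellId", "DynamicsCall", function(object) object@cellId)

#' @rdname accessors
setMethod("timeMin", "ActivityTrace", function(object) object@timeMin)
#' @rdname accessors
setMethod("timeMin", "LocalizationTrace", function(object) object@timeMin)

#' @rdname accessors
setMethod("ratioValues", "ActivityTrace", function(object) object@ratio)
#' @rdname accessors
setMethod("ratioValues", "LocalizationTrace", function(object) object@ncRatio)

#' @rdname accessors
setMethod("coverage", "ActivityTrace", function(object) object@coverage)
#' @rdname accessors
setMethod("traceFlags", "ActivityTrace", function(object) object@flags)

#' @rdname accessors
setMethod("peakTimes", "PeakSet", function(object) object@peakTimes)
#' @rdname accessors
setMethod("peakAmplitudes", "PeakSet", function(object) object@peakAmplitudes)
#' @rdname accessors
setMethod("peakCount", "PeakSet", function(object) length(object@peakTimes))

#' @rdname accessors
setMethod("dynamicsLabel", "DynamicsCall", function(object) object@label)
#' @rdname accessors
setMethod("dynamicsFeatures", "DynamicsCall", function(object) object@features)

#' @rdname accessors
setMethod("angles", "AngleSample", function(object) object@anglesDeg)
#' @rdname accessors
setMethod("nObservations", "AngleSample",
          function(object) length(object@anglesDeg))

#' @rdname accessors
setMethod("medianP", "SubsamplingKSResult", function(object) object@medianP)

#' @rdname accessors
setMethod("fittedMean", "GaussianFit", function(object) object@meanUm)
#' @rdname accessors
setMethod("fittedSigma", "GaussianFit", function(object) object@sigmaUm)

setMethod("show", "ActivityTrace", function(object) {
  cat("ActivityTrace for cell", object@cellId, "\n")
  cat(sprintf("  %d frames, %.0f-%.0f min, coverage %.2f\n",
              length(object@timeMin),
              if (length(object@timeMin)) min(object@timeMin) else NA,
              if (length(object@timeMin)) max(object@timeMin) else NA,
              object@coverage))
  if (length(object@ratio))
    cat(sprintf("  C/N ratio: median %.3f, range [%.3f, %.3f]\n",
                stats::median(object@ratio), min(object@ratio),
                max(object@ratio)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet for cell %s: %d peak(s)\n", object@cellId,
              length(object@peakTimes)))
  if (length(object@peakTimes))
    cat("  times (min):", paste(round(object@peakTimes, 1), collapse = ", "),
        "\n")
  invisible(NULL)
})

setMethod("show", "DynamicsCall", function(object) {
  cat(sprintf("DynamicsCall for cell %s: %s\n", object@cellId, object@label))
  f <- object@features
  cat(sprintf("  peaks %g, duty cycle %.2f, final-window mean %.3f\n",
              f[["peak_count"]], f[["duty_cycle"]],
              f[["final_window_mean"]]))
  invisible(NULL)
})

setMethod("show", "AngleSample", function(object) {
  cat(sprintf("AngleSample '%s' (%s): %d angles from %d cells\n",
              object@condition, object@epoch, length(object@anglesDeg),
              object@nCells))
  if (length(object@anglesDeg))
    cat(sprintf("  median angle %.1f deg\n",
                stats::median(object@anglesDeg)))
  invisible(NULL)
})

setMethod("show", "SubsamplingKSResult", function(object) {
  cat(sprintf(
    "Subsampled two-sample KS: median p = %.4g (%s)\n",
    object@medianP, object@stars))
  cat(sprintf("  %d iterations, subsample sizes %s\n", object@nIterations,
              paste(object@subsampleSize, collapse = "/")))
  invisible(NULL)
})

setMethod("show", "ZIntensityProfile", function(object) {
  cat(sprintf("ZIntensityProfile '%s' channel '%s': %d planes, z %.1f-%.1f um\n",
              object@positionId, object@channel, length(object@zUm),
              min(object@zUm), max(object@zUm)))
  invisible(NULL)
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: mean %.2f um, sigma %.2f um (%s)\n", object@meanUm,
    object@sigmaUm,
    if (object@converged) "converged" else "moment fallback"))
  invisible(NULL)
})
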