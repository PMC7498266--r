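#' @include AllClasses.R
NULL

#' Accessors for mapkdyn S4 containers
#'
#' Small accessor family mirroring the slots of the core containers; user
#' code should use these rather than `@`.
#'
#' @param object a mapkdyn S4 object.
#' @return the slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("timeMin", function(object) standardGeneric("timeMin"))

#' @rdname accessors
#' @export
setGeneric("ratioValues", function(object) standardGeneric("ratioValues"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("traceFlags", function(object) standardGeneric("traceFlags"))

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' @rdname accessors
#' @export
setGeneric("peakAmplitudes",
           function(object) standardGeneric("peakAmplitudes"))

#' @rdname accessors
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))

#' @rdname accessors
#' @export
setGeneric("dynamicsLabel", function(object) standardGeneric("dynamicsLabel"))

#' @rdname accessors
#' @export
setGeneric("dynamicsFeatures",
           function(object) standardGeneric("dynamicsFeatures"))

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("nObservations", function(object) standardGeneric("nObservations"))

#' @rdname accessors
#' @export
setGeneric("medianP", function(object) standardGeneric("medianP"))

#' @rdname accessors
#' @export
setGeneric("fittedMean", function(object) standardGeneric("fittedMean"))

#' @rdname accessors
#' @export
setGeneric("fittedSigma", function(object) standardGeneric("fittedSigma"))
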