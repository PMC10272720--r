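#' @include AllClasses.R
NULL

#' Accessors for AngioTIC classes
#'
#' Small accessor generics: slot access in user code should go through
#' these rather than `@`.
#'
#' @param object an AngioTIC S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("resolution", function(object) standardGeneric("resolution"))

#' @rdname accessors
#' @export
setGeneric("frameCount", function(object) standardGeneric("frameCount"))

#' @rdname accessors
#' @export
setGeneric("frameDim", function(object) standardGeneric("frameDim"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("centerlinePoints", function(object)
  standardGeneric("centerlinePoints"))

#' @rdname accessors
#' @export
setGeneric("cumulativeArcPx", function(object)
  standardGeneric("cumulativeArcPx"))

#' @rdname accessors
#' @export
setGeneric("ticValues", function(object) standardGeneric("ticValues"))

#' @rdname accessors
#' @export
setGeneric("peakFrames", function(object) standardGeneric("peakFrames"))

#' @rdname accessors
#' @export
setGeneric("perPeakVelocities", function(object)
  standardGeneric("perPeakVelocities"))

#' @rdname accessors
#' @export
setGeneric("meanVelocity", function(object) standardGeneric("meanVelocity"))

#' @rdname accessors
#' @export
setGeneric("sdVelocity", function(object) standardGeneric("sdVelocity"))

#' @rdname accessors
#' @export
setGeneric("diameterMm", function(object) standardGeneric("diameterMm"))

#' @rdname accessors
#' @export
setGeneric("retentionPct", function(object) standardGeneric("retentionPct"))
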