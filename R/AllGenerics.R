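#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the package's S4 containers. Slot access via \code{@} is
#' discouraged; use these instead.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("roiIntensity", function(x) standardGeneric("roiIntensity"))

#' @rdname accessors
#' @export
setGeneric("referenceIntensity", function(x) standardGeneric("referenceIntensity"))

#' @rdname accessors
#' @export
setGeneric("backgroundIntensity", function(x) standardGeneric("backgroundIntensity"))

#' @rdname accessors
#' @export
setGeneric("nPre", function(x) standardGeneric("nPre"))

#' @rdname accessors
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))

#' @rdname accessors
#' @export
setGeneric("recoveryRate", function(x) standardGeneric("recoveryRate"))

#' @rdname accessors
#' @export
setGeneric("halfTime", function(x) standardGeneric("halfTime"))

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("foldEnrichment", function(x, ...) standardGeneric("foldEnrichment"))

#' @rdname accessors
#' @export
setGeneric("percentRemaining", function(x) standardGeneric("percentRemaining"))

#' @rdname accessors
#' @export
setGeneric("endpointDepletion", function(x) standardGeneric("endpointDepletion"))

#' @rdname accessors
#' @export
setGeneric("controlDepletion", function(x) standardGeneric("controlDepletion"))

#' @rdname accessors
#' @export
setGeneric("correctedRedistribution",
           function(x) standardGeneric("correctedRedistribution"))

#' @rdname accessors
#' @export
setGeneric("cycleFractions", function(x) standardGeneric("cycleFractions"))
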