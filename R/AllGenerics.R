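#' @rdname PulseEventSet-class
#' @param x,object a \code{PulseEventSet}, \code{EventFeatureTable} or
#'   other cytogate object.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname PulseEventSet-class
#' @export
setGeneric("sampleSpacing", function(x) standardGeneric("sampleSpacing"))

#' @rdname PulseEventSet-class
#' @export
setGeneric("adcMax", function(x) standardGeneric("adcMax"))

#' @rdname PulseEventSet-class
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' @rdname EventFeatureTable-class
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname EventFeatureTable-class
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' @rdname ClassificationResult-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname ClassificationResult-class
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname ClassificationResult-class
#' @export
setGeneric("viabilityPercent", function(x) standardGeneric("viabilityPercent"))

#' @rdname ClassificationResult-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
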