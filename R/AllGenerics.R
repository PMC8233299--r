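#' @rdname samplingSpec
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname samplingSpec
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname samplingSpec
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))
#' @rdname samplingSpec
#' @export
setGeneric("deltaFHz", function(x) standardGeneric("deltaFHz"))
#' @rdname samplingSpec
#' @export
setGeneric("durationSeconds", function(x) standardGeneric("durationSeconds"))

#' @rdname bandAccessors
#' @export
setGeneric("loHz", function(x) standardGeneric("loHz"))
#' @rdname bandAccessors
#' @export
setGeneric("hiHz", function(x) standardGeneric("hiHz"))
#' @rdname bandAccessors
#' @export
setGeneric("centerIndex", function(x) standardGeneric("centerIndex"))
#' @rdname bandAccessors
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname bandAccessors
#' @export
setGeneric("widthRatio", function(x) standardGeneric("widthRatio"))

#' @rdname bandTable
#' @export
setGeneric("bandTable", function(x, ...) standardGeneric("bandTable"))

#' @rdname decomposeBands
#' @export
setGeneric("decomposeBands",
  function(ts, bandset, ...) standardGeneric("decomposeBands"))

#' @rdname decodedAccessors
#' @export
setGeneric("bandComponent", function(x, band) standardGeneric("bandComponent"))
#' @rdname decodedAccessors
#' @export
setGeneric("residualComponent", function(x) standardGeneric("residualComponent"))
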