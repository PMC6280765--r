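#' @rdname GenomeIndex-class
#' @param x,object an object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeIndex-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname EndSignalTrack-class
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @rdname EndSignalTrack-class
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txInfo", function(x) standardGeneric("txInfo"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txExons", function(x, id) standardGeneric("txExons"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txLength", function(x, id) standardGeneric("txLength"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("txTPM", function(x, id) standardGeneric("txTPM"))

#' @rdname LibraryStats-class
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))

#' @rdname TranscriptTrack-class
#' @export
setGeneric("maskedMass", function(x) standardGeneric("maskedMass"))
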