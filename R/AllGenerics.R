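#' @include AllClasses.R
NULL

#' @rdname ConcatenatedReference-class
#' @param x a \linkS4class{ConcatenatedReference}.
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname ConcatenatedReference-class
#' @export
setGeneric("scaffoldOffsets", function(x) standardGeneric("scaffoldOffsets"))

#' @rdname ConcatenatedReference-class
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' @rdname TagArray-class
#' @param x a \linkS4class{TagArray}.
#' @param strand \code{"+"} or \code{"-"}.
#' @export
setGeneric("strandTrack", function(x, strand) standardGeneric("strandTrack"))

#' @rdname TagArray-class
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname SimTruth-class
#' @param x a \linkS4class{SimTruth}.
#' @export
setGeneric("trueTpm", function(x) standardGeneric("trueTpm"))

#' @rdname SimTruth-class
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))

#' @rdname SOMGrid-class
#' @param x a \linkS4class{SOMGrid}.
#' @export
setGeneric("somAssignment", function(x) standardGeneric("somAssignment"))

#' @rdname SOMGrid-class
#' @export
setGeneric("somCodebook", function(x) standardGeneric("somCodebook"))
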