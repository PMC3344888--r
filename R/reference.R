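#' @include AllGenerics.R
NULL

#' Build a concatenated reference with 60-N spacers
#'
#' Joins all scaffolds of a genome into a single sequence, appending a run of
#' \code{spacer} \code{N}s after each segment, and records the offset map so
#' that scaffold-local and concatenated-global coordinates round-trip
#' exactly. Mapping is performed against this single sequence; tags can never
#' align across a spacer because \code{N} has no di-base color.
#'
#' @param genome a named \code{DNAStringSet} (or named character vector of
#'   sequences).
#' @param spacer integer, number of \code{N}s after each scaffold
#'   (default 60).
#' @return a \linkS4class{ConcatenatedReference}.
#' @examples
#' ref <- concatenateReference(Biostrings::DNAStringSet(
#'     c(s1 = "ACGTACGTAC", s2 = "TTTTGGGGCC")))
#' scaffoldOffsets(ref)
#' @export
concatenateReference <- function(genome, spacer = 60L) {
    seqs <- as.character(genome)
    if (length(seqs) == 0L) stop("empty genome: nothing to concatenate")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("all scaffolds must be named")
    if (anyDuplicated(names(seqs)))
        stop("duplicate scaffold names: ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    lens <- nchar(seqs)
    pad <- strrep("N", spacer)
    new("ConcatenatedReference",
        sequence = paste0(paste0(seqs, pad), collapse = ""),
        offsets = setNames(as.integer(cumsum(c(0L, head(lens + spacer, -1L)))),
                           names(seqs)),
        lengths = setNames(as.integer(lens), names(seqs)),
        spacer = as.integer(spacer))
}

#' @rdname ConcatenatedReference-class
#' @export
setMethod("refSequence", "ConcatenatedReference", function(x) x@sequence)

#' @rdname ConcatenatedReference-class
#' @export
setMethod("scaffoldOffsets", "ConcatenatedReference", function(x) x@offsets)

#' @rdname ConcatenatedReference-class
#' @export
setMethod("scaffoldLengths", "ConcatenatedReference", function(x) x@lengths)

setMethod("show", "ConcatenatedReference", function(object) {
    cat("ConcatenatedReference with", length(object@lengths),
        "scaffold(s),", nchar(object@sequence), "bp total (",
        object@spacer, "N spacers )\n")
})

#' Convert scaffold-local coordinates to concatenated-global
#'
#' Positions are 1-based on both sides; the round trip through
#' \code{\link{globalToLocal}} is the identity for every scaffold position.
#'
#' @param ref a \linkS4class{ConcatenatedReference}.
#' @param scaffold character vector of scaffold names.
#' @param pos integer vector of 1-based scaffold positions.
#' @return integer vector of 1-based global positions.
#' @export
localToGlobal <- function(ref, scaffold, pos) {
    off <- scaffoldOffsets(ref)[scaffold]
    len <- scaffoldLengths(ref)[scaffold]
    if (anyNA(off)) stop("unknown scaffold: ",
                         paste(unique(scaffold[is.na(off)]), collapse = ", "))
    if (any(pos < 1L | pos > len))
        stop("position outside scaffold bounds")
    as.integer(off + pos)
}

#' Convert concatenated-global coordinates to scaffold-local
#'
#' @param ref a \linkS4class{ConcatenatedReference}.
#' @param gpos integer vector of 1-based global positions.
#' @return data.frame with columns \code{scaffold} and \code{pos}; positions
#'   falling inside a spacer come back as \code{NA}.
#' @export
globalToLocal <- function(ref, gpos) {
    off <- scaffoldOffsets(ref)
    len <- scaffoldLengths(ref)
    idx <- findInterval(gpos - 1L, off)
    bad <- idx < 1L | gpos > nchar(refSequence(ref))
    idx[bad] <- NA_integer_
    local <- gpos - off[idx]
    spacer <- !is.na(local) & local > len[idx]
    data.frame(
        scaffold = ifelse(is.na(idx) | spacer, NA_character_,
                          names(off)[idx]),
        pos = ifelse(is.na(idx) | spacer, NA_integer_, as.integer(local)),
        stringsAsFactors = FALSE)
}
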