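#' @include AllGenerics.R
NULL

#' SOLiD di-base color-space encoding
#'
#' Encodes DNA into SOLiD color space: color \code{i} represents the di-base
#' transition from the previous base (initially the synthetic primer base) to
#' base \code{i} through the canonical 4x4 matrix — identical pair -> 0,
#' A/C or G/T -> 1, A/G or C/T -> 2, A/T or C/G -> 3. Colors are
#' complement-invariant, so the color string of a reverse complement is the
#' reverse of the original color string (with the leading primer transition
#' re-derived); minus-strand mapping exploits exactly this property.
#'
#' @param sequences character vector or \code{DNAStringSet} of A/C/G/T
#'   sequences.
#' @param primer single primer base (default \code{"T"}, the standard SOLiD
#'   P1 adaptor terminal base), or one base per sequence.
#' @return character vector of color strings over \code{0123}, one color per
#'   input base (the first color encodes primer -> base 1).
#' @examples
#' encodeColorspace("ACG", primer = "T")   # "313"
#' decodeColorspace("313", primer = "T")   # "ACG"
#' @export
encodeColorspace <- function(sequences, primer = "T") {
    .cs_encode(as.character(sequences), primer)
}

#' Decode SOLiD color space back to DNA
#'
#' Inverse of \code{\link{encodeColorspace}}:
#' \code{decodeColorspace(encodeColorspace(x, b), b) == x}.
#'
#' @param colors character vector of color strings over \code{0123}.
#' @param primer single primer base, or one base per read.
#' @return character vector of DNA sequences.
#' @export
decodeColorspace <- function(colors, primer = "T") {
    .cs_decode(primer, as.character(colors))
}

#' Remove low-information color reads
#'
#' Reads with \code{threshold} (default 3) or fewer non-0 colors carry
#' little sequence information and cause spurious mappings (a long run of
#' color 0 is any homopolymer); they are removed before mapping. The filter
#' is idempotent and order-independent.
#'
#' @param reads data.frame of color reads with columns \code{id},
#'   \code{primer}, \code{colors} (see \code{\link{readCsfasta}}).
#' @param threshold maximum number of non-0 colors for a read to be removed
#'   (default 3).
#' @return list with elements \code{kept}, \code{removed} (both data.frames)
#'   and \code{report} (input count, removed count, removed fraction).
#' @export
filterLowInformation <- function(reads, threshold = 3L) {
    stopifnot(is.data.frame(reads), "colors" %in% names(reads))
    nonzero <- nchar(gsub("0", "", reads$colors, fixed = TRUE))
    drop <- nonzero <= threshold
    list(kept = reads[!drop, , drop = FALSE],
         removed = reads[drop, , drop = FALSE],
         report = list(n_input = nrow(reads), n_removed = sum(drop),
                       fraction_removed = if (nrow(reads)) mean(drop) else 0))
}

#' Read a csfasta file of color-space reads
#'
#' csfasta stores one read per record: a header line \code{">id"} followed by
#' the sequenced line, a primer base and one color character per sequenced
#' base (e.g. \code{"T03120..."}). Lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return data.frame with columns \code{id}, \code{primer}, \code{colors}.
#' @export
readCsfasta <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    hdr <- startsWith(ln, ">")
    if (!any(hdr)) return(data.frame(id = character(), primer = character(),
                                     colors = character()))
    if (!all(hdr == rep(c(TRUE, FALSE), length.out = length(ln))))
        stop("malformed csfasta: expected alternating header/read lines")
    ids <- sub("^>", "", ln[hdr])
    seqs <- ln[!hdr]
    data.frame(id = ids, primer = substr(seqs, 1L, 1L),
               colors = substr(seqs, 2L, nchar(seqs)),
               stringsAsFactors = FALSE)
}

#' Write color-space reads as csfasta
#'
#' @param reads data.frame with columns \code{id}, \code{primer},
#'   \code{colors}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeCsfasta <- function(reads, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# csfasta: primer base + di-base colors (0-3)", con)
    writeLines(paste0(">", reads$id, "\n", reads$primer, reads$colors), con)
    invisible(path)
}
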