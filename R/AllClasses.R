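#' @include fiveDGE-package.R
NULL

#' Concatenated reference genome
#'
#' A single reference sequence built by joining scaffolds with a spacer of
#' 60 \code{N}s after each segment, together with the offset map needed to
#' translate between scaffold-local and concatenated ("global") coordinates.
#' The spacers make tags that would span two scaffolds unmappable by
#' construction, because \code{N} encodes no valid di-base color.
#'
#' @slot sequence single character string, the concatenated sequence.
#' @slot offsets named integer, 0-based offset of each scaffold's first base
#'   within the concatenation.
#' @slot lengths named integer, scaffold lengths.
#' @slot spacer integer, number of \code{N}s appended after each scaffold.
#' @aliases ConcatenatedReference
#' @exportClass ConcatenatedReference
setClass("ConcatenatedReference",
    slots = c(sequence = "character", offsets = "integer",
              lengths = "integer", spacer = "integer"))

setValidity("ConcatenatedReference", function(object) {
    msg <- NULL
    if (length(object@sequence) != 1L)
        msg <- c(msg, "sequence must be a single string")
    if (!identical(names(object@offsets), names(object@lengths)))
        msg <- c(msg, "offsets and lengths must share scaffold names")
    if (anyDuplicated(names(object@lengths)))
        msg <- c(msg, "duplicate scaffold names")
    expect <- cumsum(c(0L, head(object@lengths + object@spacer, -1L)))
    if (length(object@offsets) && !all(object@offsets == expect))
        msg <- c(msg, "offset map inconsistent with lengths and spacer")
    total <- sum(object@lengths + object@spacer)
    if (length(object@lengths) && nchar(object@sequence) != total)
        msg <- c(msg, "sequence length does not match offsets/lengths")
    if (is.null(msg)) TRUE else msg
})

#' Strand-resolved tag weight array
#'
#' A zero-initialised pair of floating-point arrays (one per DNA strand) over
#' the concatenated reference, into which mapped tags are accumulated with
#' fractional 1/n multi-hit assignment. The total accumulated weight equals
#' the number of reads that contributed (each read carries total weight 1).
#'
#' @slot plus,minus numeric vectors, one cell per concatenated-reference
#'   position.
#' @slot reference the \linkS4class{ConcatenatedReference} the array indexes.
#' @slot totalMapped numeric, total accumulated weight.
#' @slot stats list of accumulation counters (reads, unique, multi,
#'   discarded).
#' @aliases TagArray
#' @exportClass TagArray
setClass("TagArray",
    slots = c(plus = "numeric", minus = "numeric",
              reference = "ConcatenatedReference",
              totalMapped = "numeric", stats = "list"))

setValidity("TagArray", function(object) {
    msg <- NULL
    n <- nchar(object@reference@sequence)
    if (length(object@plus) != n || length(object@minus) != n)
        msg <- c(msg, "strand arrays must span the concatenated reference")
    if (any(object@plus < 0) || any(object@minus < 0))
        msg <- c(msg, "tag weights must be non-negative")
    tot <- sum(object@plus) + sum(object@minus)
    if (abs(tot - object@totalMapped) > 1e-6)
        msg <- c(msg, "totalMapped does not equal the summed cell weights")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a simulated expression time course
#'
#' Per-gene true TPM for each time point, the temporal pattern label used to
#' generate it, and the positional parameters of the tag simulator (weight of
#' the transcription-start-site peak and the decay scale of the exon-body
#' background).
#'
#' @slot tpm numeric matrix, genes x time points; every column sums to 1e6.
#' @slot pattern character, per-gene pattern label ("null" for flat genes).
#' @slot tssWeight numeric, per-gene fraction of tags placed exactly at the
#'   annotated 5' end.
#' @slot decayScale numeric scalar, exponential decay scale (bp) of the
#'   exon-body tag background.
#' @slot params list of generator parameters.
#' @aliases SimTruth
#' @exportClass SimTruth
setClass("SimTruth",
    slots = c(tpm = "matrix", pattern = "character", tssWeight = "numeric",
              decayScale = "numeric", params = "list"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    if (any(object@tpm < 0)) msg <- c(msg, "true TPM values must be >= 0")
    if (ncol(object@tpm) > 0) {
        cs <- colSums(object@tpm)
        if (any(abs(cs - 1e6) > 1e-3))
            msg <- c(msg, "per-sample true TPM must sum to 1e6")
    }
    if (length(object@pattern) != nrow(object@tpm))
        msg <- c(msg, "pattern labels must match genes")
    if (length(object@tssWeight) != nrow(object@tpm))
        msg <- c(msg, "tssWeight must match genes")
    if (is.null(msg)) TRUE else msg
})

#' Trained self-organizing map
#'
#' A rectangular SOM over time-course expression profiles: the codebook
#' vector of every grid node and the best-matching-unit assignment of every
#' input gene.
#'
#' @slot codebook numeric matrix, (rows*cols) x time points; node k sits at
#'   grid row \code{(k-1) \%/\% cols + 1}, column \code{(k-1) \%\% cols + 1}.
#' @slot assignment named integer, node index per input gene.
#' @slot shape integer of length 2, grid (rows, cols).
#' @slot params list of training parameters (iterations, learning rate,
#'   radius schedule, seed, init).
#' @aliases SOMGrid
#' @exportClass SOMGrid
setClass("SOMGrid",
    slots = c(codebook = "matrix", assignment = "integer",
              shape = "integer", params = "list"))

setValidity("SOMGrid", function(object) {
    msg <- NULL
    if (length(object@shape) != 2L || any(object@shape < 1L))
        msg <- c(msg, "shape must be two positive integers")
    if (nrow(object@codebook) != prod(object@shape))
        msg <- c(msg, "codebook must have one row per grid node")
    if (length(object@assignment) &&
        (min(object@assignment) < 1L ||
         max(object@assignment) > prod(object@shape)))
        msg <- c(msg, "assignments must index grid nodes")
    if (is.null(msg)) TRUE else msg
})
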