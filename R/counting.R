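#' @include mapper.R
NULL

#' Accumulate mapped tags into a strand-resolved array
#'
#' Implements fractional multi-hit assignment: for each read, the hits with
#' the fewest mismatches are selected; a unique best hit adds 1.0 to its
#' cell, and a read with \code{n} equally-best hits adds \code{1/n} to each
#' of them (the two strands count as different positions, so cross-strand
#' ties share the split). In \code{"unique"} mode multi-hit reads are
#' discarded entirely, for comparing fractional against unique-only
#' counting. Total accumulated weight therefore equals the number of reads
#' retained, conserving tag mass.
#'
#' The cell a tag is recorded in is, by default (\code{positionMode =
#' "tss"}), the genomic position of the transcript's 5'-most base of the
#' tag: tag reads run antisense to the transcript, so this is the right end
#' of a tag mapped to the plus strand and the left end of a tag mapped to
#' the minus strand. \code{positionMode = "start"} records the leftmost
#' mapped base instead. One cell per read, not one per covered base.
#'
#' @param hits data.frame from \code{\link{mapColorReads}}; every read
#'   present must have at least one hit (unmapped reads are simply absent).
#' @param reference the \linkS4class{ConcatenatedReference} the hits refer
#'   to.
#' @param mode \code{"fractional"} (default) or \code{"unique"}.
#' @param positionMode \code{"tss"} (default) or \code{"start"}.
#' @param tagLength tag length in bases (default 25).
#' @return a \linkS4class{TagArray}.
#' @export
accumulateTags <- function(hits, reference, mode = c("fractional", "unique"),
                           positionMode = c("tss", "start"),
                           tagLength = 25L) {
    mode <- match.arg(mode)
    positionMode <- match.arg(positionMode)
    ref <- .asReference(reference)
    need <- c("read", "gpos", "strand", "mm")
    if (!all(need %in% names(hits)))
        stop("hits must have columns ", paste(need, collapse = ", "))
    if (anyNA(hits$gpos) || anyNA(hits$mm))
        stop("hit stream contains missing values; the caller must pass ",
             "mapped hits only")
    o <- order(hits$read)
    res <- .cs_accumulate(as.integer(hits$read[o]),
                          as.integer(hits$gpos[o]),
                          ifelse(hits$strand[o] == "+", 1L, -1L),
                          as.integer(hits$mm[o]),
                          nchar(refSequence(ref)), as.integer(tagLength),
                          mode == "unique", positionMode == "tss")
    new("TagArray", plus = res$plus, minus = res$minus, reference = ref,
        totalMapped = res$total,
        stats = list(n_reads = res$n_reads, n_unique = res$n_unique,
                     n_multi = res$n_multi, n_discarded = res$n_discarded,
                     mode = mode, position_mode = positionMode))
}

#' @rdname TagArray-class
#' @export
setMethod("strandTrack", "TagArray", function(x, strand) {
    switch(strand, "+" = x@plus, "-" = x@minus,
           stop("strand must be '+' or '-'"))
})

#' @rdname TagArray-class
#' @export
setMethod("totalMapped", "TagArray", function(x) x@totalMapped)

setMethod("show", "TagArray", function(object) {
    cat("TagArray over", length(object@reference@lengths), "scaffold(s);",
        format(object@totalMapped, digits = 10), "tags accumulated (",
        object@stats$n_unique, "unique,", object@stats$n_multi, "multi )\n")
})

.regionStrands <- function(geneStrand, convention) {
    switch(convention,
        antisense = ifelse(geneStrand == "+", "-", "+"),
        sense = geneStrand,
        both = rep(NA_character_, length(geneStrand)),
        stop("unknown strand convention: ", convention))
}

#' Count tag weight over regions
#'
#' Sums the accumulated tag weights over each region. Under the default
#' \code{"antisense"} convention a gene on strand \emph{s} is counted from
#' tags mapped to strand \emph{-s}, because 5'-tag reads are sequenced
#' antisense to their transcript; \code{"sense"} counts the gene's own
#' strand and \code{"both"} sums both strands.
#'
#' @param tagArray a \linkS4class{TagArray}.
#' @param regions a \code{GRanges} (e.g. from
#'   \code{\link{extendGeneModels}}) with a \code{gene_id} metadata column.
#' @param convention \code{"antisense"} (default), \code{"sense"} or
#'   \code{"both"}.
#' @return named numeric vector of fractional counts.
#' @export
countRegions <- function(tagArray, regions,
                         convention = c("antisense", "sense", "both")) {
    convention <- match.arg(convention)
    ref <- tagArray@reference
    sc <- as.character(seqnames(regions))
    len <- scaffoldLengths(ref)[sc]
    if (anyNA(len)) stop("region scaffold missing from the reference")
    s <- start(regions); e <- end(regions)
    if (any(s < 1L) || any(e > len)) stop("region outside scaffold bounds")
    gs <- scaffoldOffsets(ref)[sc] + s
    ge <- scaffoldOffsets(ref)[sc] + e
    arrStrand <- .regionStrands(as.character(strand(regions)), convention)
    out <- numeric(length(regions))
    for (i in seq_along(regions)) {
        idx <- gs[i]:ge[i]
        out[i] <- if (is.na(arrStrand[i]))
            sum(tagArray@plus[idx]) + sum(tagArray@minus[idx])
        else sum(strandTrack(tagArray, arrStrand[i])[idx])
    }
    ids <- mcols(regions)$gene_id
    if (!is.null(ids)) names(out) <- ids
    out
}

#' Convert raw tag counts to tags per million (TPM)
#'
#' TPM is the tag count divided by the total number of tags mapped to the
#' genome, times 1e6. No transcript-length normalization is applied: a
#' 5'-tag library yields one tag per transcript molecule, so counts are
#' already proportional to molar transcript abundance.
#'
#' @param counts numeric vector (or matrix) of raw fractional counts.
#' @param totalMapped total mapped tag count (scalar, or one per matrix
#'   column).
#' @return TPM values with the shape of \code{counts}.
#' @export
computeTpm <- function(counts, totalMapped) {
    if (any(totalMapped <= 0)) stop("totalMapped must be > 0")
    if (is.matrix(counts))
        sweep(counts, 2L, totalMapped, "/") * 1e6
    else counts / totalMapped * 1e6
}

#' Binned tag-count track over a range
#'
#' Divides a range into equal bins and sums the tag weight per bin (the
#' histogram drawn over a locus). Bin totals conserve the region total.
#'
#' @param tagArray a \linkS4class{TagArray}.
#' @param region a single-range \code{GRanges} (its strand selects the array
#'   strand via \code{convention}).
#' @param nBins number of bins (capped at one position per bin).
#' @param convention see \code{\link{countRegions}}.
#' @return data.frame with columns \code{bin}, \code{start}, \code{end}
#'   (1-based closed, scaffold-local) and \code{count}.
#' @export
binnedTrack <- function(tagArray, region, nBins,
                        convention = c("antisense", "sense", "both")) {
    convention <- match.arg(convention)
    stopifnot(length(region) == 1L, nBins >= 1L)
    w <- width(region)
    nBins <- min(as.integer(nBins), w)
    edges <- floor(seq(0L, w, length.out = nBins + 1L))
    ref <- tagArray@reference
    g0 <- localToGlobal(ref, as.character(seqnames(region)), start(region))
    arrStrand <- .regionStrands(as.character(strand(region)), convention)
    track <- if (is.na(arrStrand)) tagArray@plus + tagArray@minus
             else strandTrack(tagArray, arrStrand)
    counts <- vapply(seq_len(nBins), function(b) {
        sum(track[(g0 + edges[b]):(g0 + edges[b + 1L] - 1L)])
    }, numeric(1))
    data.frame(bin = seq_len(nBins),
               start = start(region) + edges[-length(edges)],
               end = start(region) + edges[-1L] - 1L,
               count = counts)
}

#' Write a strand's tag track as bedGraph
#'
#' Runs of equal non-zero weight are merged; coordinates are emitted 0-based
#' half-open as the format requires, stated in the header comment.
#'
#' @param tagArray a \linkS4class{TagArray}.
#' @param path output path.
#' @param strand \code{"+"} or \code{"-"}.
#' @return invisibly, the path.
#' @export
writeBedGraph <- function(tagArray, path, strand = "+") {
    ref <- tagArray@reference
    track <- strandTrack(tagArray, strand)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# fiveDGE tag track; coordinates 0-based half-open",
                 sprintf("track type=bedGraph name=\"tags_%s\"", strand)),
               con)
    off <- scaffoldOffsets(ref)
    for (sc in names(off)) {
        v <- track[(off[[sc]] + 1L):(off[[sc]] + scaffoldLengths(ref)[[sc]])]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        keep <- r$values != 0
        if (!any(keep)) next
        starts <- ends - r$lengths + 1L
        write.table(data.frame(sc, starts[keep] - 1L, ends[keep],
                               r$values[keep]),
                    con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(path)
}

#' Assemble a gene-by-sample count table
#'
#' Counts every sample's \linkS4class{TagArray} over the extended gene
#' regions and returns a \code{SummarizedExperiment} with assays
#' \code{counts} (raw fractional) and \code{tpm}, the regions as row ranges
#' and per-sample totals in \code{colData}.
#'
#' @param tagArrays named list of \linkS4class{TagArray}, one per sample.
#' @param regions extended gene regions (\code{GRanges} with
#'   \code{gene_id}).
#' @param colData optional \code{DataFrame} of sample metadata (time point,
#'   replicate); rows must match \code{tagArrays}.
#' @param convention see \code{\link{countRegions}}.
#' @return a \code{SummarizedExperiment}.
#' @export
buildCountTable <- function(tagArrays, regions, colData = NULL,
                            convention = "antisense") {
    stopifnot(is.list(tagArrays), length(tagArrays) > 0)
    counts <- vapply(tagArrays, countRegions, numeric(length(regions)),
                     regions = regions, convention = convention)
    counts <- matrix(counts, nrow = length(regions),
                     dimnames = list(mcols(regions)$gene_id,
                                     names(tagArrays)))
    totals <- vapply(tagArrays, totalMapped, numeric(1))
    cd <- if (is.null(colData)) DataFrame(row.names = names(tagArrays))
          else DataFrame(colData)
    cd$total_mapped <- totals
    SummarizedExperiment(
        assays = list(counts = counts, tpm = computeTpm(counts, totals)),
        rowRanges = regions, colData = cd)
}

#' Write a count table as TSV
#'
#' @param se \code{SummarizedExperiment} from \code{\link{buildCountTable}}.
#' @param path output path.
#' @param assay which assay to write (\code{"tpm"} or \code{"counts"}).
#' @return invisibly, the path.
#' @export
writeCountTable <- function(se, path, assay = "tpm") {
    m <- assays(se)[[assay]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fiveDGE %s table (genes x samples)", assay), con)
    write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
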