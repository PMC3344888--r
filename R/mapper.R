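#' @include reference.R
NULL

.asReference <- function(reference) {
    if (is(reference, "ConcatenatedReference")) reference
    else concatenateReference(reference)
}

#' Map color-space reads to a concatenated reference
#'
#' Aligns SOLiD color reads to both strands of the reference, reporting every
#' location with at most \code{maxMismatches} color mismatches over the
#' informative colors of the tag. The search is a lossless seed-and-verify
#' scan: the informative colors are cut into blocks of \code{seedK}; with at
#' most two mismatches at least one block matches exactly (pigeonhole), so an
#' exact k-mer index over the reference color string enumerates all
#' candidates, which are then verified color by color. Results are identical
#' to a brute-force full scan.
#'
#' The first color of a read encodes the transition from the synthetic
#' primer base and is excluded from mismatch counting by default
#' (\code{skipFirstColor}). A minus-strand hit means the read's reversed
#' color string matches the forward reference colors (reverse complementing
#' a sequence reverses its colors). Windows touching an \code{N} (including
#' the 60-N scaffold spacers) can never match.
#'
#' @param reads data.frame of color reads (columns \code{id}, \code{primer},
#'   \code{colors}).
#' @param reference a \linkS4class{ConcatenatedReference} or a named
#'   \code{DNAStringSet} (concatenated automatically).
#' @param maxMismatches maximum color mismatches (default 2).
#' @param skipFirstColor exclude the primer-transition color from mismatch
#'   counting (default TRUE).
#' @param seedK seed length in colors for the index (default 8).
#' @return data.frame of hits with columns \code{read} (row index into
#'   \code{reads}), \code{read_id}, \code{scaffold}, \code{pos} (1-based
#'   leftmost base of the tag on its scaffold), \code{gpos} (global
#'   coordinate), \code{strand} (\code{"+"}/\code{"-"}), \code{mm}. Reads
#'   without any hit simply do not appear.
#' @export
mapColorReads <- function(reads, reference, maxMismatches = 2L,
                          skipFirstColor = TRUE, seedK = 8L) {
    ref <- .asReference(reference)
    refc <- .cs_ref_colors(refSequence(ref))
    hits <- .cs_map_reads(reads$colors, refc, as.integer(maxMismatches),
                          isTRUE(skipFirstColor), as.integer(seedK))
    loc <- globalToLocal(ref, hits$pos)
    keep <- !is.na(loc$pos)   # spacer hits are impossible; belt and braces
    data.frame(read = hits$read[keep],
               read_id = reads$id[hits$read[keep]],
               scaffold = loc$scaffold[keep],
               pos = loc$pos[keep],
               gpos = hits$pos[keep],
               strand = ifelse(hits$strand[keep] > 0, "+", "-"),
               mm = hits$mm[keep],
               stringsAsFactors = FALSE)
}

#' Map a single color read
#'
#' Convenience wrapper around \code{\link{mapColorReads}} for one read.
#'
#' @param colors color string of the read (primer transition first).
#' @param primer primer base (default \code{"T"}).
#' @param reference,maxMismatches,skipFirstColor,seedK see
#'   \code{\link{mapColorReads}}.
#' @return data.frame of hits (possibly empty).
#' @export
mapRead <- function(colors, reference, primer = "T", maxMismatches = 2L,
                    skipFirstColor = TRUE, seedK = 8L) {
    mapColorReads(data.frame(id = "read1", primer = primer, colors = colors,
                             stringsAsFactors = FALSE),
                  reference, maxMismatches, skipFirstColor, seedK)
}

#' Write mapped hits as TSV
#'
#' Positions are written 0-based (half-open tag interval
#' \code{[position, position + tag length)}), stated in the header comment.
#'
#' @param hits data.frame from \code{\link{mapColorReads}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHitsTsv <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# fiveDGE mapped hits; coordinates 0-based half-open",
                 "read_id\tscaffold\tposition\tstrand\tmismatches"), con)
    if (nrow(hits))
        write.table(data.frame(hits$read_id, hits$scaffold, hits$pos - 1L,
                               hits$strand, hits$mm),
                    con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(path)
}
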