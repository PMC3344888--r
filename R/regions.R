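#' @include reference.R
NULL

#' Read gene models from GFF3
#'
#' Light pre-validation reports malformed lines with their line numbers,
#' then the file is imported with \pkg{rtracklayer}. \code{gene} features
#' become the gene models; \code{exon} features are attached to their parent
#' gene (genes without exon children are treated as single-exon). Genes are
#' stably sorted by (scaffold, start, gene_id); duplicate gene identifiers
#' are an error.
#'
#' @param path GFF3 file (1-based inclusive coordinates, as the format
#'   defines).
#' @return \code{GRanges} of genes with metadata columns \code{gene_id} and
#'   \code{exons} (an \code{IRangesList} of genomic exon intervals).
#' @export
readGeneModels <- function(path) {
    ln <- readLines(path)
    body <- !startsWith(ln, "#") & nzchar(ln)
    if (!any(body)) return(GRanges(gene_id = character(),
                                   exons = IRangesList()))
    fields <- strsplit(ln[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L))
        stop("malformed GFF3 line(s) (expected 9 tab-separated fields): ",
             paste(which(body)[nf != 9L], collapse = ", "))
    st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    bad <- is.na(st) | is.na(en) | en < st
    if (any(bad))
        stop("invalid coordinates (end < start or non-numeric) at line(s): ",
             paste(which(body)[bad], collapse = ", "))
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    if (length(genes) == 0L)
        return(GRanges(gene_id = character(), exons = IRangesList()))
    ids <- if (!is.null(genes$ID)) as.character(genes$ID)
           else as.character(genes$Name)
    if (anyNA(ids) || any(!nzchar(ids)))
        stop("gene feature without an ID attribute")
    if (anyDuplicated(ids))
        stop("duplicate gene_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    exons <- gr[gr$type == "exon"]
    exParent <- if (length(exons)) unlist(exons$Parent) else character()
    exl <- lapply(ids, function(id) {
        ex <- exons[exParent == id]
        if (length(ex) == 0L) return(NULL)
        sort(IRanges(start(ex), end(ex)))
    })
    g <- granges(genes)
    mcols(g)$gene_id <- ids
    mcols(g)$exons <- IRangesList(lapply(seq_along(exl), function(i) {
        if (is.null(exl[[i]])) IRanges(start(g)[i], end(g)[i]) else exl[[i]]
    }))
    o <- order(as.character(seqnames(g)), start(g), mcols(g)$gene_id)
    g <- g[o]
    .validateGeneModels(g)
    g
}

.validateGeneModels <- function(g) {
    ex <- mcols(g)$exons
    if (is.null(ex)) return(invisible(g))
    for (i in seq_along(g)) {
        e <- ex[[i]]
        if (any(start(e) < start(g)[i]) || any(end(e) > end(g)[i]))
            stop("exons of ", mcols(g)$gene_id[i],
                 " extend beyond the gene interval")
        if (length(e) > 1L && any(start(e)[-1L] <= end(e)[-length(e)]))
            stop("overlapping exons in ", mcols(g)$gene_id[i])
    }
    invisible(g)
}

#' Extend gene models into counting regions
#'
#' 5'-tag peaks often fall outside the annotated gene model because UTR
#' annotation is sparse, so each gene is widened into an extended counting
#' region: 2 kb beyond its 5' end and 1 kb beyond its 3' end when the
#' distance to the neighboring gene model on the same strand exceeds
#' \code{gapThreshold} (3 kb). For a shorter same-strand gap \code{d}, the
#' intervening region is divided 1:2 so the expansions abut without
#' overlap — \code{floor(d/3)} to the 3' side of the transcriptionally
#' upstream gene and the remainder to the 5' side of the downstream gene.
#' This orientation of the split is forced by continuity: at \code{d} = 3 kb
#' it coincides with the full 1 kb (3') and 2 kb (5') caps. 5' and 3' are in
#' transcription orientation, so on the minus strand the 5' extension grows
#' the genomic end. Opposite-strand neighbors are ignored (counting is
#' strand-resolved, so opposite-strand region overlap cannot double-count).
#' Extensions are clipped at scaffold boundaries.
#'
#' @param genes \code{GRanges} of gene models with \code{gene_id} (from
#'   \code{\link{readGeneModels}} or \code{\link{makeToyGenome}});
#'   same-strand genes must not overlap.
#' @param fiveExt maximum 5' extension in bp (default 2000).
#' @param threeExt maximum 3' extension in bp (default 1000).
#' @param gapThreshold same-strand gap above which both genes take their
#'   full extension (default 3000; a gap of exactly 3000 takes the split
#'   branch, which gives the identical 1000/2000 outcome).
#' @param scaffoldLengths named integer of scaffold lengths; defaults to
#'   \code{seqlengths(genes)} if set.
#' @return \code{GRanges} of extended regions with metadata columns
#'   \code{gene_id}, \code{five_ext}, \code{three_ext} (achieved
#'   extensions), \code{five_clipped}, \code{three_clipped}.
#' @export
extendGeneModels <- function(genes, fiveExt = 2000L, threeExt = 1000L,
                             gapThreshold = 3000L, scaffoldLengths = NULL) {
    if (is.null(scaffoldLengths)) {
        scaffoldLengths <- seqlengths(genes)
        if (anyNA(scaffoldLengths))
            stop("scaffoldLengths must be supplied (or set on the GRanges)")
    }
    sc <- as.character(seqnames(genes))
    str <- as.character(strand(genes))
    if (any(!str %in% c("+", "-")))
        stop("gene models must be stranded")
    s <- start(genes); e <- end(genes)
    n <- length(genes)
    leftExt <- integer(n); rightExt <- integer(n)

    for (key in unique(paste(sc, str))) {
        idx <- which(paste(sc, str) == key)
        idx <- idx[order(s[idx])]
        if (length(idx) > 1L) {
            prev <- idx[-length(idx)]; nxt <- idx[-1L]
            if (any(s[nxt] <= e[prev])) {
                i <- which(s[nxt] <= e[prev])[1L]
                stop("overlapping same-strand gene models: ",
                     mcols(genes)$gene_id[prev[i]], " and ",
                     mcols(genes)$gene_id[nxt[i]])
            }
        }
        onPlus <- str[idx[1L]] == "+"
        for (k in seq_along(idx)) {
            g <- idx[k]
            # left side of gene g: 5' if + strand, 3' if - strand
            capL <- if (onPlus) fiveExt else threeExt
            capR <- if (onPlus) threeExt else fiveExt
            if (k == 1L) leftExt[g] <- capL
            else {
                d <- s[g] - e[idx[k - 1L]] - 1L
                if (d > gapThreshold) leftExt[g] <- capL
                else leftExt[g] <- if (onPlus) d - d %/% 3L else d %/% 3L
            }
            if (k == length(idx)) rightExt[g] <- capR
            else {
                d <- s[idx[k + 1L]] - e[g] - 1L
                if (d > gapThreshold) rightExt[g] <- capR
                else rightExt[g] <- if (onPlus) d %/% 3L else d - d %/% 3L
            }
        }
    }

    len <- scaffoldLengths[sc]
    newStart <- pmax(1L, s - leftExt)
    newEnd <- pmin(as.integer(len), e + rightExt)
    achievedL <- s - newStart
    achievedR <- newEnd - e
    plus <- str == "+"
    out <- GRanges(sc, IRanges(newStart, newEnd), strand = str)
    mcols(out)$gene_id <- mcols(genes)$gene_id
    mcols(out)$five_ext <- ifelse(plus, achievedL, achievedR)
    mcols(out)$three_ext <- ifelse(plus, achievedR, achievedL)
    mcols(out)$five_clipped <- ifelse(plus, achievedL < leftExt,
                                      achievedR < rightExt)
    mcols(out)$three_clipped <- ifelse(plus, achievedR < rightExt,
                                       achievedL < leftExt)
    out
}

#' Write extended regions as BED6 plus an audit table
#'
#' BED is 0-based half-open (converted from the internal 1-based ranges);
#' the audit TSV lists the achieved extension and clip flags per gene.
#'
#' @param regions \code{GRanges} from \code{\link{extendGeneModels}}.
#' @param bedPath BED6 output path (\code{NULL} to skip).
#' @param auditPath audit TSV path (\code{NULL} to skip).
#' @return invisibly, \code{regions}.
#' @export
writeExtendedRegions <- function(regions, bedPath = NULL, auditPath = NULL) {
    if (!is.null(bedPath)) {
        con <- file(bedPath, "w")
        writeLines("# fiveDGE extended regions; BED6, 0-based half-open",
                   con)
        write.table(data.frame(as.character(seqnames(regions)),
                               start(regions) - 1L, end(regions),
                               mcols(regions)$gene_id, 0L,
                               as.character(strand(regions))),
                    con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        close(con)
    }
    if (!is.null(auditPath)) {
        con <- file(auditPath, "w")
        writeLines("# fiveDGE extension audit; achieved extensions in bp",
                   con)
        write.table(as.data.frame(mcols(regions)), con, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        close(con)
    }
    invisible(regions)
}
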