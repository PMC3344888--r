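#' @include regions.R
NULL

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Split a gene of geneLen bp into k exons separated by k-1 introns; returns
# local 1-based IRanges of the exons. Falls back to a single exon when the
# gene is too short to host the requested structure.
.exonLayout <- function(geneLen, k, minExon = 120L, minIntron = 80L) {
    if (k > 1L) {
        spare <- geneLen - k * minExon - (k - 1L) * minIntron
        if (spare < 0L) k <- 1L
    }
    if (k == 1L) return(IRanges(1L, geneLen))
    nseg <- 2L * k - 1L
    lens <- rep(c(minExon, minIntron), length.out = nseg)
    lens <- lens + as.integer(stats::rmultinom(1L, spare, rep(1, nseg)))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    IRanges(starts[seq(1L, nseg, by = 2L)], ends[seq(1L, nseg, by = 2L)])
}

#' Generate a toy genome with annotated gene models
#'
#' Builds random A/C/G/T scaffolds carrying non-overlapping gene models on
#' both strands with known inter-gene gaps, for exercising the full tag
#' pipeline without external data. Same-strand genes never overlap; every
#' exon is at least 120 bp, so a 25 bp tag always fits in the first exon.
#' Output is byte-reproducible for a given seed.
#'
#' @param nGenes number of genes (>= 2).
#' @param nScaffolds number of scaffolds; genes are distributed evenly.
#' @param meanGeneLen mean gene length in bp (default 1500).
#' @param meanGap mean inter-gene gap in bp (exponential with a 200 bp
#'   floor), so sampled gaps span both sides of the 3 kb extension
#'   threshold; default 2000.
#' @param fixedGap if non-NULL, every gap is exactly this many bp (used to
#'   construct extension-rule fixtures).
#' @param exonsPerGene integer vector sampled from for the exon count per
#'   gene (default \code{1:2}).
#' @param scaffoldLength optional fixed scaffold length; an error is raised
#'   if the requested genes do not fit. By default scaffolds are grown to
#'   their content, padded to at least 10 kb.
#' @param seed random seed.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{genes}
#'   (\code{GRanges} with \code{gene_id} and \code{exons}, seqlengths set).
#' @export
makeToyGenome <- function(nGenes, nScaffolds = 1L, meanGeneLen = 1500L,
                          meanGap = 2000L, fixedGap = NULL,
                          exonsPerGene = 1:2, scaffoldLength = NULL,
                          seed = 1L) {
    stopifnot(nGenes >= 2L, nScaffolds >= 1L)
    withr::with_seed(seed, {
        perScaffold <- diff(floor(seq(0L, nGenes,
                                      length.out = nScaffolds + 1L)))
        seqs <- character(nScaffolds)
        names(seqs) <- sprintf("scaffold_%d", seq_len(nScaffolds))
        allGenes <- list()
        gi <- 0L
        for (si in seq_len(nScaffolds)) {
            pos <- 0L
            rows <- list()
            for (g in seq_len(perScaffold[si])) {
                gap <- if (!is.null(fixedGap)) as.integer(fixedGap)
                       else max(200L, as.integer(round(rexp(1L,
                                                            1 / meanGap))))
                geneLen <- max(300L, as.integer(round(
                    rnorm(1L, meanGeneLen, meanGeneLen / 4))))
                gi <- gi + 1L
                exLocal <- .exonLayout(geneLen,
                                       sample(exonsPerGene, 1L))
                gstart <- pos + gap + 1L
                rows[[g]] <- list(
                    id = sprintf("g%04d", gi),
                    start = gstart, end = gstart + geneLen - 1L,
                    strand = sample(c("+", "-"), 1L),
                    exons = IRanges(start(exLocal) + gstart - 1L,
                                    end(exLocal) + gstart - 1L))
                pos <- gstart + geneLen - 1L
            }
            tailGap <- if (!is.null(fixedGap)) as.integer(fixedGap)
                       else max(200L, as.integer(round(rexp(1L,
                                                            1 / meanGap))))
            contentLen <- pos + tailGap
            scafLen <- if (is.null(scaffoldLength))
                max(contentLen, 10000L) else as.integer(scaffoldLength)
            if (contentLen > scafLen)
                stop("requested genes do not fit on scaffold ", si,
                     " (need ", contentLen, " bp, have ", scafLen, ")")
            seqs[si] <- .randomDna(scafLen)
            if (length(rows)) {
                allGenes[[si]] <- data.frame(
                    scaffold = names(seqs)[si],
                    id = vapply(rows, `[[`, "", "id"),
                    start = vapply(rows, `[[`, 0L, "start"),
                    end = vapply(rows, `[[`, 0L, "end"),
                    strand = vapply(rows, `[[`, "", "strand"),
                    stringsAsFactors = FALSE)
                attr(allGenes[[si]], "exons") <- lapply(rows, `[[`, "exons")
            }
        }
        tab <- do.call(rbind, allGenes)
        exl <- do.call(c, lapply(allGenes, attr, "exons"))
        genome <- DNAStringSet(seqs)
        genes <- GRanges(tab$scaffold, IRanges(tab$start, tab$end),
                         strand = tab$strand,
                         seqlengths = setNames(nchar(seqs), names(seqs)))
        mcols(genes)$gene_id <- tab$id
        mcols(genes)$exons <- IRangesList(exl)
        list(genome = genome, genes = genes)
    })
}

#' Copy a genomic segment elsewhere (planted duplication)
#'
#' Overwrites \code{width} bases at the destination with the source segment,
#' creating an exact repeat so that tags from either copy become genuine
#' multi-mapping reads.
#'
#' @param genome \code{DNAStringSet}.
#' @param scaffold,start,width source segment (1-based).
#' @param destScaffold,destStart destination (1-based).
#' @return modified \code{DNAStringSet}.
#' @export
plantDuplication <- function(genome, scaffold, start, width,
                             destScaffold, destStart) {
    seqs <- as.character(genome)
    seg <- substr(seqs[[scaffold]], start, start + width - 1L)
    s <- seqs[[destScaffold]]
    if (destStart + width - 1L > nchar(s))
        stop("destination segment outside scaffold")
    substr(s, destStart, destStart + width - 1L) <- seg
    seqs[[destScaffold]] <- s
    DNAStringSet(seqs)
}

#' Write a toy genome as FASTA and its gene models as GFF3
#'
#' GFF3 is written 1-based inclusive as the format defines, with one
#' \code{gene} feature per gene and \code{exon} children.
#'
#' @param genome \code{DNAStringSet}.
#' @param genes \code{GRanges} from \code{\link{makeToyGenome}}.
#' @param fastaPath,gffPath output paths (\code{NULL} to skip either).
#' @return invisibly, a list of the written paths.
#' @export
writeToyGenome <- function(genome, genes, fastaPath = NULL, gffPath = NULL) {
    if (!is.null(fastaPath)) writeXStringSet(genome, fastaPath)
    if (!is.null(gffPath)) {
        ids <- mcols(genes)$gene_id
        exl <- mcols(genes)$exons
        exCount <- lengths(exl)
        ex <- unlist(exl)
        exScaffold <- rep(as.character(seqnames(genes)), exCount)
        exStrand <- rep(as.character(strand(genes)), exCount)
        exParent <- rep(ids, exCount)
        lines <- c("##gff-version 3",
                   sprintf("%s\tfiveDGE\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                           as.character(seqnames(genes)), start(genes),
                           end(genes), as.character(strand(genes)), ids),
                   sprintf(paste0("%s\tfiveDGE\texon\t%d\t%d\t.\t%s\t.\t",
                                  "ID=%s.e%d;Parent=%s"),
                           exScaffold, start(ex), end(ex), exStrand,
                           exParent,
                           unlist(lapply(exCount, seq_len)), exParent))
        writeLines(lines, gffPath)
    }
    invisible(list(fasta = fastaPath, gff = gffPath))
}
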