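#' @include expression-sim.R
NULL

#' Library-preparation parameters for the tag simulator
#'
#' Bundles the observable consequences of 5'-tag library chemistry that the
#' counting pipeline sees. The enzymology itself (template switching,
#' adaptors, PCR) is abstracted away.
#'
#' @param depth total tags per sample.
#' @param tagLength tag length in bases (default 25, the EcoP15I product).
#' @param colorErrorRate per-color error probability in [0, 0.25).
#' @param ecop15iBias either \code{NULL} (no bias) or \code{c(factor,
#'   window)}: candidate tag positions within \code{window} bp 3' of a
#'   reverse (CTGCTG) recognition site are down-weighted by \code{factor}
#'   before sampling.
#' @param antisense emit reads antisense to the transcript strand (default
#'   TRUE, as the sequencing primer sits distal to the mRNA 5' end).
#' @param homopolymerReads number of additional all-zero-color reads to
#'   append (a fixture for the low-information filter; default 0).
#' @param primer SOLiD primer base (default \code{"T"}).
#' @return a named list of validated parameters.
#' @export
libraryParams <- function(depth = 1e6, tagLength = 25L,
                          colorErrorRate = 0, ecop15iBias = NULL,
                          antisense = TRUE, homopolymerReads = 0L,
                          primer = "T") {
    stopifnot(depth > 0, tagLength >= 2L,
              colorErrorRate >= 0, colorErrorRate < 0.25)
    if (!is.null(ecop15iBias))
        stopifnot(length(ecop15iBias) == 2L, ecop15iBias[1] > 1,
                  ecop15iBias[2] >= 1)
    list(depth = depth, tagLength = as.integer(tagLength),
         colorErrorRate = colorErrorRate, ecop15iBias = ecop15iBias,
         antisense = isTRUE(antisense),
         homopolymerReads = as.integer(homopolymerReads), primer = primer)
}

#' In-silico EcoP15I digestion
#'
#' EcoP15I is a type III enzyme cleaving 25/27 nt downstream of its
#' recognition site, releasing a fragment that carries exactly 25 bp of
#' flanking sequence with a 2-nt 5' overhang. For every occurrence of the
#' forward site (CAGCAG) the 25 bp 3' of the site on the given strand are
#' returned, and for every reverse site (CTGCTG) the 25 bp on the opposite
#' strand; in both cases the tag is taken 3' of the site in the site's own
#' orientation. Sites with fewer than 27 bp of downstream sequence cannot be
#' cleaved into a full tag and are dropped with a warning.
#'
#' @param sequence a DNA string (character or \code{DNAString}), e.g. a
#'   simulated double-stranded cDNA whose engineered site flanks the 5' tag.
#' @return data.frame with columns \code{tag} (25 bp), \code{overhang}
#'   (2 nt), \code{site_pos} (1-based position of the site's first base as
#'   written on the input strand) and \code{orientation}
#'   (\code{"+"}/\code{"-"}); zero rows signal an undigested molecule.
#' @export
digestEcoP15I <- function(sequence) {
    s <- toupper(as.character(sequence))
    L <- nchar(s)
    hit <- function(motif) {
        m <- gregexpr(motif, s, fixed = TRUE)[[1]]
        if (m[1] == -1L) integer() else as.integer(m)
    }
    out <- list()
    dropped <- 0L
    for (i in hit("CAGCAG")) {
        if (i + 32L > L) { dropped <- dropped + 1L; next }
        out[[length(out) + 1L]] <- data.frame(
            tag = substr(s, i + 6L, i + 30L),
            overhang = substr(s, i + 31L, i + 32L),
            site_pos = i, orientation = "+", stringsAsFactors = FALSE)
    }
    for (i in hit("CTGCTG")) {
        if (i - 27L < 1L) { dropped <- dropped + 1L; next }
        out[[length(out) + 1L]] <- data.frame(
            tag = .cs_revcomp(substr(s, i - 25L, i - 1L)),
            overhang = .cs_revcomp(substr(s, i - 27L, i - 26L)),
            site_pos = i, orientation = "-", stringsAsFactors = FALSE)
    }
    if (dropped > 0L)
        warning(dropped, " site(s) closer than 27 bp to the molecule end; ",
                "dropped")
    if (length(out) == 0L)
        return(data.frame(tag = character(), overhang = character(),
                          site_pos = integer(), orientation = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

# Candidate tag 5'-end positions for one gene: transcript offset (1-based,
# from the annotated 5' end along the exon chain) and the genomic coordinate
# of the transcript-5'-most base of a tag starting there. Only windows fully
# inside one exon qualify (junction tags are out of scope).
.tagCandidates <- function(exons, geneStrand, tagLength) {
    exStarts <- start(exons); exEnds <- end(exons)
    if (geneStrand == "-") { # transcript runs right to left
        exStarts <- rev(start(exons)); exEnds <- rev(end(exons))
    }
    txOff <- 0L
    d <- integer(); gpos <- integer()
    for (k in seq_along(exStarts)) {
        w <- exEnds[k] - exStarts[k] + 1L
        nvalid <- w - tagLength + 1L
        if (nvalid > 0L) {
            d <- c(d, txOff + seq_len(nvalid))
            gpos <- c(gpos, if (geneStrand == "+")
                exStarts[k] + seq_len(nvalid) - 1L
                else exEnds[k] - seq_len(nvalid) + 1L)
        }
        txOff <- txOff + w
    }
    list(d = d, gpos = gpos)
}

# Positions (1-based) within `window` bp 3' of a reverse EcoP15I site, in
# the site's orientation: for CTGCTG as written on the forward strand this
# is the window immediately LEFT of the site's first base.
.reverseSiteWindows <- function(scafSeq, window) {
    sites <- gregexpr("CTGCTG", scafSeq, fixed = TRUE)[[1]]
    if (sites[1] == -1L) return(integer())
    sites <- as.integer(sites)
    unique(as.vector(outer(sites, seq_len(window), function(s, k) s - k)))
}

#' Simulate a 5'-DGE tag library for one sample
#'
#' Generates color-space tag reads from a genome, gene models and an
#' expression truth. Per-gene tag counts are Poisson with mean
#' \code{depth * TPM / 1e6}. Each tag's position is drawn from a mixture:
#' with probability \code{tssWeight} exactly the annotated transcript 5'
#' end (the sharp TSS peak), otherwise an exonic position with weight
#' decaying exponentially in transcript coordinates (truncated mRNAs and
#' premature template switching). Reads are emitted antisense to the
#' transcript strand, encoded in color space, and corrupted with uniform
#' color errors at the configured rate. Optionally, candidate positions
#' within a window 3' of reverse EcoP15I sites are suppressed by a constant
#' factor before sampling (restriction-site bias).
#'
#' @param genome \code{DNAStringSet}.
#' @param genes \code{GRanges} with \code{gene_id} and \code{exons}.
#' @param truth a \linkS4class{SimTruth} covering all genes.
#' @param params list from \code{\link{libraryParams}}.
#' @param sample time-point column of the truth to simulate (index or
#'   name).
#' @param seed random seed.
#' @return list with \code{reads} (color-read data.frame), \code{truthHits}
#'   (read_id, scaffold, pos = 1-based leftmost mapped base, strand =
#'   mapped strand, gene_id) and \code{trueCounts} (named numeric).
#' @export
simulateTags <- function(genome, genes, truth, params = libraryParams(),
                         sample = 1L, seed = 1L) {
    tpm <- trueTpm(truth)
    ids <- mcols(genes)$gene_id
    if (!all(ids %in% rownames(tpm)))
        stop("truth does not cover all genes")
    tagLen <- params$tagLength
    seqs <- as.character(genome)
    withr::with_seed(seed, {
        counts <- rpois(length(ids),
                        params$depth * tpm[ids, sample] / 1e6)
        suppressed <- list()  # per scaffold, lazily
        geneTab <- vector("list", length(ids))
        for (g in seq_along(ids)) {
            if (counts[g] == 0L) next
            sc <- as.character(seqnames(genes))[g]
            str <- as.character(strand(genes))[g]
            cand <- .tagCandidates(mcols(genes)$exons[[g]], str, tagLen)
            if (length(cand$d) == 0L || cand$d[1] != 1L)
                stop("gene ", ids[g], " shorter than the tag length")
            w <- exp(-(cand$d - 1) / truth@decayScale)
            w <- w / sum(w)
            tw <- truth@tssWeight[match(ids[g], rownames(tpm))]
            w <- (1 - tw) * w
            w[1] <- w[1] + tw
            if (!is.null(params$ecop15iBias)) {
                if (is.null(suppressed[[sc]]))
                    suppressed[[sc]] <- .reverseSiteWindows(
                        seqs[[sc]], as.integer(params$ecop15iBias[2]))
                hitw <- cand$gpos %in% suppressed[[sc]]
                w[hitw] <- w[hitw] / params$ecop15iBias[1]
                w <- w / sum(w)
            }
            pick <- sample.int(length(cand$d), counts[g], replace = TRUE,
                               prob = w)
            geneTab[[g]] <- data.frame(gene = ids[g], scaffold = sc,
                                       strand = str,
                                       g5 = cand$gpos[pick],
                                       stringsAsFactors = FALSE)
        }
        tab <- do.call(rbind, geneTab)
        if (is.null(tab))
            tab <- data.frame(gene = character(), scaffold = character(),
                              strand = character(), g5 = integer())
        # genomic window of the tag and the strand the read maps to
        onPlus <- tab$strand == "+"
        left <- ifelse(onPlus, tab$g5, tab$g5 - tagLen + 1L)
        mapStrand <- if (params$antisense) ifelse(onPlus, "-", "+")
                     else ifelse(onPlus, "+", "-")
        readSeq <- character(nrow(tab))
        for (sc in unique(tab$scaffold)) {
            j <- tab$scaffold == sc
            readSeq[j] <- substring(seqs[[sc]], left[j],
                                    left[j] + tagLen - 1L)
        }
        needRc <- mapStrand == "-"
        readSeq[needRc] <- .cs_revcomp(readSeq[needRc])
        colors <- if (nrow(tab)) .cs_encode(readSeq, params$primer)
                  else character()
        if (params$colorErrorRate > 0 && length(colors)) {
            big <- paste(colors, collapse = "")
            nc <- nchar(big)
            nErr <- rbinom(1L, nc, params$colorErrorRate)
            if (nErr > 0L) {
                idx <- sample.int(nc, nErr)
                raw <- charToRaw(big)
                old <- as.integer(raw[idx]) - utf8ToInt("0")
                newc <- (old + sample.int(3L, nErr, replace = TRUE)) %% 4L
                raw[idx] <- as.raw(newc + utf8ToInt("0"))
                big <- rawToChar(raw)
            }
            starts <- seq(1L, by = tagLen, length.out = length(colors))
            colors <- substring(big, starts, starts + tagLen - 1L)
        }
        readId <- sprintf("s%s_r%06d", as.character(sample),
                          seq_len(nrow(tab)))
        reads <- data.frame(id = readId, primer = params$primer,
                            colors = colors, stringsAsFactors = FALSE)
        truthHits <- data.frame(read_id = readId, scaffold = tab$scaffold,
                                pos = left, strand = mapStrand,
                                gene_id = tab$gene,
                                stringsAsFactors = FALSE)
        if (params$homopolymerReads > 0L) {
            hp <- data.frame(
                id = sprintf("s%s_lowinfo%04d", as.character(sample),
                             seq_len(params$homopolymerReads)),
                primer = params$primer,
                colors = strrep("0", tagLen), stringsAsFactors = FALSE)
            reads <- rbind(reads, hp)
        }
        list(reads = reads, truthHits = truthHits,
             trueCounts = setNames(counts, ids))
    })
}

#' Simulate a replicated time-course experiment
#'
#' Calls \code{\link{simulateTags}} once per (time point, replicate) pair
#' with distinct seeds derived from \code{seed}, and assembles the sample
#' sheet.
#'
#' @param genome,genes,truth,params see \code{\link{simulateTags}}.
#' @param nReplicates replicates per time point.
#' @param seed base seed.
#' @return list with \code{reads} (named list of read data.frames),
#'   \code{sampleSheet} (sample, timepoint, replicate) and
#'   \code{truthCounts} (genes x samples matrix).
#' @export
simulateExperiment <- function(genome, genes, truth,
                               params = libraryParams(), nReplicates = 2L,
                               seed = 1L) {
    nT <- ncol(trueTpm(truth))
    sheet <- expand.grid(replicate = seq_len(nReplicates),
                         timepoint = seq_len(nT))[, 2:1]
    sheet$sample <- sprintf("t%d_r%d", sheet$timepoint, sheet$replicate)
    reads <- list()
    truthCounts <- NULL
    for (j in seq_len(nrow(sheet))) {
        sim <- simulateTags(genome, genes, truth, params,
                            sample = sheet$timepoint[j],
                            seed = seed + j)
        reads[[sheet$sample[j]]] <- sim$reads
        truthCounts <- cbind(truthCounts, sim$trueCounts)
    }
    colnames(truthCounts) <- sheet$sample
    list(reads = reads, sampleSheet = sheet[, c("sample", "timepoint",
                                                "replicate")],
         truthCounts = truthCounts)
}
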