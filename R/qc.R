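#' @include counting.R
NULL

#' Cumulative tag profile around EcoP15I recognition sites
#'
#' Because EcoP15I is used during library construction, tags near its
#' recognition sequence may be over- or under-represented. For every exact
#' occurrence of the forward (CAGCAG) and reverse (CTGCTG) site in the
#' genome, tag weights (both strands summed) at relative offsets within
#' \code{window} bp are accumulated over all sites. Offset 0 is the first C
#' of the site as written on the forward strand; for the reverse site,
#' "3' of the site" in the site's own orientation corresponds to negative
#' offsets.
#'
#' @param genome \code{DNAStringSet} (the scaffolds the tag array indexes).
#' @param tagArray a \linkS4class{TagArray}.
#' @param window half-width of the profile in bp (default 100).
#' @return data.frame with columns \code{motif}, \code{offset},
#'   \code{weight}, and an attribute \code{n_sites} (named count per
#'   motif). Motifs without occurrences get an empty profile with a
#'   warning.
#' @export
ecop15iBiasProfile <- function(genome, tagArray, window = 100L) {
    ref <- tagArray@reference
    track <- tagArray@plus + tagArray@minus
    offs <- seq(-window, window)
    out <- list()
    nSites <- c(CAGCAG = 0L, CTGCTG = 0L)
    for (motif in c("CAGCAG", "CTGCTG")) {
        total <- numeric(length(offs))
        for (sc in names(scaffoldLengths(ref))) {
            s <- as.character(genome[[sc]])
            sites <- gregexpr(motif, s, fixed = TRUE)[[1]]
            if (sites[1] == -1L) next
            sites <- as.integer(sites)
            nSites[motif] <- nSites[motif] + length(sites)
            len <- scaffoldLengths(ref)[[sc]]
            g0 <- scaffoldOffsets(ref)[[sc]]
            for (k in seq_along(offs)) {
                p <- sites + offs[k]
                p <- p[p >= 1L & p <= len]
                total[k] <- total[k] + sum(track[g0 + p])
            }
        }
        if (nSites[motif] == 0L) {
            warning("no occurrences of ", motif, " in the genome")
            next
        }
        out[[motif]] <- data.frame(motif = motif, offset = offs,
                                   weight = total,
                                   stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(motif = character(), offset = integer(),
                           weight = numeric())
    rownames(res) <- NULL
    attr(res, "n_sites") <- nSites
    res
}

#' Estimate the suppression factor next to a recognition site
#'
#' Ratio of the mean profile weight in a flanking stretch to the mean in
#' the window immediately 3' of the site (site orientation): a factor of 3
#' means tags in the window are threefold depleted relative to the flank.
#' For the reverse site (CTGCTG) the 3' window lies at negative offsets;
#' for the forward site it starts just past the 6 bp recognition sequence.
#'
#' @param profile data.frame from \code{\link{ecop15iBiasProfile}}.
#' @param motif \code{"CTGCTG"} (default) or \code{"CAGCAG"}.
#' @param window width in bp of the suppressed region 3' of the site
#'   (default 20).
#' @param flank offsets (relative distance beyond the window, in bp) used
#'   as the unbiased baseline; default extends to the profile edge.
#' @return the estimated suppression factor (flank mean / window mean).
#' @export
estimateSiteSuppression <- function(profile, motif = "CTGCTG",
                                    window = 20L, flank = NULL) {
    p <- profile[profile$motif == motif, ]
    if (nrow(p) == 0L) stop("no profile for motif ", motif)
    if (motif == "CTGCTG") {
        winOff <- -seq_len(window)
        flankOff <- if (is.null(flank)) seq(min(p$offset), -window - 1L)
                    else -flank
    } else {
        winOff <- 6L + seq_len(window) - 1L
        flankOff <- if (is.null(flank)) seq(window + 6L, max(p$offset))
                    else flank
    }
    winMean <- mean(p$weight[p$offset %in% winOff])
    flankMean <- mean(p$weight[p$offset %in% flankOff])
    if (winMean <= 0) return(Inf)
    flankMean / winMean
}

#' Squared correlation between two samples
#'
#' Pearson R-squared of two samples' TPM values over genes passing a
#' minimum TPM in both samples, computed on log10 scale by default (tag
#' TPM spans several orders of magnitude; replicate scatter is judged
#' log-log).
#'
#' @param x \code{SummarizedExperiment} with a \code{tpm} assay, or a
#'   numeric genes x samples TPM matrix.
#' @param a,b sample names or indices.
#' @param scale \code{"log10"} (default) or \code{"linear"}.
#' @param minTpm inclusion threshold; genes need \code{tpm >= minTpm} in
#'   both samples (default 1).
#' @return squared Pearson correlation (scalar).
#' @export
replicateCorrelation <- function(x, a, b, scale = c("log10", "linear"),
                                 minTpm = 1) {
    scale <- match.arg(scale)
    tpm <- if (is(x, "SummarizedExperiment")) assays(x)$tpm else x
    va <- tpm[, a]; vb <- tpm[, b]
    keep <- va >= minTpm & vb >= minTpm
    if (sum(keep) < 3L)
        stop("fewer than 3 genes pass minTpm = ", minTpm, " in both samples")
    if (scale == "log10") { va <- log10(va[keep]); vb <- log10(vb[keep]) }
    else { va <- va[keep]; vb <- vb[keep] }
    cor(va, vb)^2
}

#' Transcript length versus TPM, in bins of equal gene count
#'
#' Genes are sorted by summed exon length (gene id breaking ties, so bin
#' boundaries are deterministic) and chunked into bins of \code{binSize}
#' genes; each bin is summarised by its five-number TPM summary. A trailing
#' partial bin is retained and flagged.
#'
#' @param genes \code{GRanges} with \code{gene_id} and \code{exons}.
#' @param tpm named numeric vector of TPM values (names = gene ids), or a
#'   \code{SummarizedExperiment} plus \code{sample}.
#' @param binSize genes per bin (default 1000).
#' @param sample sample to use when \code{tpm} is a
#'   \code{SummarizedExperiment}.
#' @return data.frame with one row per bin: \code{bin}, \code{n},
#'   \code{median_length}, the five-number summary of TPM and
#'   \code{partial}.
#' @export
lengthVsTpm <- function(genes, tpm, binSize = 1000L, sample = 1L) {
    if (is(tpm, "SummarizedExperiment")) tpm <- assays(tpm)$tpm[, sample]
    ids <- mcols(genes)$gene_id
    exLen <- vapply(mcols(genes)$exons, function(e) sum(width(e)),
                    numeric(1))
    o <- order(exLen, ids)
    v <- tpm[ids][o]
    lens <- exLen[o]
    bin <- ceiling(seq_along(v) / binSize)
    res <- lapply(unique(bin), function(b) {
        fv <- fivenum(v[bin == b])
        data.frame(bin = b, n = sum(bin == b),
                   median_length = median(lens[bin == b]),
                   min = fv[1], q1 = fv[2], median = fv[3], q3 = fv[4],
                   max = fv[5], partial = sum(bin == b) < binSize)
    })
    do.call(rbind, res)
}

#' Mapping statistics manifest
#'
#' Percentages of mappable, low-information and uniquely mapped reads.
#' Ratios with a zero denominator are reported as \code{NA}.
#'
#' @param nTotal total reads sequenced.
#' @param nMapped reads with at least one accepted hit.
#' @param nLowInfo reads removed by the low-information filter.
#' @param nUnique mapped reads with a unique best hit.
#' @return one-row data.frame of counts and percentages.
#' @export
mappingStats <- function(nTotal, nMapped, nLowInfo = 0L, nUnique = NA) {
    pct <- function(num, den) if (is.na(den) || den == 0) NA_real_
                              else num / den * 100
    data.frame(n_total = nTotal, n_mapped = nMapped,
               n_low_info = nLowInfo, n_unique = nUnique,
               pct_mapped = pct(nMapped, nTotal),
               pct_low_info = pct(nLowInfo, nTotal),
               pct_unique_of_mapped = pct(nUnique, nMapped))
}

#' Stochastic error of a TPM estimate at a given depth
#'
#' Monte-Carlo Poisson resampling of the tag count of a gene expressed at
#' \code{trueTpm}, sequenced to \code{depth} mapped tags: the relative
#' stochastic error is the standard deviation of the re-estimated TPM over
#' simulations, as a percentage of the true value. At 1 TPM and 16 million
#' tags the count is Poisson(16), so the expected value is
#' \code{100/sqrt(16)} = 25 percent.
#'
#' @param trueTpm true expression in TPM (default 1).
#' @param depth mapped tags per library (default 16e6).
#' @param nSim number of Monte-Carlo resamplings (default 2000).
#' @param seed random seed.
#' @return list with \code{percent} (relative error, percent),
#'   \code{mean_tpm} and \code{sd_tpm}.
#' @export
stochasticErrorTpm <- function(trueTpm = 1, depth = 16e6, nSim = 2000L,
                               seed = 1L) {
    withr::with_seed(seed, {
        counts <- rpois(nSim, depth * trueTpm / 1e6)
        est <- computeTpm(counts, depth)
        list(percent = sd(est) / trueTpm * 100,
             mean_tpm = mean(est), sd_tpm = sd(est))
    })
}
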