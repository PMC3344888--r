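#' @include genome-sim.R
NULL

#' Assign time-course expression truth to genes
#'
#' Draws a baseline abundance per gene (log-normal, so most genes are low
#' and a few dominate, as in real tag libraries) and overlays temporal
#' patterns: a fraction \code{fractionNull} of genes stay flat across time;
#' the rest receive one of \code{nPatterns} smooth multiplicative bumps
#' peaking at distinct times with a maximum fold change of
#' \code{effectSize}. Every pattern is guaranteed at least one gene when
#' enough non-null genes exist. Each time-point column is normalised to sum
#' to 1e6 TPM.
#'
#' @param genes \code{GRanges} of gene models (or a character vector of gene
#'   ids).
#' @param nTimepoints number of time points (default 6, as in a
#'   0/1/3/6/12/24 h course).
#' @param nPatterns number of temporal patterns (<= 9; default 3).
#' @param fractionNull fraction of genes with flat profiles (default 0.9).
#' @param effectSize peak fold change of a pattern (default 4).
#' @param tssPeakWeight fraction of a gene's tags placed exactly at its
#'   annotated 5' end (default 0.6; the remainder spreads over the exons).
#' @param decayScale exponential decay scale, in bp from the 5' end, of the
#'   exon-body tag background (default 500).
#' @param baseMeanLog,baseSdLog log-normal parameters of the baseline TPM.
#' @param seed random seed.
#' @return a \linkS4class{SimTruth}.
#' @export
assignExpressionProfiles <- function(genes, nTimepoints = 6L,
                                     nPatterns = 3L, fractionNull = 0.9,
                                     effectSize = 4, tssPeakWeight = 0.6,
                                     decayScale = 500,
                                     baseMeanLog = log(20),
                                     baseSdLog = 1.2, seed = 1L) {
    stopifnot(nPatterns >= 1L, nPatterns <= 9L,
              fractionNull >= 0, fractionNull <= 1,
              nTimepoints >= 1L, effectSize >= 1)
    ids <- if (is.character(genes)) genes else mcols(genes)$gene_id
    n <- length(ids)
    withr::with_seed(seed, {
        base <- rlnorm(n, baseMeanLog, baseSdLog)
        nNull <- round(fractionNull * n)
        isNull <- seq_len(n) %in% sample.int(n, nNull)
        pattern <- rep("null", n)
        nSig <- n - nNull
        if (nSig > 0) {
            lab <- sample(rep_len(seq_len(nPatterns), nSig))
            pattern[!isNull] <- paste0("P", lab)
        }
        peaks <- seq(1, nTimepoints, length.out = nPatterns + 2L)
        peaks <- peaks[-c(1L, nPatterns + 2L)]
        t <- seq_len(nTimepoints)
        tpm <- matrix(base, n, nTimepoints,
                      dimnames = list(ids, paste0("t", t)))
        for (j in seq_len(nPatterns)) {
            sel <- pattern == paste0("P", j)
            if (!any(sel)) next
            bump <- effectSize ^ exp(-(t - peaks[j])^2 / 2)
            tpm[sel, ] <- tpm[sel, , drop = FALSE] *
                matrix(bump, sum(sel), nTimepoints, byrow = TRUE)
        }
        # TPM is compositional: the bump mass is balanced within the
        # regulated gene set (a column factor on non-null genes only), so
        # null genes are genuinely flat in TPM while every column keeps the
        # same total.
        nn <- pattern != "null"
        if (any(nn) && any(!nn)) {
            target <- sum(base[nn])
            corr <- target / colSums(tpm[nn, , drop = FALSE])
            tpm[nn, ] <- sweep(tpm[nn, , drop = FALSE], 2L, corr, "*")
        }
        tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
        new("SimTruth", tpm = tpm, pattern = pattern,
            tssWeight = rep(tssPeakWeight, n), decayScale = decayScale,
            params = list(nTimepoints = nTimepoints, nPatterns = nPatterns,
                          fractionNull = fractionNull,
                          effectSize = effectSize, seed = seed,
                          peaks = peaks))
    })
}

#' @rdname SimTruth-class
#' @export
setMethod("trueTpm", "SimTruth", function(x) x@tpm)

#' @rdname SimTruth-class
#' @export
setMethod("patternLabels", "SimTruth", function(x) x@pattern)

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@tpm), "genes x", ncol(object@tpm),
        "time points;", sum(object@pattern != "null"),
        "non-null gene(s) in",
        length(setdiff(unique(object@pattern), "null")), "pattern(s)\n")
})

#' Write the true TPM matrix as TSV
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTruthTpm <- function(truth, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# fiveDGE simulation truth: TPM per time point", con)
    write.table(data.frame(gene_id = rownames(trueTpm(truth)),
                           pattern = patternLabels(truth),
                           trueTpm(truth), check.names = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Simulate a count/TPM matrix directly from expression truth
#'
#' Draws per-gene tag counts as independent Poisson samples at the given
#' sequencing depth for every replicate of every time point — the count
#' distribution the tag pipeline would produce for uniquely mapped tags —
#' without simulating reads. Used for statistical calibration studies
#' (null uniformity, FDR, power, clustering recovery) where read-level
#' detail is irrelevant.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param depth tags per sample (default 5e6).
#' @param nReplicates replicates per time point (default 3).
#' @param seed random seed.
#' @return \code{SummarizedExperiment} with assays \code{counts} and
#'   \code{tpm}, and \code{colData} columns \code{timepoint},
#'   \code{replicate}, \code{total_mapped}.
#' @export
simulateCountMatrix <- function(truth, depth = 5e6, nReplicates = 3L,
                                seed = 1L) {
    tpm <- trueTpm(truth)
    nT <- ncol(tpm)
    n <- nrow(tpm)
    withr::with_seed(seed, {
        cols <- expand.grid(replicate = seq_len(nReplicates),
                            timepoint = seq_len(nT))[, 2:1]
        counts <- matrix(0, n, nrow(cols))
        for (j in seq_len(nrow(cols)))
            counts[, j] <- rpois(n, depth * tpm[, cols$timepoint[j]] / 1e6)
        dimnames(counts) <- list(rownames(tpm),
                                 sprintf("t%d_r%d", cols$timepoint,
                                         cols$replicate))
        totals <- colSums(counts)
        SummarizedExperiment(
            assays = list(counts = counts,
                          tpm = computeTpm(counts, totals)),
            colData = DataFrame(timepoint = factor(cols$timepoint),
                                replicate = cols$replicate,
                                total_mapped = totals,
                                row.names = colnames(counts)))
    })
}
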